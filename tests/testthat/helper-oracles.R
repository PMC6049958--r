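# Independent count-based oracles: every statistic is recomputed from an
# explicit chromosome expansion of the genotypes, never from the package's
# frequency-form code paths.

# Expand a dosage matrix (sites x individuals) into a 0/1 chromosome
# matrix (sites x total chromosomes); no missing dosages allowed.
chrom_expand <- function(geno, ploidy) {
  stopifnot(!anyNA(geno))
  cols <- lapply(seq_len(ncol(geno)), function(j) {
    t(vapply(geno[, j], function(d)
      c(rep(1L, d), rep(0L, ploidy[j] - d)), integer(ploidy[j])))
  })
  do.call(cbind, cols)
}

# Mean pairwise difference per window by enumerating chromosome pairs.
oracle_theta_pi <- function(chr) {
  n <- ncol(chr)
  tot <- 0
  for (a in seq_len(n - 1))
    for (b in (a + 1):n)
      tot <- tot + sum(chr[, a] != chr[, b])
  tot / choose(n, 2)
}

oracle_tajd <- function(chr) {
  n <- ncol(chr)
  cnt <- rowSums(chr)
  s <- sum(cnt > 0 & cnt < n)
  if (s == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (oracle_theta_pi(chr) - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

# H = pi - theta_H with theta_H from derived counts.
oracle_fwh <- function(chr) {
  n <- ncol(chr)
  cnt <- rowSums(chr)
  seg <- cnt > 0 & cnt < n
  if (!any(seg)) return(NA_real_)
  th <- sum(2 * cnt[seg]^2 / (n * (n - 1)))
  pi_seg <- sum(cnt[seg] * (n - cnt[seg])) / choose(n, 2)
  pi_seg - th
}

# G_ST with heterozygosities taken as the probability that two
# with-replacement chromosome draws differ (enumerated, not 2p(1-p)).
oracle_gst <- function(chr_by_pop) {
  het <- function(chr_col) {
    n <- length(chr_col)
    mean(outer(chr_col, chr_col, `!=`))
  }
  n_sites <- nrow(chr_by_pop[[1]])
  num <- den <- 0
  for (s in seq_len(n_sites)) {
    hs <- mean(vapply(chr_by_pop, function(m) het(m[s, ]), numeric(1)))
    pooled_p <- mean(vapply(chr_by_pop, function(m) mean(m[s, ]),
                            numeric(1)))
    # H_T from the unweighted mean frequency, via two virtual draws
    ht <- 2 * pooled_p * (1 - pooled_p)
    num <- num + (ht - hs)
    den <- den + ht
  }
  if (den == 0) NA_real_ else num / den
}

# ABBA/BABA family by enumerating chromosome quartets (via exact counts
# of each pattern among all c1 x c2 x c3 x cO combinations).
oracle_quartet_sums <- function(chr1, chr2, chr3, chro,
                                mode = c("d", "fhom", "fd")) {
  mode <- match.arg(mode)
  n_sites <- nrow(chr1)
  num <- den <- 0
  for (s in seq_len(n_sites)) {
    c1 <- chr1[s, ]; c2 <- chr2[s, ]; c3 <- chr3[s, ]; co <- chro[s, ]
    n_quart <- length(c1) * length(c2) * length(c3) * length(co)
    abba <- sum(c1 == 0) * sum(c2 == 1) * sum(c3 == 1) * sum(co == 0)
    baba <- sum(c1 == 1) * sum(c2 == 0) * sum(c3 == 1) * sum(co == 0)
    if ((abba + baba) == 0) next  # not informative
    num <- num + (abba - baba) / n_quart
    den <- den + switch(mode,
      d = (abba + baba) / n_quart,
      fhom = {
        a <- sum(c1 == 0) * sum(c3 == 1) * sum(c3 == 1) * sum(co == 0)
        b <- sum(c1 == 1) * sum(c3 == 0) * sum(c3 == 1) * sum(co == 0)
        (a - b) / (length(c1) * length(c3)^2 * length(co))
      },
      fd = {
        cd <- if (mean(c2) >= mean(c3)) c2 else c3
        a <- sum(c1 == 0) * sum(cd == 1) * sum(cd == 1) * sum(co == 0)
        b <- sum(c1 == 1) * sum(cd == 0) * sum(cd == 1) * sum(co == 0)
        (a - b) / (length(c1) * length(cd)^2 * length(co))
      })
  }
  if (mode == "fd" && num < 0) return(list(value = 0))
  if (mode == "fhom" && den <= 0) return(list(value = NA_real_))
  list(value = if (den == 0) NA_real_ else num / den)
}
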