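#' Nei's G_ST over a set of sites
#'
#' Multi-population differentiation aggregated as a ratio of sums across
#' sites (stable at low-diversity sites):
#' `G_ST = sum(H_T - H_S) / sum(H_T)`, where per site `H_S` is the
#' unweighted mean within-population expected heterozygosity `2p(1-p)`
#' and `H_T = 2 pbar (1-pbar)` from the unweighted mean frequency. Sites
#' with fewer than two non-missing populations are skipped; if every
#' counted site is monomorphic overall (`sum(H_T) = 0`) the value is
#' undefined and `NA` is returned.
#'
#' @param p_mat Numeric matrix, sites x populations, of allele
#'   frequencies (polarization is irrelevant: G_ST is invariant to
#'   p -> 1-p).
#' @return A single value in `[0, 1]`, or `NA`.
#' @export
gst_window <- function(p_mat) {
  p_mat <- as.matrix(p_mat)
  keep <- rowSums(!is.na(p_mat)) >= 2
  if (!any(keep)) return(NA_real_)
  p <- p_mat[keep, , drop = FALSE]
  hs <- rowMeans(2 * p * (1 - p), na.rm = TRUE)
  pbar <- rowMeans(p, na.rm = TRUE)
  ht <- 2 * pbar * (1 - pbar)
  if (sum(ht) <= 0) return(NA_real_)
  sum(ht - hs) / sum(ht)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# per-site unbiased pairwise heterozygosity n/(n-1) * 2p(1-p)
theta_pi_sites <- function(p, n_chr) {
  n_chr / (n_chr - 1) * 2 * p * (1 - p)
}

#' Tajima's D over a window of sites in one population
#'
#' `D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S-1))` with the standard
#' constants evaluated at a window-level chromosome count `n` (the median
#' per-site count, robust to missingness varying site by site).
#' `theta_pi` sums the per-site unbiased heterozygosity
#' `n/(n-1) 2p(1-p)`; `theta_W = S / a1` with `S` the number of
#' segregating sites.
#'
#' @param p Per-site allele frequencies (sample frequencies within the
#'   population; any consistent polarization).
#' @param n_chr Per-site chromosome counts (4 x genotyped individuals for
#'   tetraploids).
#' @return A single value, or `NA` when `S = 0` or `n < 4`.
#' @export
tajimas_d_window <- function(p, n_chr) {
  keep <- !is.na(p) & !is.na(n_chr)
  p <- p[keep]; n_chr <- n_chr[keep]
  if (!length(p)) return(NA_real_)
  seg <- p > 0 & p < 1
  s <- sum(seg)
  n <- median(n_chr)
  if (s == 0 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  theta_pi <- sum(theta_pi_sites(p[seg], n_chr[seg]))
  theta_w <- s / k$a1
  (theta_pi - theta_w) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

#' Fay and Wu's H over a window of polarized sites in one population
#'
#' `H = theta_pi - theta_H` in the original (unnormalized) form, with
#' `theta_H = sum 2 p^2 n/(n-1)` over derived-allele frequencies --
#' equivalently `sum 2 S_i i^2 / (n (n-1))` over derived counts.
#' Strongly negative values flag an excess of high-frequency derived
#' variants. Requires outgroup-polarized frequencies; unpolarizable sites
#' must be excluded upstream.
#'
#' @param p Per-site derived-allele frequencies.
#' @param n_chr Per-site chromosome counts.
#' @return A single value, or `NA` when no site segregates.
#' @export
fay_wu_h_window <- function(p, n_chr) {
  keep <- !is.na(p) & !is.na(n_chr)
  p <- p[keep]; n_chr <- n_chr[keep]
  seg <- p > 0 & p < 1
  if (!sum(seg)) return(NA_real_)
  theta_pi <- sum(theta_pi_sites(p[seg], n_chr[seg]))
  theta_h <- sum(2 * p[seg]^2 * n_chr[seg] / (n_chr[seg] - 1))
  theta_pi - theta_h
}
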