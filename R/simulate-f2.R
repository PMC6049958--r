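#' QTL plan for F2 simulation
#'
#' @param markers Integer marker indices carrying planted QTL.
#' @param effects Phenotype effect per QTL: days added per dosage unit
#'   (additive) or per carrier/quadruplex state.
#' @param modes One of `"additive"`, `"dominant"`, `"recessive"` per QTL.
#' @param residual_sd Residual phenotype SD (days).
#' @param baseline Baseline days to bolting.
#' @param censor_threshold Experiment end (days); later phenotypes are
#'   recorded at this value with a censoring flag, the convention used for
#'   plants that had not bolted by experiment end.
#' @return A list with class `qtl_plan`.
#' @export
qtl_plan <- function(markers, effects,
                     modes = rep("additive", length(markers)),
                     residual_sd = 10, baseline = 40,
                     censor_threshold = 140) {
  abort_if(length(markers) != length(effects) ||
             length(markers) != length(modes),
           "markers, effects, modes must have equal length")
  abort_if(any(!is.finite(effects)), "effects must be finite")
  abort_if(censor_threshold <= 0, "censor_threshold must be positive")
  abort_if(!all(modes %in% c("additive", "dominant", "recessive")),
           "unknown dominance mode")
  structure(list(markers = as.integer(markers), effects = effects,
                 modes = modes, residual_sd = residual_sd,
                 baseline = baseline,
                 censor_threshold = censor_threshold),
            class = "qtl_plan")
}

#' Simulate a tetraploid F2 mapping population
#'
#' Two parents (given as dosage vectors over `m` markers) are crossed; two
#' F1 siblings are intercrossed to give `n_f2` F2 individuals. Meiosis
#' follows bivalent pairing without double reduction: each gamete receives
#' one strand from each of two random homolog pairs, with recombination
#' probability `recomb` between adjacent markers on a scaffold and
#' independent assortment across scaffolds. Parental dosages are phased
#' maximally (the first `d` homologs carry the derived allele), the
#' natural phase for near-inbred parental accessions.
#'
#' Phenotype is `baseline + sum of QTL effects + N(0, residual_sd)`,
#' right-censored at `censor_threshold`.
#'
#' @param parent1,parent2 Integer dosage vectors (0..4) of equal length.
#' @param qtl A [qtl_plan()].
#' @param n_f2 Number of F2 individuals (>= 2).
#' @param scaffold Character vector assigning markers to scaffolds
#'   (default: all on one).
#' @param recomb Recombination fraction between adjacent markers.
#' @param missing_rate Probability a marker genotype is missing (RADseq
#'   dropout).
#' @param seed Integer RNG seed.
#' @return An `f2_panel`: list with `markers` (tibble: marker, scaffold,
#'   position), `geno` (markers x individuals dosage matrix), `phenotype`
#'   (tibble: individual, days_to_bolting, censored). The `qtl` attribute
#'   stores the truth.
#' @export
simulate_f2 <- function(parent1, parent2, qtl, n_f2 = 300L,
                        scaffold = NULL, recomb = 0.01,
                        missing_rate = 0, seed = 1L) {
  m <- length(parent1)
  abort_if(length(parent2) != m, "parents differ in marker count")
  abort_if(n_f2 < 2, "need at least two F2 individuals")
  abort_if(any(c(parent1, parent2) < 0 | c(parent1, parent2) > 4),
           "parental dosages must lie in 0..4")
  stopifnot(inherits(qtl, "qtl_plan"))
  scaffold <- scaffold %||% rep("scaffold_1", m)
  phase <- function(d) outer(d, 1:4, function(dd, h) as.integer(h <= dd))
  h1 <- phase(parent1); h2 <- phase(parent2)
  gamete <- function(hap) meiosis_gamete(hap, scaffold, recomb)

  with_seed(seed, {
    f1a <- cbind(gamete(h1), gamete(h2))
    f1b <- cbind(gamete(h1), gamete(h2))
    geno <- matrix(0L, m, n_f2)
    for (i in seq_len(n_f2))
      geno[, i] <- rowSums(cbind(gamete(f1a), gamete(f1b)))
    effect_of <- function(d, eff, mode)
      switch(mode, additive = eff * d,
             dominant = eff * (d > 0),
             recessive = eff * (d == 4))
    y <- rep(qtl$baseline, n_f2) + rnorm(n_f2, 0, qtl$residual_sd)
    for (q in seq_along(qtl$markers))
      y <- y + effect_of(geno[qtl$markers[q], ], qtl$effects[q],
                         qtl$modes[q])
    cens <- y > qtl$censor_threshold
    y[cens] <- qtl$censor_threshold
    if (missing_rate > 0)
      geno[runif(length(geno)) < missing_rate] <- NA_integer_
    out <- structure(list(
      markers = tibble::tibble(marker = sprintf("m%04d", seq_len(m)),
                               scaffold = scaffold,
                               position = seq_len(m) * 1000L),
      geno = geno,
      phenotype = tibble::tibble(individual = sprintf("F2_%03d",
                                                      seq_len(n_f2)),
                                 days_to_bolting = y,
                                 censored = cens)),
      class = "f2_panel")
    attr(out, "qtl") <- qtl
    out
  })
}

# One meiosis under bivalent pairing: homologs pair at random into two
# bivalents; the gamete takes one (recombining) strand from each.
meiosis_gamete <- function(hap, scaffold, recomb) {
  m <- nrow(hap)
  new_scaf <- c(TRUE, scaffold[-1] != scaffold[-m])
  if (m == 1L) new_scaf <- TRUE
  seg <- cumsum(new_scaf)
  perm <- sample.int(4)
  strands <- matrix(0L, m, 2)
  for (b in 1:2) {
    pair <- perm[c(2 * b - 1, 2 * b)]
    sw <- runif(m) < recomb
    sw[new_scaf] <- FALSE
    toggles <- stats::ave(as.integer(sw), seg, FUN = cumsum)
    start <- sample(0:1, max(seg), replace = TRUE)[seg]
    state <- (start + toggles) %% 2
    chr <- pair[state + 1L]
    strands[, b] <- hap[cbind(seq_len(m), chr)]
  }
  strands
}

#' Draw tetraploid gametes from a parental dosage vector
#'
#' Exposes the meiosis model used by [simulate_f2()]: bivalent pairing,
#' no double reduction, recombination fraction `recomb` between adjacent
#' markers within a scaffold. Returns gamete dosage vectors (each gamete
#' carries two of the four homologs).
#'
#' @param parent Integer dosage vector (0..4).
#' @param n_gametes Number of gametes to draw.
#' @param scaffold Marker scaffold assignment (default: one scaffold).
#' @param recomb Recombination fraction between adjacent markers.
#' @param seed Integer RNG seed.
#' @return Integer matrix, markers x gametes, entries 0..2.
#' @export
tetra_gametes <- function(parent, n_gametes, scaffold = NULL,
                          recomb = 0.01, seed = 1L) {
  m <- length(parent)
  scaffold <- scaffold %||% rep("scaffold_1", m)
  hap <- outer(parent, 1:4, function(dd, h) as.integer(h <= dd))
  with_seed(seed, {
    vapply(seq_len(n_gametes), function(i)
      rowSums(meiosis_gamete(hap, scaffold, recomb)),
      numeric(m)) |> matrix(nrow = m)
  })
}

#' @export
print.f2_panel <- function(x, ...) {
  cat(sprintf("<f2_panel> %d markers x %d individuals; %d censored\n",
              nrow(x$geno), ncol(x$geno), sum(x$phenotype$censored)))
  invisible(x)
}
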