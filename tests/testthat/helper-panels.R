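# Small deterministic panels used across tests.

# Build a geno_panel from a list of per-population dosage matrices
# (sites x individuals); the outgroup defaults to fixed ancestral.
toy_panel <- function(geno_by_pop, ploidy_by_pop = NULL,
                      outgroup = "O", n_outgroup = 4L) {
  pops <- names(geno_by_pop)
  n_sites <- nrow(geno_by_pop[[1]])
  if (is.null(ploidy_by_pop))
    ploidy_by_pop <- setNames(rep(4L, length(pops)), pops)
  if (!outgroup %in% pops) {
    geno_by_pop[[outgroup]] <- matrix(0L, n_sites, n_outgroup)
    ploidy_by_pop[outgroup] <- 2L
    pops <- c(pops, outgroup)
  }
  geno <- do.call(cbind, geno_by_pop[pops])
  samples <- dplyr::bind_rows(lapply(pops, function(p)
    tibble::tibble(
      sample = sprintf("%s_%d", p, seq_len(ncol(geno_by_pop[[p]]))),
      population = p, ploidy = as.integer(ploidy_by_pop[[p]]))))
  sites <- tibble::tibble(scaffold = "scaffold_1",
                          position = seq_len(n_sites) * 100L,
                          ref = "A", alt = "T")
  geno_panel(sites, geno, samples)
}

# Random small dosage matrix with every site polymorphic allowed.
rand_dosage <- function(n_sites, n_ind, ploidy = 4L) {
  matrix(sample(0:ploidy, n_sites * n_ind, replace = TRUE),
         n_sites, n_ind)
}

toy_freqs <- function(panel, ...) {
  estimate_frequencies(panel, outgroup = "O", min_individuals = 1L, ...)
}
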