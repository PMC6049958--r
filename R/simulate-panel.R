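#' Population model for panel simulation
#'
#' Describes a star (optionally two-level) drift model for multi-population
#' biallelic SNP panels. Each site draws an ancestral frequency `p0` from
#' the ancestral law; each population then draws its frequency from a
#' Balding-Nichols beta law `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with that
#' population's drift parameter `F`, and individual dosages are binomial
#' with `n = ploidy`. When a `clade` column is present, a clade-level
#' frequency is drawn first (with `clade_fst`) and populations drift from
#' it -- this makes populations of a clade (e.g. two railway demes)
#' correlated, as sister populations are.
#'
#' The `"neutral"` ancestral law instead draws, independently per
#' population, a derived chromosome count `i` with probability
#' proportional to `1/i` -- the standard neutral site-frequency spectrum --
#' and places the `i` derived alleles on random chromosomes. It is the
#' reference condition under which Tajima's D is centred at zero.
#'
#' @param populations Tibble with columns `population`, `n` (individuals),
#'   `ploidy`, `fst`, and optionally `clade`.
#' @param n_sites Number of SNP sites.
#' @param ancestral One of `"uniform"`, `"beta"`, `"neutral"`.
#' @param beta_shape Length-2 shape parameters when `ancestral = "beta"`.
#' @param clade_fst Named vector of clade-level drift parameters (required
#'   when `populations$clade` exists).
#' @param n_scaffolds Sites are split evenly over this many scaffolds.
#' @param bp_spacing Base pairs between consecutive sites.
#' @param missing_rate Probability a genotype is missing.
#' @return A list with class `pop_model`.
#' @export
pop_model <- function(populations = default_populations(),
                      n_sites = 10000L,
                      ancestral = c("uniform", "beta", "neutral"),
                      beta_shape = c(0.5, 0.5),
                      clade_fst = NULL,
                      n_scaffolds = 1L,
                      bp_spacing = 100L,
                      missing_rate = 0) {
  populations <- tibble::as_tibble(populations)
  abort_if(!all(c("population", "n", "ploidy", "fst") %in%
                  names(populations)),
           "`populations` needs population, n, ploidy, fst")
  abort_if(any(populations$fst < 0 | populations$fst >= 1),
           "fst must lie in [0, 1)")
  abort_if(any(populations$n < 1), "each population needs individuals")
  check_count(n_sites)
  if ("clade" %in% names(populations)) {
    abort_if(is.null(clade_fst) ||
               !all(populations$clade %in% names(clade_fst)),
             "`clade_fst` must name every clade")
  }
  structure(list(populations = populations,
                 n_sites = as.integer(n_sites),
                 ancestral = match.arg(ancestral),
                 beta_shape = beta_shape,
                 clade_fst = clade_fst,
                 n_scaffolds = as.integer(n_scaffolds),
                 bp_spacing = as.integer(bp_spacing),
                 missing_rate = missing_rate),
            class = "pop_model")
}

#' Default quartet design: background, focal, donor, diploid outgroup
#'
#' Twenty tetraploid individuals per ingroup population with moderate
#' drift (F = 0.25, the differentiation level of separated outcrossing
#' demes), and a 12-individual diploid outgroup with stronger divergence
#' (F = 0.5).
#'
#' @return A populations tibble for [pop_model()].
#' @export
default_populations <- function() {
  tibble::tibble(
    population = c("P1", "P2", "P3", "O"),
    n = c(20L, 20L, 20L, 12L),
    ploidy = c(4L, 4L, 4L, 2L),
    fst = c(0.25, 0.25, 0.25, 0.5))
}

balding_nichols <- function(p0, fst) {
  p <- p0
  drift <- fst > 1e-12 & p0 > 0 & p0 < 1
  if (any(drift)) {
    f <- if (length(fst) == 1L) rep(fst, length(p0)) else fst
    a <- p0[drift] * (1 - f[drift]) / f[drift]
    b <- (1 - p0[drift]) * (1 - f[drift]) / f[drift]
    p[drift] <- rbeta(sum(drift), a, b)
  }
  p
}

#' Simulate a multi-population genotype panel with known truth
#'
#' @param model A [pop_model()].
#' @param seed Integer RNG seed; the same (model, seed) pair always yields
#'   the same panel.
#' @return A [geno_panel()] with attributes `truth` (sites x populations
#'   matrix of true derived... strictly ALT-allele frequencies),
#'   `p_ancestral`, and `clade_freq` (when clades are modelled).
#' @export
simulate_panel <- function(model, seed = 1L) {
  stopifnot(inherits(model, "pop_model"))
  pops <- model$populations
  n_sites <- model$n_sites
  abort_if(n_sites < 1 || nrow(pops) < 1, "need sites and populations")
  with_seed(seed, {
    if (model$ancestral == "neutral") {
      return(simulate_panel_neutral(model))
    }
    p0 <- switch(model$ancestral,
                 uniform = runif(n_sites),
                 beta = rbeta(n_sites, model$beta_shape[1],
                              model$beta_shape[2]))
    clade_freq <- NULL
    if ("clade" %in% names(pops)) {
      clades <- unique(pops$clade)
      clade_freq <- vapply(clades, function(cl)
        balding_nichols(p0, model$clade_fst[[cl]]), numeric(n_sites))
      colnames(clade_freq) <- clades
    }
    truth <- matrix(NA_real_, n_sites, nrow(pops),
                    dimnames = list(NULL, pops$population))
    geno <- NULL
    samples <- list()
    for (k in seq_len(nrow(pops))) {
      base <- if (!is.null(clade_freq)) clade_freq[, pops$clade[k]] else p0
      pk <- balding_nichols(base, pops$fst[k])
      truth[, k] <- pk
      g <- matrix(rbinom(n_sites * pops$n[k], pops$ploidy[k],
                         rep(pk, pops$n[k])), n_sites, pops$n[k])
      geno <- cbind(geno, g)
      samples[[k]] <- tibble::tibble(
        sample = sprintf("%s_%02d", pops$population[k],
                         seq_len(pops$n[k])),
        population = pops$population[k],
        ploidy = pops$ploidy[k])
    }
    if (model$missing_rate > 0)
      geno[runif(length(geno)) < model$missing_rate] <- NA_integer_
    panel <- geno_panel(make_site_table(model), geno,
                        dplyr::bind_rows(samples))
    attr(panel, "truth") <- truth
    attr(panel, "p_ancestral") <- p0
    attr(panel, "clade_freq") <- clade_freq
    panel
  })
}

simulate_panel_neutral <- function(model) {
  pops <- model$populations
  n_sites <- model$n_sites
  truth <- matrix(NA_real_, n_sites, nrow(pops),
                  dimnames = list(NULL, pops$population))
  geno <- NULL
  samples <- list()
  for (k in seq_len(nrow(pops))) {
    n_chr <- pops$n[k] * pops$ploidy[k]
    w <- 1 / seq_len(n_chr - 1)
    i <- sample.int(n_chr - 1, n_sites, replace = TRUE, prob = w)
    truth[, k] <- i / n_chr
    # place i derived alleles on random chromosomes, then fold to dosage
    g <- vapply(i, function(cnt) {
      chr <- integer(n_chr)
      chr[sample.int(n_chr, cnt)] <- 1L
      colSums(matrix(chr, nrow = pops$ploidy[k]))
    }, numeric(pops$n[k]))
    geno <- cbind(geno, t(matrix(as.integer(g), nrow = pops$n[k])))
    samples[[k]] <- tibble::tibble(
      sample = sprintf("%s_%02d", pops$population[k], seq_len(pops$n[k])),
      population = pops$population[k],
      ploidy = pops$ploidy[k])
  }
  panel <- geno_panel(make_site_table(model), geno,
                      dplyr::bind_rows(samples))
  attr(panel, "truth") <- truth
  panel
}

make_site_table <- function(model) {
  n_sites <- model$n_sites
  per <- ceiling(n_sites / model$n_scaffolds)
  scaf_idx <- rep(seq_len(model$n_scaffolds), each = per)[seq_len(n_sites)]
  pos <- sequence(tabulate(scaf_idx)) * model$bp_spacing
  tibble::tibble(scaffold = sprintf("scaffold_%d", scaf_idx),
                 position = as.integer(pos), ref = "A", alt = "T")
}

#' Plant introgression tracts into a focal population
#'
#' For each chromosome of every individual of the `target` population,
#' contiguous blocks of `tract_length` sites are independently replaced
#' with probability `alpha`; replaced alleles are redrawn as Bernoulli
#' draws from the donor frequency track. Allele copies at unreplaced sites
#' are untouched (dosages are decomposed onto chromosomes at random, the
#' masked cells redrawn, and the dosage re-summed). `force_sites` marks
#' sites replaced on every target chromosome regardless of `alpha` --
#' used to plant fully introgressed genes in an otherwise clean
#' background.
#'
#' @param panel A panel from [simulate_panel()] (its `truth` attribute
#'   supplies frequency tracks).
#' @param target Population receiving gene flow.
#' @param donor Population whose truth track alleles are drawn from.
#' @param alpha Genome-wide introgressed fraction in `[0, 1]`.
#' @param tract_length Tract size in sites.
#' @param seed Integer RNG seed.
#' @param donor_track Optional numeric vector of per-site donor
#'   frequencies overriding `donor` (e.g. a clade-level track).
#' @param force_sites Integer site indices fully replaced in all target
#'   chromosomes.
#' @return The modified `geno_panel`; attributes `introgression_mask`
#'   (sites x target chromosomes logical) and `realized_alpha` record the
#'   truth.
#' @export
apply_introgression <- function(panel, target = "P2", donor = "P3",
                                alpha = 0.1, tract_length = 1000L,
                                seed = 1L, donor_track = NULL,
                                force_sites = integer(0)) {
  stopifnot(inherits(panel, "geno_panel"))
  abort_if(alpha < 0 || alpha > 1, "`alpha` must lie in [0, 1]")
  truth <- attr(panel, "truth")
  if (is.null(donor_track)) {
    abort_if(is.null(truth) || !donor %in% colnames(truth),
             "donor frequency track unavailable")
    donor_track <- truth[, donor]
  }
  cols <- which(panel$samples$population == target)
  abort_if(length(cols) == 0, sprintf("no samples in target '%s'", target))
  pl <- unique(panel$samples$ploidy[cols])
  abort_if(length(pl) != 1, "target must have uniform ploidy")
  n_sites <- nrow(panel$sites)
  if (alpha == 0 && !length(force_sites)) {
    attr(panel, "introgression_mask") <-
      matrix(FALSE, n_sites, length(cols) * pl)
    attr(panel, "realized_alpha") <- 0
    return(panel)
  }
  block <- make_blocks(panel$sites$scaffold, tract_length)
  n_block <- max(block)
  with_seed(seed, {
    mask_all <- matrix(FALSE, n_sites, length(cols) * pl)
    for (idx in seq_along(cols)) {
      j <- cols[idx]
      d <- panel$geno[, j]
      # random dosage decomposition onto `pl` chromosome copies
      u <- matrix(runif(n_sites * pl), n_sites, pl)
      rk <- matrix(0L, n_sites, pl)
      for (c1 in seq_len(pl))
        rk[, c1] <- 1L + rowSums(u < u[, c1])
      carrier <- rk <= ifelse(is.na(d), 0L, d)
      for (c1 in seq_len(pl)) {
        chosen <- runif(n_block) < alpha
        m <- chosen[block]
        if (length(force_sites)) m[force_sites] <- TRUE
        if (any(m))
          carrier[m, c1] <- runif(sum(m)) < donor_track[m]
        mask_all[, (idx - 1L) * pl + c1] <- m
      }
      new_d <- rowSums(carrier)
      new_d[is.na(d)] <- NA_integer_
      panel$geno[, j] <- as.integer(new_d)
    }
    attr(panel, "introgression_mask") <- mask_all
    attr(panel, "realized_alpha") <- mean(mask_all)
    panel
  })
}

# contiguous blocks of `len` sites, never spanning scaffolds
make_blocks <- function(scaffold, len) {
  r <- rle(scaffold)
  out <- integer(0)
  base <- 0L
  for (k in seq_along(r$lengths)) {
    b <- (seq_len(r$lengths[k]) - 1L) %/% len + 1L
    out <- c(out, b + base)
    base <- base + max(b)
  }
  out
}
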