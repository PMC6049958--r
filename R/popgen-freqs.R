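#' Estimate polarized per-population allele frequencies
#'
#' Computes, per site and population, the frequency of the derived allele,
#' polarized against an outgroup panel: the outgroup consensus (major)
#' allele is taken as ancestral. Sites where the outgroup is missing, or
#' polymorphic with minor-allele frequency above `max_outgroup_minor`, are
#' flagged unpolarizable. Populations with fewer than `min_individuals`
#' genotyped individuals at a site get a missing frequency there.
#'
#' @param panel A [geno_panel()] containing ingroup populations and the
#'   outgroup samples.
#' @param outgroup Population label of the outgroup panel. Its records
#'   contribute only allele polarity and its own derived frequency (used
#'   by the ABBA-BABA machinery); it never enters within-population
#'   statistics.
#' @param min_individuals Minimum genotyped individuals per population and
#'   site (default 5).
#' @param max_outgroup_minor Outgroup minor-allele frequency above which a
#'   site is unpolarizable (default 0.2).
#' @return A tibble (one row per site x population, outgroup included)
#'   with columns `site`, `scaffold`, `position`, `population`, `p`
#'   (derived-allele frequency), `n_chr`, `provenance`
#'   (`"genotype"`/`"missing"`), `derived` (`"alt"`/`"ref"`/`NA`) and
#'   `polarizable`.
#' @export
estimate_frequencies <- function(panel, outgroup = "O",
                                 min_individuals = 5L,
                                 max_outgroup_minor = 0.2) {
  stopifnot(inherits(panel, "geno_panel"))
  pops <- unique(panel$samples$population)
  abort_if(!outgroup %in% pops,
           sprintf("outgroup population '%s' absent from panel", outgroup))
  n_sites <- nrow(panel$sites)

  alt_freq <- function(popname) {
    cols <- which(panel$samples$population == popname)
    g <- panel$geno[, cols, drop = FALSE]
    pl <- panel$samples$ploidy[cols]
    n_ind <- rowSums(!is.na(g))
    n_chr <- (!is.na(g)) %*% pl
    p <- rowSums(g, na.rm = TRUE) / n_chr
    list(p = as.numeric(p), n_chr = as.numeric(n_chr), n_ind = n_ind)
  }

  og <- alt_freq(outgroup)
  polarizable <- og$n_ind > 0 &
    (og$p <= max_outgroup_minor | og$p >= 1 - max_outgroup_minor)
  derived <- ifelse(!polarizable, NA_character_,
                    ifelse(og$p <= max_outgroup_minor, "alt", "ref"))

  out <- lapply(pops, function(popname) {
    fr <- alt_freq(popname)
    min_n <- if (popname == outgroup) 1L else min_individuals
    ok <- fr$n_ind >= min_n & polarizable
    p <- ifelse(ok, ifelse(derived == "alt", fr$p, 1 - fr$p), NA_real_)
    tibble::tibble(
      site = seq_len(n_sites),
      scaffold = panel$sites$scaffold,
      position = panel$sites$position,
      population = popname,
      p = p,
      n_chr = ifelse(ok, fr$n_chr, NA_real_),
      provenance = ifelse(ok, "genotype", "missing"),
      derived = derived,
      polarizable = polarizable)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$site, match(.data$population, pops))
}

#' Fill missing frequencies from pooled read counts
#'
#' For sites missing in the genotype-based panel, the derived-allele
#' frequency is inferred directly from pooled population read counts
#' (reads should already be filtered for mapping quality and depth
#' upstream): `ALT reads / total reads`, flipped when the derived allele
#' is the reference. Entries stay missing when total reads are zero.
#'
#' @param freqs Frequency tibble from [estimate_frequencies()].
#' @param read_counts Tibble with `site`, `population`, `ref_reads`,
#'   `alt_reads` (pooled over the population's individuals).
#' @return `freqs` with fallback entries filled and `provenance` set to
#'   `"read_count"`.
#' @export
read_count_fallback <- function(freqs, read_counts) {
  rc <- tibble::as_tibble(read_counts)
  abort_if(!all(c("site", "population", "ref_reads", "alt_reads") %in%
                  names(rc)),
           "read_counts needs site, population, ref_reads, alt_reads")
  freqs |>
    dplyr::left_join(rc, by = c("site", "population")) |>
    dplyr::mutate(
      total = .data$ref_reads + .data$alt_reads,
      use = .data$provenance == "missing" & .data$polarizable &
        !is.na(.data$total) & .data$total > 0,
      p_rc = dplyr::if_else(.data$derived == "alt",
                            .data$alt_reads / .data$total,
                            .data$ref_reads / .data$total),
      p = dplyr::if_else(.data$use, .data$p_rc, .data$p),
      provenance = dplyr::if_else(.data$use, "read_count",
                                  .data$provenance)) |>
    dplyr::select(-"ref_reads", -"alt_reads", -"total", -"use", -"p_rc")
}

#' Spread a frequency table to a site x population matrix
#'
#' @param freqs Frequency tibble from [estimate_frequencies()].
#' @param populations Populations to keep (default: all).
#' @return List with `p` (matrix), `n_chr` (matrix), and the per-site
#'   `sites` tibble.
#' @export
freqs_matrix <- function(freqs, populations = NULL) {
  populations <- as.character(populations %||% unique(freqs$population))
  sub <- dplyr::filter(freqs, .data$population %in% populations)
  wide_p <- tidyr::pivot_wider(sub[c("site", "population", "p")],
                               names_from = "population",
                               values_from = "p")
  wide_n <- tidyr::pivot_wider(sub[c("site", "population", "n_chr")],
                               names_from = "population",
                               values_from = "n_chr")
  sites <- dplyr::distinct(sub[c("site", "scaffold", "position",
                                 "polarizable")])
  list(p = as.matrix(wide_p[populations]),
       n_chr = as.matrix(wide_n[populations]),
       sites = sites[match(wide_p$site, sites$site), ])
}
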