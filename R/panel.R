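#' Genotype panel container
#'
#' A lightweight container for a biallelic SNP panel: a site table, an
#' integer dosage matrix (sites x samples, counting copies of the ALT
#' allele, `NA` for missing), and a sample table giving each sample's
#' population and ploidy. Tetraploid samples carry dosages 0..4, a diploid
#' outgroup 0..2.
#'
#' @param sites Tibble with columns `scaffold`, `position`, `ref`, `alt`.
#' @param geno Integer matrix, `nrow(sites)` x `nrow(samples)`.
#' @param samples Tibble with columns `sample`, `population`, `ploidy`.
#' @return An object of class `geno_panel`.
#' @export
geno_panel <- function(sites, geno, samples) {
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  abort_if(!all(c("scaffold", "position") %in% names(sites)),
           "`sites` needs columns scaffold, position")
  abort_if(!all(c("sample", "population", "ploidy") %in% names(samples)),
           "`samples` needs columns sample, population, ploidy")
  geno <- as.matrix(geno)
  abort_if(nrow(geno) != nrow(sites) || ncol(geno) != nrow(samples),
           "`geno` must be sites x samples")
  pl <- rep(samples$ploidy, each = nrow(geno))
  bad <- !is.na(geno) & (geno < 0 | geno > pl)
  abort_if(any(bad), "dosages must lie in 0..ploidy or be NA")
  colnames(geno) <- samples$sample
  structure(list(sites = sites, geno = geno, samples = samples),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("<geno_panel> %d sites x %d samples (%d populations)\n",
              nrow(x$sites), nrow(x$samples),
              dplyr::n_distinct(x$samples$population)))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_panel <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Long-format view of a genotype panel
#'
#' @param x A [geno_panel()].
#' @param ... Unused.
#' @return A tibble with one row per site x sample: scaffold, position,
#'   sample, population, ploidy, dosage.
#' @export
tidy.geno_panel <- function(x, ...) {
  dplyr::cross_join(
    dplyr::mutate(x$sites[c("scaffold", "position")],
                  .site = dplyr::row_number()),
    x$samples
  ) |>
    dplyr::mutate(dosage = as.vector(x$geno[cbind(
      .data$.site, match(.data$sample, x$samples$sample))])) |>
    dplyr::select(-".site")
}

#' Subset a genotype panel by site index and/or samples
#'
#' @param panel A [geno_panel()].
#' @param sites Integer site indices (default all).
#' @param samples Character sample names or logical/integer index
#'   (default all).
#' @return A `geno_panel`.
#' @export
panel_subset <- function(panel, sites = NULL, samples = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  si <- sites %||% seq_len(nrow(panel$sites))
  sa <- samples %||% seq_len(nrow(panel$samples))
  if (is.character(sa)) sa <- match(sa, panel$samples$sample)
  geno_panel(panel$sites[si, , drop = FALSE],
             panel$geno[si, sa, drop = FALSE],
             panel$samples[sa, , drop = FALSE])
}
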