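#' Build fixed-SNP-count windows
#'
#' Partitions usable sites, in (scaffold, position) order, into
#' consecutive blocks of exactly `window_size_snps` SNPs per scaffold;
#' windows never span scaffolds. A trailing remainder per scaffold is
#' emitted flagged `short`. With `stride < window_size_snps` windows
#' slide; the default is disjoint windows (independent, so empirical
#' quantiles and jackknife blocks are not double-counted).
#'
#' @param sites Tibble with `site`, `scaffold`, `position` (one row per
#'   usable SNP, sorted by scaffold and position).
#' @param window_size_snps SNPs per window.
#' @param stride Usable SNPs between window starts (default
#'   `window_size_snps`).
#' @return Tibble of windows: `window`, `scaffold`, `first_site`,
#'   `last_site` (values of `sites$site`), `start_bp`, `end_bp`,
#'   `n_snps`, `short`, plus a `site_index` list-column of row positions
#'   into `sites`.
#' @export
make_windows <- function(sites, window_size_snps = 25L,
                         stride = window_size_snps) {
  check_count(window_size_snps); check_count(stride)
  sites <- dplyr::arrange(tibble::as_tibble(sites), .data$scaffold,
                          .data$position)
  out <- list()
  wid <- 0L
  for (scaf in unique(sites$scaffold)) {
    rows <- which(sites$scaffold == scaf)
    starts <- seq(1L, length(rows), by = stride)
    for (s in starts) {
      e <- min(s + window_size_snps - 1L, length(rows))
      if (s > 1L && e < s + window_size_snps - 1L &&
          stride < window_size_snps) next  # sliding: skip ragged tail
      wid <- wid + 1L
      ix <- rows[s:e]
      out[[wid]] <- tibble::tibble(
        window = wid, scaffold = scaf,
        first_site = sites$site[ix[1]],
        last_site = sites$site[ix[length(ix)]],
        start_bp = sites$position[ix[1]],
        end_bp = sites$position[ix[length(ix)]],
        n_snps = length(ix),
        short = length(ix) < window_size_snps,
        site_index = list(ix))
    }
  }
  if (!length(out)) return(tibble::tibble())
  dplyr::bind_rows(out)
}

#' Windowed G_ST / Tajima's D / Fay and Wu's H scan
#'
#' Computes per-window statistics over a shared window grid. Usable SNPs
#' are polarizable sites with a non-missing frequency in every population
#' involved, so that the three statistics are comparable window by
#' window.
#'
#' @param freqs Frequency tibble from [estimate_frequencies()].
#' @param populations Populations scanned (default: all non-outgroup
#'   populations present, i.e. every population in `freqs`; pass the
#'   subset you need).
#' @param stats Any of `"gst"`, `"tajd"`, `"fwh"`.
#' @param gst_groups Optional list of two character vectors; when given,
#'   G_ST is computed between the two group mean frequency profiles
#'   instead of across all populations.
#' @param window_size_snps,stride Passed to [make_windows()].
#' @return A tidy tibble: `window`, `scaffold`, `start_bp`, `end_bp`,
#'   `n_snps`, `short`, `statistic` (`GST`/`TajD`/`FWH`), `population`
#'   (`NA` for G_ST), `value`.
#' @export
window_stats <- function(freqs, populations = NULL,
                         stats = c("gst", "tajd", "fwh"),
                         gst_groups = NULL,
                         window_size_snps = 25L,
                         stride = window_size_snps) {
  stats <- match.arg(stats, several.ok = TRUE)
  populations <- populations %||% unique(freqs$population)
  fm <- freqs_matrix(freqs, populations)
  usable <- fm$sites$polarizable & rowSums(is.na(fm$p)) == 0
  p <- fm$p[usable, , drop = FALSE]
  n_chr <- fm$n_chr[usable, , drop = FALSE]
  sites <- fm$sites[usable, c("site", "scaffold", "position")]
  windows <- make_windows(sites, window_size_snps, stride)
  if (!nrow(windows)) return(tibble::tibble())

  res <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    ix <- windows$site_index[[w]]
    meta <- windows[w, c("window", "scaffold", "start_bp", "end_bp",
                         "n_snps", "short")]
    rows <- list()
    if ("gst" %in% stats) {
      pm <- if (is.null(gst_groups)) p[ix, , drop = FALSE] else
        cbind(rowMeans(p[ix, gst_groups[[1]], drop = FALSE]),
              rowMeans(p[ix, gst_groups[[2]], drop = FALSE]))
      rows$gst <- dplyr::mutate(meta, statistic = "GST",
                                population = NA_character_,
                                value = gst_window(pm))
    }
    for (pop in populations) {
      if ("tajd" %in% stats)
        rows[[paste0("tajd_", pop)]] <-
          dplyr::mutate(meta, statistic = "TajD", population = pop,
                        value = tajimas_d_window(p[ix, pop],
                                                 n_chr[ix, pop]))
      if ("fwh" %in% stats)
        rows[[paste0("fwh_", pop)]] <-
          dplyr::mutate(meta, statistic = "FWH", population = pop,
                        value = fay_wu_h_window(p[ix, pop],
                                                n_chr[ix, pop]))
    }
    dplyr::bind_rows(rows)
  })
  dplyr::arrange(res, .data$window, .data$statistic, .data$population)
}

#' Tetraploid Hardy-Weinberg genotype probabilities
#'
#' Genotype-class probabilities from the multinomial expansion of
#' `(sum p_i)^4` for an autotetraploid in Hardy-Weinberg equilibrium.
#' Three query types: probability of being homozygous for one allele
#' (`p^4`); of carrying exactly `k` copies of it
#' (`choose(4,k) p^k (1-p)^(4-k)`); or of carrying zero copies of every
#' allele in a set (`(1 - sum p_set)^4`).
#'
#' @param p Named numeric vector of allele frequencies summing to 1 (a
#'   single unnamed frequency is treated as a biallelic `c(a = p,
#'   other = 1-p)`).
#' @param query `"homozygous"`, `"exact"`, or `"zero_of_set"`.
#' @param allele Allele name for `homozygous`/`exact` (default: first).
#' @param k Copy number for `query = "exact"`.
#' @param alleles Allele names for `query = "zero_of_set"`.
#' @param tol Tolerance on `sum(p) == 1`.
#' @return A probability.
#' @examples
#' hwe_genotype_prob(0.8, "homozygous")        # 0.4096
#' hwe_genotype_prob(0.3, "zero_of_set")       # 0.7^4 = 0.2401
#' hwe_genotype_prob(0.2, "exact", k = 2)      # 6 * .04 * .64
#' @export
hwe_genotype_prob <- function(p, query = c("homozygous", "exact",
                                           "zero_of_set"),
                              allele = NULL, k = NULL, alleles = NULL,
                              tol = 1e-8) {
  query <- match.arg(query)
  if (length(p) == 1L && is.null(names(p))) p <- c(a = p, other = 1 - p)
  check_prob(p)
  abort_if(abs(sum(p) - 1) > tol, "allele frequencies must sum to 1")
  pick <- function(nm) {
    nm <- nm %||% names(p)[1]
    abort_if(!all(nm %in% names(p)), "unknown allele name")
    nm
  }
  switch(query,
    homozygous = unname(p[pick(allele)]^4),
    exact = {
      abort_if(is.null(k) || !k %in% 0:4, "`k` must be in 0..4")
      pa <- unname(p[pick(allele)])
      choose(4, k) * pa^k * (1 - pa)^(4 - k)
    },
    zero_of_set = {
      nm <- pick(alleles)
      (1 - sum(p[nm]))^4
    })
}
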