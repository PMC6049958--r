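utils::globalVariables(c("scaffold", "position", "start", "end",
                         "start_bp", "end_bp"))

#' Gene-wise aggregation of window statistics
#'
#' Per gene, the directed extreme of all windows whose bp span (first to
#' last SNP, inclusive) intersects the gene interval: selection scans
#' keep the most extreme mark touching a gene. Direction conventions:
#' G_ST is aggregated by `max`, Fay & Wu's H and Tajima's D by `min`
#' (their selection-relevant tails).
#'
#' @param windows Window tibble from [window_stats()] (or any tibble
#'   with `scaffold`, `start_bp`, `end_bp`, `value`), already filtered
#'   to one statistic (and population).
#' @param genes Gene annotations from [read_gff_genes()].
#' @param direction `"max"` or `"min"`.
#' @return Tibble: `gene_id`, `value`, `n_windows`. Genes with no
#'   overlapping window are omitted.
#' @export
genewise_aggregate <- function(windows, genes, direction = c("max",
                                                             "min")) {
  direction <- match.arg(direction)
  fn <- if (direction == "max") max else min
  genes <- tibble::as_tibble(genes)
  hits <- dplyr::inner_join(
    tibble::as_tibble(windows), genes,
    by = dplyr::join_by(scaffold, start_bp <= end, end_bp >= start)) |>
    dplyr::filter(!is.na(.data$value))
  if (!nrow(hits))
    return(tibble::tibble(gene_id = character(), value = numeric(),
                          n_windows = integer()))
  hits |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(value = fn(.data$value),
                     n_windows = dplyr::n())
}

#' Conservative gene value across comparisons
#'
#' Per gene, the least extreme value across several comparisons (for a
#' `max`-directed statistic like G_ST the minimum across comparisons;
#' for a `min`-directed one the maximum): a gene scores only as high as
#' its weakest comparison. Genes missing from any comparison are
#' omitted.
#'
#' @param gene_tables Named list of gene tibbles from
#'   [genewise_aggregate()], one per comparison.
#' @param direction The aggregation direction of the statistic
#'   (`"max"` for G_ST, `"min"` for H and Tajima's D).
#' @return Tibble: `gene_id`, `value`, `n_comparisons`.
#' @export
least_extreme_across <- function(gene_tables, direction = c("max",
                                                            "min")) {
  direction <- match.arg(direction)
  fn <- if (direction == "max") min else max  # least extreme
  n_cmp <- length(gene_tables)
  dplyr::bind_rows(gene_tables, .id = "comparison") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(value = fn(.data$value),
                     n_comparisons = dplyr::n()) |>
    dplyr::filter(.data$n_comparisons == n_cmp)
}

#' Empirical outlier cutoff
#'
#' The genome-wide empirical quantile (inverse-ECDF order statistic) on
#' the requested tail; outliers are flagged by strict inequality beyond
#' the cutoff.
#'
#' @param values Numeric vector (>= 100 finite values).
#' @param tail Tail mass, e.g. 0.05.
#' @param side `"upper"` (top tail, e.g. G_ST) or `"lower"` (bottom
#'   tail, e.g. H, Tajima's D).
#' @return The cutoff value.
#' @export
empirical_threshold <- function(values, tail = 0.05,
                                side = c("upper", "lower")) {
  side <- match.arg(side)
  v <- values[is.finite(values)]
  abort_if(length(v) < 100,
           "need at least 100 finite values for an empirical threshold")
  probs <- if (side == "upper") 1 - tail else tail
  unname(quantile(v, probs, type = 1))
}

#' Railway-specific selection candidates
#'
#' Implements the three-way intersection: genes in the top `gst` tail of
#' railway-vs-mountain differentiation whose Fay & Wu's H falls below
#' its genome-wide cutoff in every railway population and in no mountain
#' population; candidates are additionally marked when Tajima's D is
#' below its cutoff in every railway population.
#'
#' @param gene_gst Gene tibble (`gene_id`, `value`) of
#'   railway-vs-mountain G_ST (typically the least-extreme value across
#'   couples).
#' @param gene_h Gene tibble with a `population` column of gene-wise H
#'   per population.
#' @param gene_tajd As `gene_h`, for Tajima's D.
#' @param railway_pops,mountain_pops Population labels of each group.
#' @param quantiles Named list of tail masses (`gst`, `h`, `tajd`),
#'   as in [run_config()].
#' @return Tibble of candidates: `gene_id`, `gst`, `h_railway_outlier`,
#'   `tajd_mark`.
#' @export
railway_selection_candidates <- function(gene_gst, gene_h, gene_tajd,
                                         railway_pops, mountain_pops,
                                         quantiles = list(gst = 0.05,
                                                          h = 0.05,
                                                          tajd = 0.05)) {
  abort_if(!all(c(railway_pops, mountain_pops) %in%
                  unique(gene_h$population)),
           "gene_h must cover all railway and mountain populations")
  gst_cut <- empirical_threshold(gene_gst$value, quantiles$gst, "upper")
  gst_out <- gene_gst$gene_id[gene_gst$value > gst_cut]

  outlier_by_pop <- function(tbl, tail) {
    tbl |>
      dplyr::group_by(.data$population) |>
      dplyr::mutate(cut = empirical_threshold(.data$value, tail,
                                              "lower"),
                    outlier = .data$value < .data$cut) |>
      dplyr::ungroup()
  }
  h <- outlier_by_pop(gene_h, quantiles$h)
  h_status <- h |>
    dplyr::filter(.data$population %in% c(railway_pops, mountain_pops)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      rail_all = all(.data$outlier[.data$population %in% railway_pops]) &&
        sum(.data$population %in% railway_pops) == length(railway_pops),
      mtn_none = !any(.data$outlier[.data$population %in% mountain_pops]))

  cand <- gene_gst |>
    dplyr::filter(.data$gene_id %in% gst_out) |>
    dplyr::inner_join(h_status, by = "gene_id") |>
    dplyr::filter(.data$rail_all, .data$mtn_none)
  if (!nrow(cand))
    return(tibble::tibble(gene_id = character(), gst = numeric(),
                          h_railway_outlier = logical(),
                          tajd_mark = logical()))

  td <- outlier_by_pop(
    dplyr::filter(gene_tajd, .data$population %in% railway_pops),
    quantiles$tajd) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(tajd_mark = all(.data$outlier) &&
                       dplyr::n() == length(railway_pops))

  cand |>
    dplyr::transmute(gene_id = .data$gene_id, gst = .data$value,
                     h_railway_outlier = TRUE) |>
    dplyr::left_join(td, by = "gene_id") |>
    dplyr::mutate(tajd_mark = !is.na(.data$tajd_mark) & .data$tajd_mark)
}

#' Mean derived frequency of a haplotype signature
#'
#' Per population, the arithmetic mean of derived-allele frequencies
#' across the signature sites (e.g. the sites diagnostic of a selected
#' haplotype), together with the number of sites filled by the
#' read-count fallback. Populations with all signature sites missing get
#' `NA`.
#'
#' @param freqs Frequency tibble (after [read_count_fallback()] if
#'   desired).
#' @param signature Tibble with `scaffold`, `position` of signature
#'   sites.
#' @param populations Populations to report (default: all in `freqs`).
#' @return Tibble: `population`, `mean_freq`, `n_sites`, `n_fallback`,
#'   `n_missing`.
#' @export
signature_frequencies <- function(freqs, signature,
                                  populations = NULL) {
  populations <- populations %||% unique(freqs$population)
  sig <- dplyr::semi_join(freqs,
                          tibble::as_tibble(signature),
                          by = c("scaffold", "position")) |>
    dplyr::filter(.data$population %in% populations)
  sig |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      mean_freq = if (all(is.na(.data$p))) NA_real_ else
        mean(.data$p, na.rm = TRUE),
      n_sites = dplyr::n(),
      n_fallback = sum(.data$provenance == "read_count"),
      n_missing = sum(is.na(.data$p))) |>
    dplyr::arrange(match(.data$population, populations))
}

#' Sites strongly differentiated between two population groups
#'
#' Flags sites whose group-mean derived frequencies differ by strictly
#' more than `min_diff`, annotated with the group carrying the derived
#' state.
#'
#' @param freqs Frequency tibble.
#' @param group_a,group_b Population labels of the two groups.
#' @param min_diff Strict frequency-difference threshold (default
#'   0.30).
#' @return Tibble: `site`, `scaffold`, `position`, `mean_a`, `mean_b`,
#'   `diff`, `derived_in` (`"A"`/`"B"`).
#' @export
differentiated_variants <- function(freqs, group_a, group_b,
                                    min_diff = 0.30) {
  grp_mean <- function(pops, nm) {
    freqs |>
      dplyr::filter(.data$population %in% pops, !is.na(.data$p)) |>
      dplyr::group_by(.data$site, .data$scaffold, .data$position) |>
      dplyr::summarise("{nm}" := mean(.data$p), .groups = "drop")
  }
  dplyr::inner_join(grp_mean(group_a, "mean_a"),
                    grp_mean(group_b, "mean_b"),
                    by = c("site", "scaffold", "position")) |>
    dplyr::mutate(diff = .data$mean_a - .data$mean_b,
                  derived_in = dplyr::if_else(.data$diff > 0, "A", "B")) |>
    dplyr::filter(abs(.data$diff) > min_diff) |>
    dplyr::arrange(.data$site)
}
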