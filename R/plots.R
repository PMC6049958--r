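#' Manhattan-style plot of a single-marker scan
#'
#' @param object A `marker_scan` from [single_marker_scan()].
#' @param threshold Optional [permutation_threshold()] result drawn as
#'   horizontal lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.marker_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$position, y = .data$lod,
                                    colour = .data$model)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::facet_grid(. ~ scaffold, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "LOD",
                  colour = "best model") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(
      yintercept = c(threshold$max_lod, threshold$q95),
      linetype = c("solid", "dashed"), colour = "grey30")
  p
}

#' Plot windowed scan statistics along the genome
#'
#' @param windows Tidy window tibble from [window_stats()].
#' @param cutoffs Optional tibble with `statistic`, `population`,
#'   `cutoff` drawn as dashed lines.
#' @return A ggplot faceted by statistic.
#' @export
plot_window_stats <- function(windows, cutoffs = NULL) {
  p <- ggplot2::ggplot(
    dplyr::filter(windows, !is.na(.data$value)),
    ggplot2::aes(x = .data$start_bp, y = .data$value,
                 colour = .data$population)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_grid(statistic ~ scaffold, scales = "free") +
    ggplot2::labs(x = "window start (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs))
    p <- p + ggplot2::geom_hline(
      data = cutoffs, ggplot2::aes(yintercept = .data$cutoff),
      linetype = "dashed", colour = "grey30")
  p
}

#' Sample map of an expression PCA
#'
#' @param object An `expr_pca` from [top_variable_pca()].
#' @param samples Optional tibble with `sample` and a grouping column
#'   `population` used for colour.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2.
#' @export
autoplot.expr_pca <- function(object, samples = NULL, ...) {
  df <- object$coords
  if (!is.null(samples))
    df <- dplyr::left_join(df, tibble::as_tibble(samples),
                           by = "sample")
  aes <- if ("population" %in% names(df))
    ggplot2::aes(.data$PC1, .data$PC2, colour = .data$population) else
      ggplot2::aes(.data$PC1, .data$PC2)
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$variance_explained[1]),
      y = sprintf("PC2 (%.1f%%)", object$variance_explained[2])) +
    ggplot2::theme_minimal()
}

#' Gene-level f_d against the candidate threshold
#'
#' @param gene_fd Tibble from [gene_fd_scan()].
#' @param fhom_table Tibble of genome-wide [f_hom()] rows.
#' @param multiplier Candidate multiplier (default 3).
#' @return A ggplot faceted by quartet.
#' @export
plot_gene_fd <- function(gene_fd, fhom_table = NULL, multiplier = 3) {
  df <- dplyr::mutate(gene_fd,
                      quartet = paste0("(", .data$P1, ",", .data$P2,
                                       ",", .data$P3, ")"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n_informative,
                                        y = .data$f_d)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~quartet) +
    ggplot2::labs(x = "informative SNPs in gene", y = expression(f^d)) +
    ggplot2::theme_minimal()
  if (!is.null(fhom_table)) {
    th <- dplyr::mutate(fhom_table,
                        quartet = paste0("(", .data$P1, ",", .data$P2,
                                         ",", .data$P3, ")"),
                        cut = multiplier * .data$value)
    p <- p + ggplot2::geom_hline(
      data = th, ggplot2::aes(yintercept = .data$cut),
      linetype = "dashed", colour = "red3")
  }
  p
}
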