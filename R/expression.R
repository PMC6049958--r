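#' Median-of-ratios library-size normalization
#'
#' The classical size-factor estimator: per sample, the median across
#' genes (restricted to genes with nonzero counts in every sample) of
#' the ratio of the count to the gene's geometric mean across samples;
#' normalized counts are counts divided by the sample's size factor.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return List with `normalized` (numeric matrix) and `size_factors`
#'   (named vector).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  abort_if(any(counts < 0), "counts must be non-negative")
  all_nonzero <- rowSums(counts == 0) == 0
  abort_if(!any(all_nonzero),
           paste("no gene has nonzero counts in all samples; consider a",
                 "pseudo-reference"))
  log_geo <- rowMeans(log(counts[all_nonzero, , drop = FALSE]))
  sf <- apply(counts[all_nonzero, , drop = FALSE], 2, function(col)
    exp(median(log(col) - log_geo)))
  list(normalized = sweep(counts, 2, sf, `/`), size_factors = sf)
}

#' PCA on the most variable genes
#'
#' Principal components of the samples over the `n_genes` genes with the
#' highest variance of normalized counts, with the percentage of
#' variance each component explains.
#'
#' @param normalized Normalized count matrix (genes x samples).
#' @param n_genes Number of top-variance genes (default 500; capped at
#'   the genes available, with a warning).
#' @return List with class `expr_pca`: `coords` (tibble: sample, PC1,
#'   PC2, ...) and `variance_explained` (percent per component).
#' @export
top_variable_pca <- function(normalized, n_genes = 500L) {
  abort_if(ncol(normalized) < 3, "need at least 3 samples for PCA")
  v <- apply(normalized, 1, var)
  if (n_genes > length(v)) {
    warning("fewer genes than n_genes; using all", call. = FALSE)
    n_genes <- length(v)
  }
  top <- order(v, decreasing = TRUE)[seq_len(n_genes)]
  pc <- prcomp(t(normalized[top, , drop = FALSE]), center = TRUE,
               scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  coords <- tibble::as_tibble(pc$x, .name_repair = "minimal")
  coords <- dplyr::bind_cols(
    tibble::tibble(sample = colnames(normalized)), coords)
  structure(list(coords = coords, variance_explained = ve),
            class = "expr_pca")
}

#' Classify focal-population expression states by Tukey contrasts
#'
#' Per gene, a one-way ANOVA of normalized counts across the three
#' classes (railway RW, mountain MT, focal BGS) followed by Tukey's
#' honest significant difference test (Tukey-Kramer for the unbalanced
#' groups). A gene is differentially expressed (DE) when
#' `p(RW-MT) < de_alpha`; a DE gene is `mountain_like` in the focal
#' population when additionally `p(BGS-RW) < de_alpha` and
#' `p(BGS-MT) > similar_p`, `railway_like` in the mirrored case, and
#' `intermediate` otherwise. Genes with zero within-class variance are
#' skipped.
#'
#' @param normalized Normalized count matrix (genes x samples).
#' @param samples Tibble with `sample` and `class`
#'   (`RW`/`MT`/`BGS`) for every column.
#' @param de_alpha DE significance level (default 0.05).
#' @param similar_p Tukey p-value above which the focal class is deemed
#'   similar to a class (default 0.5; taken verbatim as a p-value
#'   threshold, not an equivalence test).
#' @return Tibble with class `tukey_classification`: `gene_id`,
#'   `p_rw_mt`, `p_bgs_rw`, `p_bgs_mt`, `de`, `class`.
#' @export
tukey_classify <- function(normalized, samples, de_alpha = 0.05,
                           similar_p = 0.5) {
  samples <- tibble::as_tibble(samples)
  abort_if(!all(c("RW", "MT", "BGS") %in% samples$class),
           "need classes RW, MT and BGS")
  cls <- factor(samples$class[match(colnames(normalized),
                                    samples$sample)],
                levels = c("BGS", "MT", "RW"))
  abort_if(anyNA(cls), "every sample column needs a class")
  abort_if(any(table(cls) < 2), "need >= 2 replicates per class")
  gene_ids <- rownames(normalized) %||%
    sprintf("gene%05d", seq_len(nrow(normalized)))

  res <- purrr::map_dfr(seq_len(nrow(normalized)), function(i) {
    y <- normalized[i, ]
    wv <- tapply(y, cls, var)
    if (all(wv == 0, na.rm = TRUE))
      return(tibble::tibble(gene_id = gene_ids[i], p_rw_mt = NA_real_,
                            p_bgs_rw = NA_real_, p_bgs_mt = NA_real_,
                            skipped = TRUE))
    tk <- TukeyHSD(aov(y ~ cls))$cls[, "p adj"]
    tibble::tibble(gene_id = gene_ids[i],
                   p_rw_mt = unname(tk["RW-MT"]),
                   p_bgs_rw = unname(tk["RW-BGS"]),
                   p_bgs_mt = unname(tk["MT-BGS"]),
                   skipped = FALSE)
  })
  n_skip <- sum(res$skipped)
  if (n_skip > 0)
    message("tukey_classify: skipped ", n_skip,
            " gene(s) with zero within-class variance")
  out <- res |>
    dplyr::mutate(
      de = !.data$skipped & .data$p_rw_mt < de_alpha,
      class = dplyr::case_when(
        .data$skipped ~ NA_character_,
        !.data$de ~ "not_de",
        .data$p_bgs_rw < de_alpha & .data$p_bgs_mt > similar_p ~
          "mountain_like",
        .data$p_bgs_rw > similar_p & .data$p_bgs_mt < de_alpha ~
          "railway_like",
        TRUE ~ "intermediate")) |>
    dplyr::select(-"skipped")
  class(out) <- c("tukey_classification", class(out))
  out
}

#' @export
glance.tukey_classification <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_de = sum(x$de, na.rm = TRUE),
    n_mountain_like = sum(x$class == "mountain_like", na.rm = TRUE),
    n_railway_like = sum(x$class == "railway_like", na.rm = TRUE),
    n_intermediate = sum(x$class == "intermediate", na.rm = TRUE))
}

#' Correlation of population-mean expression with flowering time
#'
#' Per gene, the Pearson correlation between per-population mean
#' normalized expression and the populations' mean flowering time, with
#' the focal (admixed) population excluded from the fit. Genes are first
#' filtered to those with a normalized count above `min_count` in at
#' least one sample and, when a [tukey_classify()] result is supplied,
#' to genes differentially expressed between RW and MT at `de_alpha`.
#' The top `top_fraction` by `|r|` are flagged.
#'
#' @param normalized Normalized count matrix (genes x samples).
#' @param samples Tibble with `sample`, `population`.
#' @param flowering Tibble with `population`, `flowering_time` (days).
#' @param exclude Population excluded from the correlation (default
#'   `"BGS"`).
#' @param classification Optional [tukey_classify()] result for the DE
#'   filter.
#' @param de_alpha DE filter level (default 0.05).
#' @param min_count Expression filter (default 10).
#' @param top_fraction Fraction flagged as flowering-correlated
#'   (default 0.01).
#' @return Tibble with class `flowering_scan`: `gene_id`, `r`,
#'   `abs_r`, `top` (logical), sorted by `abs_r` descending.
#' @export
flowering_correlation_scan <- function(normalized, samples, flowering,
                                       exclude = "BGS",
                                       classification = NULL,
                                       de_alpha = 0.05,
                                       min_count = 10,
                                       top_fraction = 0.01) {
  samples <- tibble::as_tibble(samples)
  flowering <- tibble::as_tibble(flowering)
  pops <- setdiff(intersect(unique(samples$population),
                            flowering$population), exclude)
  abort_if(length(pops) < 4,
           "need >= 4 populations (after exclusion) for the correlation")
  gene_ids <- rownames(normalized) %||%
    sprintf("gene%05d", seq_len(nrow(normalized)))

  keep <- apply(normalized, 1, function(y) any(y > min_count))
  if (!is.null(classification)) {
    de_genes <- classification$gene_id[!is.na(classification$de) &
                                         classification$de]
    keep <- keep & gene_ids %in% de_genes
  }
  pop_of <- samples$population[match(colnames(normalized),
                                     samples$sample)]
  means <- vapply(pops, function(pp)
    rowMeans(normalized[, which(pop_of %in% pp), drop = FALSE]),
    numeric(nrow(normalized)))
  ft <- flowering$flowering_time[match(pops, flowering$population)]

  idx <- unname(which(keep))
  r <- vapply(idx, function(i) {
    m <- means[i, ]
    if (sd(m) == 0) return(NA_real_)
    cor(m, ft)
  }, numeric(1))
  out <- tibble::tibble(gene_id = gene_ids[idx], r = r,
                        abs_r = abs(r)) |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::arrange(dplyr::desc(.data$abs_r))
  n_top <- ceiling(top_fraction * nrow(out))
  out$top <- seq_len(nrow(out)) <= n_top
  class(out) <- c("flowering_scan", class(out))
  out
}

#' Two-tailed outlier p-value for an excluded point's residual
#'
#' Fits the major axis (orthogonal / total least squares) line through
#' the included points, measures every residual as signed orthogonal
#' distance to that line, estimates sigma as the root-mean-square of the
#' included residuals about zero, and returns
#' `p = 2 (1 - Phi(|d_excluded| / sigma))` -- how likely the excluded
#' point's offset is under the noise of the trend.
#'
#' @param x,y Coordinates of the included points (e.g. flowering time
#'   and mean expression per population).
#' @param x0,y0 The excluded point.
#' @param residual `"orthogonal"` (default) or `"vertical"`.
#' @return List: `p`, `residual` (the excluded point's), `sigma`,
#'   `slope`, `intercept`.
#' @export
residual_outlier_p <- function(x, y, x0, y0,
                               residual = c("orthogonal", "vertical")) {
  residual <- match.arg(residual)
  abort_if(length(x) < 3, "need >= 3 included points")
  if (residual == "orthogonal") {
    pc <- prcomp(cbind(x, y), center = TRUE, scale. = FALSE)
    dir <- pc$rotation[, 1]
    normal <- c(-dir[2], dir[1])
    ctr <- c(mean(x), mean(y))
    d <- cbind(x - ctr[1], y - ctr[2]) %*% normal
    d0 <- sum((c(x0, y0) - ctr) * normal)
    slope <- dir[2] / dir[1]
    intercept <- ctr[2] - slope * ctr[1]
  } else {
    fit <- lm(y ~ x)
    d <- stats::resid(fit)
    d0 <- y0 - stats::predict(fit, data.frame(x = x0))
    slope <- stats::coef(fit)[2]
    intercept <- stats::coef(fit)[1]
  }
  sigma <- sqrt(mean(d^2))
  scale_xy <- max(1e-300, sd(x), sd(y))
  if (sigma <= 1e-10 * scale_xy) {
    sigma <- 0
    warning("zero residual spread among included points", call. = FALSE)
    p <- if (abs(d0) > 1e-10 * scale_xy) 0 else 1
  } else {
    p <- 2 * (1 - pnorm(abs(d0) / sigma))
  }
  list(p = unname(p), residual = unname(as.numeric(d0)), sigma = sigma,
       slope = unname(slope), intercept = unname(intercept))
}

#' Relative expression from qPCR Ct values with error propagation
#'
#' Efficiency-aware ratio method: relative expression is
#' `(1+E_t)^(-dCt_t) / (1+E_r)^(-dCt_r)`, with `dCt` the mean Ct of the
#' sample minus the mean Ct of the calibrator for the target and the
#' reference gene respectively, and primer efficiencies `E` as
#' fractions. The SD comes from first-order (delta-method) propagation
#' of the technical-replicate Ct variances:
#' `SD = RE * sqrt(ln(1+E_t)^2 Var(dCt_t) + ln(1+E_r)^2 Var(dCt_r))`,
#' each `Var(dCt)` summing the standard errors of the two well-group
#' means.
#'
#' @param ct_target,ct_reference Numeric vectors of technical-replicate
#'   Ct values for the sample's target and reference wells.
#' @param ct_target_cal,ct_reference_cal The calibrator's wells.
#' @param eff_target,eff_reference Primer efficiencies in (0, 1.5].
#' @return List: `relative_expression`, `sd`.
#' @export
qpcr_relative_expression <- function(ct_target, ct_reference,
                                     ct_target_cal, ct_reference_cal,
                                     eff_target = 1,
                                     eff_reference = 1) {
  for (v in list(ct_target, ct_reference, ct_target_cal,
                 ct_reference_cal))
    abort_if(length(v) < 2, "need >= 2 technical replicates per group")
  for (e in c(eff_target, eff_reference))
    abort_if(e <= 0 || e > 1.5, "efficiency must lie in (0, 1.5]")
  dct_t <- mean(ct_target) - mean(ct_target_cal)
  dct_r <- mean(ct_reference) - mean(ct_reference_cal)
  re <- (1 + eff_target)^(-dct_t) / (1 + eff_reference)^(-dct_r)
  var_dct_t <- var(ct_target) / length(ct_target) +
    var(ct_target_cal) / length(ct_target_cal)
  var_dct_r <- var(ct_reference) / length(ct_reference) +
    var(ct_reference_cal) / length(ct_reference_cal)
  sd_re <- re * sqrt(log(1 + eff_target)^2 * var_dct_t +
                       log(1 + eff_reference)^2 * var_dct_r)
  list(relative_expression = re, sd = sd_re)
}
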