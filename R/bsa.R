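#' Encode a tetraploid dosage vector under a genetic model
#'
#' `additive` keeps the dosage; `dominant` is presence of at least one
#' copy; `recessive` is the quadruplex (4-copy) state -- the natural
#' tetraploid analogues of the diploid encodings.
#'
#' @param dosage Integer vector in 0..4 (NA allowed).
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return Numeric regressor vector.
#' @export
encode_model <- function(dosage, model) {
  abort_if(!model %in% c("additive", "dominant", "recessive"),
           sprintf("unknown model '%s'", model))
  abort_if(any(dosage < 0 | dosage > 4, na.rm = TRUE),
           "dosages must lie in 0..4")
  switch(model,
         additive = as.numeric(dosage),
         dominant = as.numeric(dosage > 0),
         recessive = as.numeric(dosage == 4))
}

# Pairwise-deletion simple-regression moments for a marker matrix
# (markers x individuals) against one or more phenotype vectors.
# Returns r^2, n, slope for each marker x phenotype.
marker_moments <- function(x_mat, y_mat) {
  m_ok <- !is.na(x_mat)
  xz <- ifelse(m_ok, x_mat, 0)
  n <- rowSums(m_ok)
  sx <- rowSums(xz)
  sxx <- rowSums(xz^2)
  sy <- m_ok %*% y_mat
  syy <- m_ok %*% y_mat^2
  sxy <- xz %*% y_mat
  ssx <- sxx - sx^2 / n
  ssy <- syy - sy^2 / n
  sp <- sxy - sx * sy / n
  r2 <- sp^2 / (ssx * ssy)
  r2[ssx <= 1e-12 | ssy <= 1e-12] <- NA_real_
  list(r2 = r2, n = n, slope = sp / ssx)
}

lod_from_r2 <- function(r2, n) -(n / 2) * log10(1 - r2)

#' Single-marker QTL scan with genetic-model selection
#'
#' Per marker, ordinary least squares of the phenotype on each of the
#' three encodings (using only individuals genotyped at that marker);
#' `LOD = (n/2) log10(RSS_null / RSS_model) = -(n/2) log10(1 - R^2)`,
#' and the reported model is the one with the highest LOD. The p-value
#' is the regression F-test. Censored phenotypes enter at the cutoff
#' value (the recorded end date) unless `censoring = "exclude"`.
#'
#' @param panel An `f2_panel` from [simulate_f2()] (or a compatible
#'   list with `markers`, `geno`, `phenotype`).
#' @param min_genotyped_frac Markers genotyped in less than this
#'   fraction of individuals are dropped (default 0.4).
#' @param censoring `"cutoff"` (default) or `"exclude"`.
#' @return A tibble with class `marker_scan`: `marker`, `scaffold`,
#'   `position`, `n`, `model`, `lod`, `p_value`, `effect`, plus the
#'   per-model LODs `lod_additive`, `lod_dominant`, `lod_recessive`.
#' @export
single_marker_scan <- function(panel, min_genotyped_frac = 0.4,
                               censoring = c("cutoff", "exclude")) {
  censoring <- match.arg(censoring)
  y <- panel$phenotype$days_to_bolting
  keep_ind <- if (censoring == "exclude") !panel$phenotype$censored else
    rep(TRUE, length(y))
  y <- y[keep_ind]
  g <- panel$geno[, keep_ind, drop = FALSE]
  frac <- rowMeans(!is.na(g))
  keep_m <- frac >= min_genotyped_frac
  g <- g[keep_m, , drop = FALSE]
  markers <- panel$markers[keep_m, ]

  ymat <- matrix(y, ncol = 1)
  models <- c("additive", "dominant", "recessive")
  mom <- lapply(models, function(md) {
    x <- t(apply(g, 1, encode_model, model = md))
    if (nrow(g) == 1L) x <- matrix(x, nrow = 1)
    marker_moments(x, ymat)
  })
  names(mom) <- models
  lods <- vapply(models, function(md)
    lod_from_r2(mom[[md]]$r2[, 1], mom[[md]]$n), numeric(nrow(g)))
  if (nrow(g) == 1L) lods <- matrix(lods, nrow = 1,
                                    dimnames = list(NULL, models))
  best <- apply(lods, 1, function(l)
    if (all(is.na(l))) NA_integer_ else which.max(l))
  pick_best <- function(fld) vapply(seq_len(nrow(g)), function(i) {
    if (is.na(best[i])) return(NA_real_)
    mom[[best[i]]][[fld]][i, 1]
  }, numeric(1))
  r2 <- pick_best("r2")
  n <- mom$additive$n
  fstat <- r2 * (n - 2) / (1 - r2)
  out <- markers |>
    dplyr::mutate(
      n = n,
      model = ifelse(is.na(best), NA_character_, models[best]),
      lod = ifelse(is.na(best), NA_real_,
                   lods[cbind(seq_len(nrow(g)), best)]),
      p_value = pf(fstat, 1, n - 2, lower.tail = FALSE),
      effect = pick_best("slope"),
      lod_additive = lods[, "additive"],
      lod_dominant = lods[, "dominant"],
      lod_recessive = lods[, "recessive"])
  class(out) <- c("marker_scan", class(out))
  attr(out, "n_individuals") <- length(y)
  out
}

#' @export
glance.marker_scan <- function(x, ...) {
  top <- x[which.max(x$lod), ]
  tibble::tibble(n_markers = nrow(x),
                 n_individuals = attr(x, "n_individuals"),
                 top_marker = top$marker, top_lod = top$lod,
                 top_model = top$model, top_p = top$p_value)
}

#' Genome-wide LOD significance by phenotype permutation
#'
#' Permutes the phenotype across individuals `n_perm` times, rerunning
#' the full model-selection scan each time, and reports both the
#' maximum of the per-permutation maximum LODs (the conservative
#' headline number) and their 95th percentile (the conventional 5%
#' genome-wide threshold).
#'
#' @inheritParams single_marker_scan
#' @param n_perm Number of permutations (default 500; < 100 warns).
#' @param seed Integer RNG seed.
#' @return List with class `lod_threshold`: `max_lod`, `q95`,
#'   `per_perm` (vector of per-permutation maxima), `n_perm`, `seed`.
#' @export
permutation_threshold <- function(panel, n_perm = 500L, seed = 1L,
                                  min_genotyped_frac = 0.4,
                                  censoring = c("cutoff", "exclude")) {
  censoring <- match.arg(censoring)
  check_count(n_perm)
  if (n_perm < 100)
    warning("fewer than 100 permutations gives an unstable threshold",
            call. = FALSE)
  y <- panel$phenotype$days_to_bolting
  keep_ind <- if (censoring == "exclude") !panel$phenotype$censored else
    rep(TRUE, length(y))
  y <- y[keep_ind]
  g <- panel$geno[, keep_ind, drop = FALSE]
  g <- g[rowMeans(!is.na(g)) >= min_genotyped_frac, , drop = FALSE]
  with_seed(seed, {
    yperm <- vapply(seq_len(n_perm), function(i) sample(y),
                    numeric(length(y)))
    per_perm <- rep(-Inf, n_perm)
    for (md in c("additive", "dominant", "recessive")) {
      x <- t(apply(g, 1, encode_model, model = md))
      if (nrow(g) == 1L) x <- matrix(x, nrow = 1)
      mom <- marker_moments(x, yperm)
      lod <- lod_from_r2(mom$r2, mom$n)
      mx <- suppressWarnings(apply(lod, 2, max, na.rm = TRUE))
      per_perm <- pmax(per_perm, mx)
    }
    structure(list(max_lod = max(per_perm),
                   q95 = unname(quantile(per_perm, 0.95, type = 1)),
                   per_perm = per_perm, n_perm = n_perm, seed = seed),
              class = "lod_threshold")
  })
}

#' @export
print.lod_threshold <- function(x, ...) {
  cat(sprintf(
    "<lod_threshold> max over %d permutations: %.2f (95%%ile %.2f)\n",
    x$n_perm, x$max_lod, x$q95))
  invisible(x)
}

#' Stepwise multiple-marker model with semi-partial correlations
#'
#' Forward selection over a candidate marker set (additive dosage
#' regressors, complete cases): at each step the marker giving the
#' largest reduction in the error sum of squares is added if its
#' partial F-test p-value is below `alpha`. Collinear markers (no
#' residual variance left) are skipped. For each retained marker the
#' semi-partial correlation (square root of the R-squared increment
#' when that marker is added last to the final model) and its
#' single-marker percent variance explained are reported.
#'
#' @param panel An `f2_panel`.
#' @param candidate_markers Character vector of marker ids (typically
#'   the high-LOD set from [single_marker_scan()]).
#' @param alpha Partial F-test entry level (default 0.05).
#' @param censoring As in [single_marker_scan()].
#' @return Tibble: `marker`, `step`, `p_partial`, `spc`, `pve`
#'   (percent), `r2_full` attribute.
#' @export
stepwise_mlm <- function(panel, candidate_markers, alpha = 0.05,
                         censoring = c("cutoff", "exclude")) {
  censoring <- match.arg(censoring)
  idx <- match(candidate_markers, panel$markers$marker)
  abort_if(anyNA(idx), "unknown candidate marker id")
  y_all <- panel$phenotype$days_to_bolting
  keep_ind <- if (censoring == "exclude") !panel$phenotype$censored else
    rep(TRUE, length(y_all))
  x_all <- t(panel$geno[idx, keep_ind, drop = FALSE])
  y <- y_all[keep_ind]
  cc <- complete.cases(x_all)
  x <- x_all[cc, , drop = FALSE]
  colnames(x) <- candidate_markers
  y <- y[cc]
  n <- length(y)

  selected <- integer(0)
  steps <- list()
  repeat {
    remaining <- setdiff(seq_along(candidate_markers), selected)
    if (!length(remaining)) break
    base_fit <- if (length(selected))
      lm(y ~ x[, selected, drop = FALSE]) else lm(y ~ 1)
    rss0 <- sum(stats::resid(base_fit)^2)
    df0 <- n - length(selected) - 1L
    cand <- vapply(remaining, function(j) {
      fit <- lm(y ~ x[, c(selected, j), drop = FALSE])
      rss1 <- sum(stats::resid(fit)^2)
      if (fit$rank <= length(selected) + 1L) return(c(NA_real_, NA_real_))
      fstat <- (rss0 - rss1) / (rss1 / (df0 - 1L))
      c(rss1, pf(fstat, 1, df0 - 1L, lower.tail = FALSE))
    }, numeric(2))
    usable <- which(!is.na(cand[1, ]))
    if (!length(usable)) break
    best <- usable[which.min(cand[1, usable])]
    j <- remaining[best]
    p_part <- cand[2, best]
    if (is.na(p_part) || p_part >= alpha) break
    selected <- c(selected, j)
    steps[[length(steps) + 1]] <- tibble::tibble(
      marker = candidate_markers[j], step = length(selected),
      p_partial = p_part)
  }
  if (!length(selected))
    return(tibble::tibble(marker = character(), step = integer(),
                          p_partial = numeric(), spc = numeric(),
                          pve = numeric()))
  full <- lm(y ~ x[, selected, drop = FALSE])
  r2_full <- summary(full)$r.squared
  out <- dplyr::bind_rows(steps)
  out$spc <- vapply(seq_along(selected), function(k) {
    r2_red <- if (length(selected) == 1L) 0 else
      summary(lm(y ~ x[, selected[-k], drop = FALSE]))$r.squared
    sqrt(max(0, r2_full - r2_red))
  }, numeric(1))
  out$pve <- vapply(selected, function(j) {
    100 * summary(lm(y ~ x[, j]))$r.squared
  }, numeric(1))
  attr(out, "r2_full") <- r2_full
  out
}
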