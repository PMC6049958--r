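mk_windows <- function(values, start = seq_along(values) * 100 - 99,
                       end = seq_along(values) * 100) {
  tibble::tibble(scaffold = "sc1", start_bp = start, end_bp = end,
                 value = values)
}
mk_gene <- function(id, s, e) tibble::tibble(gene_id = id,
                                             scaffold = "sc1",
                                             start = s, end = e,
                                             strand = "+")

test_that("gene-wise aggregation takes the directed extreme", {
  w <- mk_windows(c(-1.2, -3.5, 0.4))
  g <- mk_gene("g1", 1, 300)
  expect_equal(genewise_aggregate(w, g, "min")$value, -3.5)
  expect_equal(genewise_aggregate(mk_windows(c(0.1, 0.6)),
                                  mk_gene("g", 1, 200), "max")$value, 0.6)
  # a gene spanning a window boundary counts both windows
  g2 <- mk_gene("g2", 95, 105)
  res <- genewise_aggregate(mk_windows(c(0.1, 0.6, 0.9)), g2, "max")
  expect_equal(res$n_windows, 2)
  expect_equal(res$value, 0.6)
  # genes with no overlapping window are omitted
  expect_equal(nrow(genewise_aggregate(w, mk_gene("far", 5000, 6000),
                                       "max")), 0)
  # idempotence: aggregating gene-level spans returns them unchanged
  gl <- mk_windows(c(0.2, 0.8))
  genes <- dplyr::bind_rows(mk_gene("a", 1, 100), mk_gene("b", 101, 200))
  again <- genewise_aggregate(gl, genes, "max")
  expect_equal(again$value, c(0.2, 0.8))
})

test_that("least-extreme reduction is conservative across comparisons", {
  tabs <- lapply(c(0.9, 0.8, 0.95, 0.7), function(v)
    tibble::tibble(gene_id = "g", value = v, n_windows = 1L))
  expect_equal(least_extreme_across(tabs, "max")$value, 0.7)
  htabs <- lapply(c(-3.5, -2.0), function(v)
    tibble::tibble(gene_id = "g", value = v))
  expect_equal(least_extreme_across(htabs, "min")$value, -2.0)
  expect_equal(least_extreme_across(htabs[1], "min")$value, -3.5)
  # genes missing in any comparison are omitted
  uneven <- list(tibble::tibble(gene_id = c("a", "b"), value = c(1, 2)),
                 tibble::tibble(gene_id = "a", value = 3))
  expect_equal(least_extreme_across(uneven, "max")$gene_id, "a")
})

test_that("empirical thresholds are order statistics with strict flags", {
  x <- seq_len(1000)
  expect_equal(empirical_threshold(x, 0.05, "upper"), 950)
  expect_equal(empirical_threshold(x, 0.05, "lower"), 50)
  expect_error(empirical_threshold(1:50, 0.05), "100")
  same <- rep(3, 200)
  cut <- empirical_threshold(same, 0.05, "upper")
  expect_equal(cut, 3)
  expect_false(any(same > cut))  # strict inequality flags none
  set.seed(61)
  u <- runif(1e5)
  expect_equal(empirical_threshold(u, 0.05, "upper"), 0.95,
               tolerance = 0.01)
})

test_that("railway-specific candidates require the three-way intersection", {
  genes <- sprintf("g%03d", 1:200)
  set.seed(62)
  gst <- tibble::tibble(gene_id = genes, value = runif(200, 0, 0.4))
  gst$value[gst$gene_id %in% c("g001", "g002", "g003")] <- c(0.9, 0.85, 0.8)
  base_h <- function(pop, outliers) {
    v <- runif(200, -0.5, 0.5)
    names(v) <- genes
    v[outliers] <- -5
    tibble::tibble(gene_id = genes, population = pop, value = unname(v))
  }
  # g001: H outlier in both railways, no mountain -> candidate
  # g002: H outlier in railway AND one mountain -> excluded
  # g003: H outlier in one railway only -> excluded
  gene_h <- dplyr::bind_rows(
    base_h("TBG", c("g001", "g002", "g003")),
    base_h("STE", c("g001", "g002")),
    base_h("HO", "g002"),
    base_h("KA", character(0)))
  gene_tajd <- dplyr::bind_rows(
    base_h("TBG", "g001"), base_h("STE", "g001"))
  out <- railway_selection_candidates(
    gst, gene_h, gene_tajd, railway_pops = c("TBG", "STE"),
    mountain_pops = c("HO", "KA"))
  expect_equal(out$gene_id, "g001")
  expect_true(out$tajd_mark)
  expect_true(out$h_railway_outlier)

  # remove the TajD mark
  gene_tajd2 <- dplyr::bind_rows(base_h("TBG", "g001"),
                                 base_h("STE", character(0)))
  out2 <- railway_selection_candidates(
    gst, gene_h, gene_tajd2, railway_pops = c("TBG", "STE"),
    mountain_pops = c("HO", "KA"))
  expect_false(out2$tajd_mark)

  # no overlap between G_ST and H outliers -> empty
  gene_h_none <- dplyr::bind_rows(base_h("TBG", character(0)),
                                  base_h("STE", character(0)),
                                  base_h("HO", character(0)),
                                  base_h("KA", character(0)))
  out3 <- railway_selection_candidates(
    gst, gene_h_none, gene_tajd, railway_pops = c("TBG", "STE"),
    mountain_pops = c("HO", "KA"))
  expect_equal(nrow(out3), 0)
  expect_error(railway_selection_candidates(
    gst, base_h("TBG", character(0)), gene_tajd,
    railway_pops = c("TBG", "STE"), mountain_pops = c("HO", "KA")),
    "populations")
})

test_that("candidate sets are monotone in the outlier quantiles", {
  genes <- sprintf("g%03d", 1:300)
  set.seed(63)
  gst <- tibble::tibble(gene_id = genes, value = runif(300))
  gene_h <- dplyr::bind_rows(lapply(c("TBG", "STE", "HO", "KA"),
                                    function(p)
    tibble::tibble(gene_id = genes, population = p,
                   value = rnorm(300))))
  gene_td <- dplyr::filter(gene_h, population %in% c("TBG", "STE"))
  loose <- railway_selection_candidates(
    gst, gene_h, gene_td, c("TBG", "STE"), c("HO", "KA"),
    quantiles = list(gst = 0.3, h = 0.3, tajd = 0.3))
  tight <- railway_selection_candidates(
    gst, gene_h, gene_td, c("TBG", "STE"), c("HO", "KA"),
    quantiles = list(gst = 0.05, h = 0.05, tajd = 0.05))
  expect_true(all(tight$gene_id %in% loose$gene_id))
})

test_that("signature frequencies average derived alleles per population", {
  freqs <- tidyr::expand_grid(site = 1:4, population = c("A", "B", "C")) |>
    dplyr::mutate(scaffold = "sc1", position = site * 10,
                  provenance = "genotype", polarizable = TRUE,
                  derived = "alt",
                  p = dplyr::case_when(
                    population == "A" ~ 1.0,
                    population == "B" ~ 0.0,
                    population == "C" & site <= 2 ~ 1.0,
                    TRUE ~ 0.6))
  freqs$provenance[freqs$population == "C" & freqs$site == 1] <-
    "read_count"
  freqs$p[freqs$population == "B"] <- NA_real_
  sig <- tibble::tibble(scaffold = "sc1", position = c(10, 20, 30, 40))
  out <- signature_frequencies(freqs, sig)
  expect_equal(out$mean_freq[out$population == "A"], 1.0)
  expect_true(is.na(out$mean_freq[out$population == "B"]))
  expect_equal(out$mean_freq[out$population == "C"], 0.8)
  expect_equal(out$n_fallback[out$population == "C"], 1)
})

test_that("differentiated variants use a strict group-difference rule", {
  mk <- function(pa, pb) {
    tidyr::expand_grid(site = seq_along(pa),
                       population = c("rw1", "rw2", "mt1", "mt2")) |>
      dplyr::mutate(scaffold = "sc1", position = site,
                    p = ifelse(population %in% c("rw1", "rw2"),
                               pa[site], pb[site]))
  }
  fr <- mk(c(0.79, 0.5, 0.2), c(0.0, 0.3, 0.9))
  out <- differentiated_variants(fr, c("rw1", "rw2"), c("mt1", "mt2"))
  expect_equal(out$site, c(1L, 3L))
  expect_equal(out$derived_in, c("A", "B"))
  # boundary: |0.5 - 0.3| = 0.2 and even 0.30 exactly is not flagged
  fr2 <- mk(c(0.6), c(0.3))
  expect_equal(nrow(differentiated_variants(fr2, c("rw1", "rw2"),
                                            c("mt1", "mt2"))), 0)
  fr3 <- mk(c(0.4, 0.2), c(0.4, 0.2))
  expect_equal(nrow(differentiated_variants(fr3, c("rw1", "rw2"),
                                            c("mt1", "mt2"))), 0)
})
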