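test_that("median-of-ratios size factors satisfy scaling identities", {
  set.seed(71)
  counts <- matrix(rnbinom(600, mu = 100, size = 10), 100, 6)
  colnames(counts) <- paste0("s", 1:6)
  doubled <- counts
  doubled[, 2] <- counts[, 1] * 2L
  nf <- normalize_counts(doubled)
  expect_equal(nf$size_factors[[2]] / nf$size_factors[[1]], 2)
  expect_equal(nf$normalized[, 1], nf$normalized[, 2],
               ignore_attr = TRUE)

  same <- matrix(rep(counts[, 1], 4), ncol = 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(unname(normalize_counts(same)$size_factors), rep(1, 4))

  # invariant to gene order
  perm <- sample(nrow(counts))
  expect_equal(unname(normalize_counts(counts[perm, ])$size_factors),
               unname(normalize_counts(counts)$size_factors))
  zero <- counts; zero[cbind(1:100, rep(1:6, length.out = 100))] <- 0L
  expect_error(normalize_counts(zero), "pseudo-reference")
})

test_that("size factors agree with the established implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(72)
  counts <- matrix(rnbinom(2000, mu = 50, size = 5), 200, 10)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(normalize_counts(counts)$size_factors),
               unname(ref), tolerance = 1e-8)
})

test_that("top-variance PCA separates planted structure", {
  set.seed(73)
  base <- matrix(rnbinom(3000, mu = 100, size = 20), 300, 10)
  base[1:50, 6:10] <- base[1:50, 6:10] + 150L
  colnames(base) <- paste0("s", 1:10)
  pc <- top_variable_pca(base, 100)
  expect_true(all(pc$variance_explained >= 0))
  expect_lte(sum(pc$variance_explained), 100 + 1e-8)
  grp <- rep(1:2, each = 5)
  expect_gt(abs(cor(pc$coords$PC1, grp)), 0.9)
  # identical samples -> identical coordinates
  twin <- cbind(base, base[, 10])
  colnames(twin) <- c(colnames(base), "s11")
  pc2 <- top_variable_pca(twin, 100)
  expect_equal(unlist(pc2$coords[10, -1]), unlist(pc2$coords[11, -1]),
               ignore_attr = TRUE)
  expect_warning(top_variable_pca(base, 10000), "fewer genes")
  expect_error(top_variable_pca(base[, 1:2]), "3 samples")
})

test_that("Tukey classification applies the published decision rule", {
  design <- default_expression_design()
  # deterministic replicates: zero-mean within-class patterns make the
  # relevant Tukey t-statistics exactly 0 where classes are equal
  mk_gene <- function(mu_rw, mu_mt, mu_bgs) {
    c(mu_rw + rep(c(-1, 0, 1), 2),       # 6 RW samples
      mu_mt + rep(c(-1, 0, 1), 4),       # 12 MT samples
      mu_bgs + c(-1, 0, 1))              # 3 BGS samples
  }
  samples <- purrr::pmap_dfr(design, function(population, class, n_reps)
    tibble::tibble(sample = sprintf("%s_r%d", population, 1:n_reps),
                   population = population, class = class))
  ord <- order(match(samples$class, c("RW", "MT", "BGS")))
  samples <- samples[ord, ]
  m <- rbind(mountainish = mk_gene(1, 100, 100),
             railwayish = mk_gene(100, 1, 100),
             flat = mk_gene(100, 100, 100),
             inter = mk_gene(200, 1, 100))
  colnames(m) <- samples$sample
  cl <- tukey_classify(m, samples)
  expect_equal(cl$class,
               c("mountain_like", "railway_like", "not_de",
                 "intermediate"))
  # classes are disjoint subsets of the DE set
  expect_true(all(cl$de[cl$class %in% c("mountain_like",
                                        "railway_like",
                                        "intermediate")]))
  # zero-variance genes are skipped with a log message
  m2 <- rbind(m, allsame = rep(5, 21))
  expect_message(cl2 <- tukey_classify(m2, samples), "zero within-class")
  expect_true(is.na(cl2$class[5]))
  g <- glance(cl)
  expect_equal(g$n_de, 3)
  expect_equal(g$n_mountain_like, 1)
})

test_that("classification is invariant to library-size rescaling", {
  sim <- simulate_expression(n_genes = 120, n_mountain_like = 20,
                             n_railway_like = 10, n_intermediate = 0,
                             seed = 75)
  scaled <- sim$counts
  scaled[, 3] <- scaled[, 3] * 4L
  cl1 <- tukey_classify(normalize_counts(sim$counts)$normalized,
                        sim$samples)
  cl2 <- tukey_classify(normalize_counts(scaled)$normalized,
                        sim$samples)
  expect_equal(cl1$class, cl2$class)
})

test_that("flowering correlation scan filters, ranks and errors", {
  pops <- c("TBG", "STE", "KA", "CA2", "HO", "SWA", "BGS")
  samples <- tibble::tibble(
    sample = paste0(rep(pops, each = 2), "_r", 1:2),
    population = rep(pops, each = 2))
  ft <- tibble::tibble(population = pops,
                       flowering_time = c(20, 25, 60, 65, 70, 75, 22))
  ft_incl <- ft$flowering_time[ft$population != "BGS"]
  set.seed(76)
  noise <- matrix(rnbinom(100 * 14, mu = 50, size = 20), 100, 14)
  # gene 1: exactly proportional to flowering time
  noise[1, ] <- rep(ft$flowering_time, each = 2) * 3
  # gene 2: constant -> sd 0 -> excluded
  noise[2, ] <- 50
  # gene 3: below the expression filter
  noise[3, ] <- 1
  colnames(noise) <- samples$sample
  rownames(noise) <- sprintf("gene%05d", 1:100)
  out <- flowering_correlation_scan(noise, samples, ft,
                                    exclude = "BGS")
  expect_equal(out$gene_id[1], "gene00001")
  expect_equal(out$r[1], 1)
  expect_false("gene00002" %in% out$gene_id)
  expect_false("gene00003" %in% out$gene_id)
  expect_true(out$top[1])
  expect_equal(sum(out$top), ceiling(0.01 * nrow(out)))
  expect_error(flowering_correlation_scan(
    noise, samples[samples$population %in% pops[1:3], ],
    ft[1:3, ], exclude = "BGS"), "4 populations")
})

test_that("planted flowering-correlated genes are recovered in the top 1%", {
  pops <- c("TBG", "STE", "KA", "CA2", "HO", "SWA")
  samples <- tibble::tibble(sample = paste0(rep(pops, each = 3), "_r",
                                            1:3),
                            population = rep(pops, each = 3))
  ft <- tibble::tibble(population = pops,
                       flowering_time = c(20, 25, 60, 65, 70, 75))
  recall <- replicate(10, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    m <- matrix(rnbinom(500 * 18, mu = 60, size = 20), 500, 18)
    planted <- 1:5
    for (g in planted)
      m[g, ] <- round(rep(ft$flowering_time, each = 3) * 2 +
                        rnorm(18, 0, 4))
    colnames(m) <- samples$sample
    rownames(m) <- sprintf("gene%05d", 1:500)
    out <- flowering_correlation_scan(m, samples, ft, exclude = NULL,
                                      top_fraction = 0.01)
    mean(sprintf("gene%05d", planted) %in% out$gene_id[out$top])
  })
  expect_gte(mean(recall), 0.8)
})

test_that("residual outlier p-values match the normal reference", {
  # included points: positions t along a slope-2 line, offsets +-s
  # along its normal chosen orthogonal to t, so the major axis is the
  # line itself and sigma is exactly s
  u <- c(1, 2) / sqrt(5); nrm <- c(-2, 1) / sqrt(5)
  t_pos <- c(-3, -1, 1, 3); off <- 0.4 * c(1, -1, -1, 1)
  x <- t_pos * u[1] + off * nrm[1]
  y <- t_pos * u[2] + off * nrm[2]
  on_line <- residual_outlier_p(x, y, x0 = 0, y0 = 0)
  expect_equal(on_line$p, 1)          # excluded residual 0
  expect_equal(on_line$sigma, 0.4)
  expect_equal(abs(on_line$slope), 2, tolerance = 1e-9)
  # residual exactly sigma -> p = 0.3173; 3 sigma -> 0.0027
  p1 <- residual_outlier_p(x, y, 0.4 * nrm[1], 0.4 * nrm[2])
  expect_equal(p1$p, 2 * (1 - pnorm(1)), tolerance = 1e-9)
  p3 <- residual_outlier_p(x, y, 1.2 * nrm[1], 1.2 * nrm[2])
  expect_equal(p3$p, 2 * (1 - pnorm(3)), tolerance = 1e-9)
  expect_equal(round(p1$p, 4), 0.3173)
  expect_equal(round(p3$p, 4), 0.0027)
})

test_that("orthogonal residuals are rotation invariant", {
  set.seed(77)
  x <- rnorm(8); y <- 1.5 * x + rnorm(8, 0, 0.4)
  x0 <- 0.5; y0 <- 3
  p0 <- residual_outlier_p(x, y, x0, y0)$p
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(x, y) %*% rot
  pt <- c(x0, y0) %*% rot
  p1 <- residual_outlier_p(xy[, 1], xy[, 2], pt[1], pt[2])$p
  expect_equal(p0, p1, tolerance = 1e-9)
  # degenerate: zero spread
  expect_warning(pz <- residual_outlier_p(1:5, 2 * (1:5), 3, 100),
                 "zero residual")
  expect_equal(pz$p, 0)
})

test_that("qPCR relative expression and its propagated error", {
  # identical Ct everywhere -> ratio 1
  r0 <- qpcr_relative_expression(c(20, 20), c(18, 18), c(20, 20),
                                 c(18, 18), 0.9, 0.9)
  expect_equal(r0$relative_expression, 1)
  # 100% efficiency, target one cycle earlier -> doubling
  r2 <- qpcr_relative_expression(c(19, 19), c(18, 18), c(20, 20),
                                 c(18, 18), 1, 1)
  expect_equal(r2$relative_expression, 2)
  expect_error(qpcr_relative_expression(c(20, 20), c(18, 18),
                                        c(20, 20), c(18, 18),
                                        eff_target = 1.8), "efficiency")
  expect_error(qpcr_relative_expression(20, c(18, 18), c(20, 20),
                                        c(18, 18)), "technical")

  # delta-method SD matches Monte-Carlo propagation within 5%
  set.seed(78)
  ct_t <- c(21.1, 21.4, 21.2); ct_r <- c(17.9, 18.1, 18.0)
  ct_tc <- c(23.0, 23.2, 23.1); ct_rc <- c(18.2, 18.0, 18.1)
  res <- qpcr_relative_expression(ct_t, ct_r, ct_tc, ct_rc, 0.87, 0.91)
  nmc <- 1e5
  draw <- function(v) rnorm(nmc, mean(v), sd(v) / sqrt(length(v)))
  mc <- (1 + 0.87)^(-(draw(ct_t) - draw(ct_tc))) /
    (1 + 0.91)^(-(draw(ct_r) - draw(ct_rc)))
  expect_equal(res$sd, sd(mc), tolerance = 0.05)
})
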