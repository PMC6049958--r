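test_that("frequency estimation polarizes against the outgroup", {
  # 8 individuals all dosage 2, outgroup fixed REF -> p = 16/32 = 0.5
  pan <- toy_panel(list(P1 = matrix(2L, 1, 8)))
  fr <- estimate_frequencies(pan, outgroup = "O", min_individuals = 5)
  p1 <- dplyr::filter(fr, population == "P1")
  expect_equal(p1$p, 0.5)
  expect_equal(p1$n_chr, 32)
  expect_equal(unique(fr$derived), "alt")

  # outgroup fixed for ALT: derived/ancestral swap, p -> 1 - p
  pan2 <- toy_panel(list(P1 = matrix(1L, 1, 8)))
  og <- which(pan2$samples$population == "O")
  pan2$geno[, og] <- 2L  # diploid outgroup homozygous ALT
  fr2 <- estimate_frequencies(pan2, outgroup = "O", min_individuals = 5)
  expect_equal(dplyr::filter(fr2, population == "P1")$p, 1 - 1 / 4)
  expect_equal(unique(fr2$derived), "ref")

  # fewer than min_individuals genotyped -> missing
  pan3 <- toy_panel(list(P1 = matrix(2L, 1, 8)))
  pan3$geno[1, 1:4] <- NA_integer_
  fr3 <- estimate_frequencies(pan3, outgroup = "O", min_individuals = 5)
  expect_true(is.na(dplyr::filter(fr3, population == "P1")$p))
  expect_equal(dplyr::filter(fr3, population == "P1")$provenance,
               "missing")

  # polymorphic outgroup above the threshold -> unpolarizable
  pan4 <- toy_panel(list(P1 = matrix(2L, 1, 8)))
  og4 <- which(pan4$samples$population == "O")
  pan4$geno[1, og4] <- c(1L, 1L, 0L, 0L)  # outgroup ALT freq 0.25
  fr4 <- estimate_frequencies(pan4, outgroup = "O",
                              max_outgroup_minor = 0.2)
  expect_false(any(fr4$polarizable))
  expect_error(estimate_frequencies(pan, outgroup = "nope"), "outgroup")
})

test_that("read-count fallback fills missing sites and tracks truth", {
  pan <- toy_panel(list(P1 = rbind(rep(2L, 8), rep(1L, 8), rep(3L, 8))))
  pan$geno[2, 1:5] <- NA_integer_  # only 3 genotyped < 5
  fr <- estimate_frequencies(pan, outgroup = "O", min_individuals = 5)
  rc <- tibble::tibble(site = c(2L, 3L), population = "P1",
                       ref_reads = c(40L, 0L), alt_reads = c(60L, 0L))
  fb <- read_count_fallback(fr, rc)
  p1 <- dplyr::filter(fb, population == "P1")
  expect_equal(p1$p[2], 0.6)
  expect_equal(p1$provenance[2], "read_count")
  expect_equal(p1$provenance[3], "genotype")  # zero reads ignored
  # 0 ALT of 50 -> 0.0
  rc0 <- tibble::tibble(site = 2L, population = "P1",
                        ref_reads = 50L, alt_reads = 0L)
  expect_equal(dplyr::filter(read_count_fallback(fr, rc0),
                             population == "P1")$p[2], 0)
})

test_that("fallback frequencies track genotype frequencies (r > 0.92)", {
  m <- pop_model(populations = tibble::tibble(
    population = c("P1", "O"), n = c(20L, 12L), ploidy = c(4L, 2L),
    fst = c(0.25, 0.5)), n_sites = 3000)
  pan <- simulate_panel(m, seed = 31)
  fr <- estimate_frequencies(pan, outgroup = "O")
  g <- dplyr::filter(fr, population == "P1", provenance == "genotype")
  # pooled read counts at matched depth (~100 reads per site)
  set.seed(32)
  truth <- attr(pan, "truth")[g$site, "P1"]  # true ALT frequency
  depth <- 100L
  alt <- rbinom(nrow(g), depth, truth)
  p_fallback <- ifelse(g$derived == "alt", alt / depth,
                       1 - alt / depth)
  expect_gt(cor(p_fallback, g$p), 0.92)
})

test_that("windows partition usable SNPs without spanning scaffolds", {
  sites <- tibble::tibble(site = 1:50, scaffold = "sc1",
                          position = (1:50) * 10L)
  w <- make_windows(sites, 25)
  expect_equal(nrow(w), 2)
  expect_equal(w$n_snps, c(25, 25))
  expect_false(any(w$short))

  sites60 <- tibble::tibble(site = 1:60, scaffold = "sc1",
                            position = (1:60) * 10L)
  w60 <- make_windows(sites60, 25)
  expect_equal(w60$n_snps, c(25, 25, 10))
  expect_equal(w60$short, c(FALSE, FALSE, TRUE))

  split <- tibble::tibble(site = 1:40,
                          scaffold = rep(c("a", "b"), each = 20),
                          position = rep((1:20) * 10L, 2))
  ws <- make_windows(split, 25)
  expect_equal(ws$scaffold, c("a", "b"))
  expect_true(all(ws$short))
})

test_that("G_ST matches hand values and the chromosome-pair oracle", {
  expect_equal(gst_window(matrix(c(1, 0), 1)), 1)    # fixed difference
  expect_equal(gst_window(matrix(c(0.3, 0.3, 0.3), 1)), 0)
  # hand computation: p = (0.2, 0.4)
  expect_equal(gst_window(matrix(c(0.2, 0.4), 1)),
               (0.42 - 0.40) / 0.42, tolerance = 1e-12)
  expect_true(is.na(gst_window(matrix(c(0, 0, 0), 1))))

  set.seed(41)
  for (rep in 1:5) {
    g1 <- rand_dosage(30, 6); g2 <- rand_dosage(30, 5)
    p_mat <- cbind(rowMeans(g1) / 4, rowMeans(g2) / 4)
    chr <- list(chrom_expand(g1, rep(4L, 6)), chrom_expand(g2, rep(4L, 5)))
    expect_equal(gst_window(p_mat), oracle_gst(chr), tolerance = 1e-9)
  }
})

test_that("Tajima's D equals the count-based oracle and behaves", {
  set.seed(42)
  for (rep in 1:8) {
    n_ind <- sample(3:10, 1)
    g <- rand_dosage(sample(10:50, 1), n_ind)
    chr <- chrom_expand(g, rep(4L, n_ind))
    p <- rowMeans(g) / 4
    n_chr <- rep(4 * n_ind, nrow(g))
    expect_equal(tajimas_d_window(p, n_chr), oracle_tajd(chr),
                 tolerance = 1e-9)
  }
  # all-singleton window is negative
  n <- 40
  p_singleton <- rep(1 / n, 12)
  expect_lt(tajimas_d_window(p_singleton, rep(n, 12)), 0)
  expect_true(is.na(tajimas_d_window(rep(0, 5), rep(40, 5))))  # S = 0
  expect_true(is.na(tajimas_d_window(0.5, 2)))                 # n < 4
})

test_that("Tajima's D is centred near zero under the neutral spectrum", {
  m <- pop_model(populations = tibble::tibble(
    population = c("P1", "O"), n = c(10L, 6L), ploidy = c(4L, 2L),
    fst = c(0.2, 0.5)), n_sites = 12500, ancestral = "neutral")
  pan <- simulate_panel(m, seed = 43)
  p <- attr(pan, "truth")[, "P1"]
  n_chr <- rep(40, length(p))
  d <- vapply(split(seq_along(p), (seq_along(p) - 1) %/% 25),
              function(ix) tajimas_d_window(p[ix], n_chr[ix]),
              numeric(1))
  expect_equal(length(d), 500)
  expect_gt(mean(d), -0.5)
  expect_lt(mean(d), 0.5)
})

test_that("Fay & Wu's H matches hand values and the count oracle", {
  # n = 4: derived count 3 -> H = 0.5 - 1.5 = -1
  expect_equal(fay_wu_h_window(3 / 4, 4), -1)
  # singleton: H = 0.5 - 1/6
  expect_equal(fay_wu_h_window(1 / 4, 4), 0.5 - 1 / 6, tolerance = 1e-12)
  expect_true(is.na(fay_wu_h_window(0, 4)))  # nothing segregating
  set.seed(44)
  for (rep in 1:8) {
    n_ind <- sample(3:10, 1)
    g <- rand_dosage(sample(10:50, 1), n_ind)
    chr <- chrom_expand(g, rep(4L, n_ind))
    expect_equal(fay_wu_h_window(rowMeans(g) / 4, rep(4 * n_ind, nrow(g))),
                 oracle_fwh(chr), tolerance = 1e-9)
  }
})

test_that("polarization involution: flipping the outgroup maps p to 1-p", {
  set.seed(45)
  g1 <- rand_dosage(40, 6); g2 <- rand_dosage(40, 6)
  pan <- toy_panel(list(P1 = g1, P2 = g2))
  fr <- toy_freqs(pan)
  flipped <- pan
  og <- which(pan$samples$population == "O")
  flipped$geno[, og] <- 2L  # outgroup now fixed ALT
  fr_f <- toy_freqs(flipped)
  for (pp in c("P1", "P2")) {
    a <- dplyr::filter(fr, population == pp)$p
    b <- dplyr::filter(fr_f, population == pp)$p
    expect_equal(b, 1 - a)
  }
  # G_ST invariant under the flip
  w <- window_stats(fr, c("P1", "P2"), stats = "gst",
                    window_size_snps = 20)
  w_f <- window_stats(fr_f, c("P1", "P2"), stats = "gst",
                      window_size_snps = 20)
  expect_equal(w$value, w_f$value)
})

test_that("tetraploid HWE arithmetic is exact and sums to one", {
  expect_equal(hwe_genotype_prob(0.8, "homozygous"), 0.4096)
  expect_equal(hwe_genotype_prob(0.3, "zero_of_set"), 0.2401)
  expect_equal(hwe_genotype_prob(1.0, "homozygous"), 1.0)
  for (p in c(0.1, 0.37, 0.5, 0.9)) {
    tot <- sum(vapply(0:4, function(k)
      hwe_genotype_prob(p, "exact", k = k), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  # multi-allele set query: lacking either of two alleles at 0.3 total
  p3 <- c(B = 0.15, B2 = 0.15, A = 0.7)
  expect_equal(hwe_genotype_prob(p3, "zero_of_set",
                                 alleles = c("B", "B2")), 0.7^4)
  expect_error(hwe_genotype_prob(c(a = 0.5, b = 0.3), "homozygous"),
               "sum to 1")
})
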