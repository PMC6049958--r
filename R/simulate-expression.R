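#' Simulate negative-binomial expression counts with class structure
#'
#' Generates per-gene counts for populations grouped into three classes
#' (`RW` lowland railway, `MT` mountain, `BGS` focal admixed). Baseline
#' per-gene means are log-normal. Planted differentially expressed genes
#' receive a fold change between RW and MT (direction random); the focal
#' class mean is then set to the MT mean (`mountain_like`), the RW mean
#' (`railway_like`), or their geometric mean (`intermediate`). Counts are
#' negative binomial with gene-level dispersion `dispersion`
#' (`Var = mu + dispersion * mu^2`); `dispersion = 0` gives Poisson
#' counts.
#'
#' @param n_genes Total genes.
#' @param populations Tibble with `population`, `class`
#'   (`RW`/`MT`/`BGS`), `n_reps` (>= 2 for downstream ANOVA).
#' @param n_mountain_like,n_railway_like,n_intermediate Planted DE gene
#'   counts per focal class.
#' @param fold RW-vs-MT fold change of planted DE genes.
#' @param dispersion NB dispersion (>= 0).
#' @param base_log_mean,base_log_sd Log-normal law of baseline means.
#' @param seed Integer RNG seed.
#' @return List with class `expression_sim`: `counts` (genes x samples
#'   integer matrix), `samples` (tibble: sample, population, class),
#'   `truth` (tibble: gene_id, class in
#'   not_de/mountain_like/railway_like/intermediate).
#' @export
simulate_expression <- function(n_genes = 1000L,
                                populations = default_expression_design(),
                                n_mountain_like = 50L,
                                n_railway_like = 25L,
                                n_intermediate = 25L,
                                fold = 4,
                                dispersion = 0.05,
                                base_log_mean = log(100),
                                base_log_sd = 1,
                                seed = 1L) {
  populations <- tibble::as_tibble(populations)
  abort_if(dispersion < 0, "dispersion must be non-negative")
  abort_if(!all(populations$class %in% c("RW", "MT", "BGS")),
           "classes must be RW, MT, BGS")
  abort_if(any(populations$n_reps < 2), "need >= 2 replicates per population")
  n_de <- n_mountain_like + n_railway_like + n_intermediate
  abort_if(n_de > n_genes, "more planted DE genes than genes")
  with_seed(seed, {
    base <- exp(rnorm(n_genes, base_log_mean, base_log_sd))
    cls <- rep("not_de", n_genes)
    de_idx <- sample.int(n_genes, n_de)
    cls[de_idx] <- rep(c("mountain_like", "railway_like", "intermediate"),
                       c(n_mountain_like, n_railway_like, n_intermediate))
    up_in_rw <- runif(n_genes) < 0.5
    mu_mt <- base
    mu_rw <- base
    de <- cls != "not_de"
    mu_rw[de] <- ifelse(up_in_rw[de], base[de] * fold, base[de] / fold)
    mu_bgs <- base
    mu_bgs[cls == "mountain_like"] <- mu_mt[cls == "mountain_like"]
    mu_bgs[cls == "railway_like"] <- mu_rw[cls == "railway_like"]
    mu_bgs[cls == "intermediate"] <-
      sqrt(mu_mt[cls == "intermediate"] * mu_rw[cls == "intermediate"])

    samples <- purrr::pmap_dfr(populations, function(population, class,
                                                     n_reps, ...) {
      tibble::tibble(sample = sprintf("%s_r%d", population,
                                      seq_len(n_reps)),
                     population = population, class = class)
    })
    mu <- cbind(MT = mu_mt, RW = mu_rw, BGS = mu_bgs)
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      m <- mu[, samples$class[j]]
      if (dispersion == 0) as.numeric(stats::rpois(n_genes, m))
      else rnbinom(n_genes, mu = m, size = 1 / dispersion)
    }, numeric(n_genes))
    storage.mode(counts) <- "integer"
    colnames(counts) <- samples$sample
    rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
    structure(list(counts = counts, samples = samples,
                   truth = tibble::tibble(gene_id = rownames(counts),
                                          class = cls)),
              class = "expression_sim")
  })
}

#' Default seven-population expression design
#'
#' Two lowland railway populations, four mountain populations and the
#' focal admixed population, three biological replicates each -- the
#' sampling structure the classifier is built for.
#'
#' @return A populations tibble for [simulate_expression()].
#' @export
default_expression_design <- function() {
  tibble::tibble(
    population = c("TBG", "STE", "KA", "CA2", "HO", "SWA", "BGS"),
    class = c("RW", "RW", "MT", "MT", "MT", "MT", "BGS"),
    n_reps = 3L)
}

#' @export
print.expression_sim <- function(x, ...) {
  cat(sprintf("<expression_sim> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$truth$class))
  invisible(x)
}
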