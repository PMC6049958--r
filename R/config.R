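#' Analysis run configuration
#'
#' Bundles the thresholds shared across the scan, introgression and mapping
#' stages. Defaults follow the study design this package implements:
#' 25-SNP windows, a per-individual depth filter of 4 reads, a minimum of 5
#' genotyped individuals per population and site, gene-level f_d reported
#' only for genes with strictly more than 25 informative SNPs, candidate
#' introgression called at f_d > 3 x genome-wide f_hom, empirical outlier
#' tails of 5%, and 500 phenotype permutations for LOD significance.
#'
#' @param window_size_snps Number of usable SNPs per scan window.
#' @param min_depth Minimum per-individual sequencing depth; genotypes below
#'   it are treated as missing.
#' @param min_individuals Minimum genotyped individuals per population for a
#'   site to contribute a frequency.
#' @param fd_multiplier Candidate rule multiplier on genome-wide f_hom.
#' @param min_informative_snps_per_gene Strict lower bound on informative
#'   SNPs for a gene-level f_d estimate (a gene with exactly this many is
#'   dropped).
#' @param outlier_quantiles Named list of tail quantiles for `gst`, `h`,
#'   `tajd`; each in (0, 0.5].
#' @param permutations Phenotype permutations for the LOD threshold.
#' @param rng_seed Integer seed recorded with every simulated dataset.
#' @return A list with class `run_config`.
#' @export
run_config <- function(window_size_snps = 25L,
                       min_depth = 4L,
                       min_individuals = 5L,
                       fd_multiplier = 3,
                       min_informative_snps_per_gene = 25L,
                       outlier_quantiles = list(gst = 0.05, h = 0.05,
                                                tajd = 0.05),
                       permutations = 500L,
                       rng_seed = 1L) {
  cfg <- list(
    window_size_snps = check_count(window_size_snps),
    min_depth = check_count(min_depth, min = 0L),
    min_individuals = check_count(min_individuals),
    fd_multiplier = fd_multiplier,
    min_informative_snps_per_gene = check_count(min_informative_snps_per_gene),
    outlier_quantiles = outlier_quantiles,
    permutations = check_count(permutations),
    rng_seed = check_count(rng_seed, min = 0L)
  )
  abort_if(fd_multiplier <= 0, "`fd_multiplier` must be positive")
  qs <- unlist(outlier_quantiles)
  abort_if(any(qs <= 0 | qs > 0.5),
           "`outlier_quantiles` must lie in (0, 0.5]")
  structure(cfg, class = "run_config")
}

#' Read or write a run configuration as a key-value text file
#'
#' Lines are `key = value`; list-valued entries (`outlier_quantiles`) use
#' dotted keys such as `outlier_quantiles.gst`.
#'
#' @param path File path.
#' @param config A [run_config()] object (for writing).
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  args <- list()
  oq <- run_config()$outlier_quantiles
  for (i in seq_along(keys)) {
    k <- trimws(keys[i]); v <- as.numeric(vals[i])
    if (startsWith(k, "outlier_quantiles.")) {
      oq[[sub("^outlier_quantiles\\.", "", k)]] <- v
    } else args[[k]] <- v
  }
  args$outlier_quantiles <- oq
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- config
  oq <- flat$outlier_quantiles
  flat$outlier_quantiles <- NULL
  lines <- c(
    sprintf("%s = %s", names(flat), vapply(flat, format, "")),
    sprintf("outlier_quantiles.%s = %s", names(oq), vapply(oq, format, ""))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in setdiff(names(x), "outlier_quantiles"))
    cat(sprintf("  %-30s %s\n", k, format(x[[k]])))
  for (k in names(x$outlier_quantiles))
    cat(sprintf("  outlier_quantiles.%-12s %s\n", k,
                format(x$outlier_quantiles[[k]])))
  invisible(x)
}
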