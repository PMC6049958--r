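#' Read tetraploid genotypes from a VCF
#'
#' Reads a VCF 4.x file into a [geno_panel()]. Only biallelic SNPs are kept;
#' genotypes whose per-sample depth (FORMAT `DP`) is below `min_depth` are
#' set missing; genotype fields with an arity other than 1, 2 or 4 cause the
#' record to be rejected with a warning. Phase separators (`|` vs `/`) are
#' ignored: every statistic downstream is frequency-based, so genotypes are
#' reduced to ALT-allele dosage.
#'
#' @param path VCF file (plain or bgzipped).
#' @param samples Tibble mapping `sample` to `population` (and optionally
#'   `ploidy`). Samples absent from it are dropped. If `NULL`, all samples
#'   are kept in population `"pop1"` with ploidy inferred from the first
#'   record.
#' @param min_depth Per-individual depth filter; genotypes with `DP <`
#'   this are set missing. Default 4.
#' @param min_individuals Populations with fewer non-missing genotypes at a
#'   site are flagged in the `low_n` attribute (sites are kept; frequency
#'   estimation applies the filter). Default 5.
#' @return A `geno_panel`; attribute `low_n` is a tibble of
#'   (site, population) pairs failing `min_individuals`.
#' @export
read_vcf <- function(path, samples = NULL, min_depth = 4L,
                     min_individuals = 5L) {
  abort_if(!file.exists(path), sprintf("cannot read VCF '%s'", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                          as.numeric = TRUE))

  # biallelic SNPs only
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
  if (any(!keep))
    message(sprintf("read_vcf: dropped %d non-biallelic/non-SNP records",
                    sum(!keep)))
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[keep, , drop = FALSE]

  parsed <- parse_gt_matrix(gt_raw)
  dos <- parsed$dosage
  colnames(dos) <- colnames(gt_raw)
  if (length(parsed$bad_rows)) {
    warning(sprintf(
      "read_vcf: rejected %d records with malformed GT arity",
      length(parsed$bad_rows)), call. = FALSE)
    ok <- setdiff(seq_len(nrow(fix)), parsed$bad_rows)
    fix <- fix[ok, , drop = FALSE]
    dos <- dos[ok, , drop = FALSE]
    ploidy <- parsed$ploidy[ok, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ok, , drop = FALSE]
  } else ploidy <- parsed$ploidy

  if (!is.null(dp)) dos[!is.na(dp) & dp < min_depth] <- NA_integer_

  sample_ploidy <- apply(ploidy, 2, function(p) {
    p <- p[!is.na(p)]
    if (!length(p)) 4L else as.integer(max(p))
  })
  if (is.null(samples)) {
    samples <- tibble::tibble(sample = colnames(gt_raw),
                              population = "pop1",
                              ploidy = sample_ploidy)
  } else {
    samples <- tibble::as_tibble(samples)
    if (!"ploidy" %in% names(samples))
      samples$ploidy <- sample_ploidy[match(samples$sample,
                                            colnames(gt_raw))]
    missing_s <- setdiff(samples$sample, colnames(gt_raw))
    abort_if(length(missing_s) > 0,
             sprintf("samples not in VCF: %s",
                     paste(missing_s, collapse = ", ")))
  }
  dos <- dos[, samples$sample, drop = FALSE]

  panel <- geno_panel(
    sites = tibble::tibble(scaffold = fix$CHROM,
                           position = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT),
    geno = dos, samples = samples)

  n_ok <- site_pop_counts(panel)
  low <- which(n_ok < min_individuals, arr.ind = TRUE)
  attr(panel, "low_n") <- tibble::tibble(
    site = low[, 1], population = colnames(n_ok)[low[, 2]])
  panel
}

# Parse a character GT matrix to dosage + ploidy; flag rows with bad arity.
parse_gt_matrix <- function(gt) {
  n_allele <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & x != "." & x != "./." & !grepl("^\\.(\\/\\.)*$", x)
    toks <- strsplit(x[ok], "[/|]")
    out[ok] <- lengths(toks)
    list(arity = out, toks = toks, ok = ok)
  }
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  ploidy <- matrix(NA_integer_, nrow(gt), ncol(gt))
  for (j in seq_len(ncol(gt))) {
    p <- n_allele(gt[, j])
    d <- rep(NA_integer_, nrow(gt))
    if (any(p$ok)) {
      vals <- vapply(p$toks, function(t) {
        if (any(t == ".")) return(NA_integer_)
        sum(t == "1")
      }, integer(1))
      d[p$ok] <- vals
    }
    dosage[, j] <- d
    ploidy[, j] <- p$arity
  }
  bad <- which(apply(ploidy, 1, function(a) {
    a <- a[!is.na(a)]
    length(a) > 0 && any(!a %in% c(1L, 2L, 4L))
  }))
  list(dosage = dosage, ploidy = ploidy, bad_rows = bad)
}

# per-site, per-population non-missing individual counts
site_pop_counts <- function(panel) {
  pops <- unique(panel$samples$population)
  out <- vapply(pops, function(p) {
    cols <- which(panel$samples$population == p)
    rowSums(!is.na(panel$geno[, cols, drop = FALSE]))
  }, numeric(nrow(panel$sites)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, pops))
  out
}

#' Write a genotype panel as VCF 4.2
#'
#' Deterministic text serializer for tetraploid (and mixed-ploidy) dosage
#' panels: dosage `d` becomes an unphased GT of `ploidy - d` REF and `d`
#' ALT alleles (e.g. dosage 1, ploidy 4 -> `0/0/0/1`). A constant or
#' supplied per-genotype depth is written as FORMAT `DP`.
#'
#' @param panel A [geno_panel()].
#' @param path Output path.
#' @param depth Integer depth written per genotype (scalar or matrix the
#'   shape of `panel$geno`). Default 30.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, depth = 30L) {
  stopifnot(inherits(panel, "geno_panel"))
  n_s <- nrow(panel$sites); n_i <- nrow(panel$samples)
  if (length(depth) == 1L) depth <- matrix(depth, n_s, n_i)
  gt <- matrix("", n_s, n_i)
  for (j in seq_len(n_i)) {
    pl <- panel$samples$ploidy[j]
    d <- panel$geno[, j]
    gt_strings <- vapply(0:pl, function(k)
      paste(c(rep("0", pl - k), rep("1", k)), collapse = "/"), "")
    col <- rep(paste(rep(".", pl), collapse = "/"), n_s)
    col[!is.na(d)] <- gt_strings[d[!is.na(d)] + 1L]
    gt[, j] <- paste0(col, ":", depth[, j])
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetrascan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample), collapse = "\t"))
  body <- paste(panel$sites$scaffold, panel$sites$position, ".",
                panel$sites$ref %||% "A", panel$sites$alt %||% "T",
                ".", "PASS", ".", "GT:DP",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
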