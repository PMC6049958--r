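#' Frequency-weighted ABBA / BABA site patterns
#'
#' For derived-allele frequencies of a (((P1,P2),P3),O) quartet,
#' `abba = (1-p1) p2 p3 (1-pO)` and `baba = p1 (1-p2) p3 (1-pO)` -- the
#' expected fractions of chromosome quartets showing each discordant
#' pattern.
#'
#' @param p1,p2,p3,po Numeric vectors of derived-allele frequencies.
#' @return Tibble with columns `abba` and `baba`.
#' @export
site_patterns <- function(p1, p2, p3, po) {
  tibble::tibble(abba = (1 - p1) * p2 * p3 * (1 - po),
                 baba = p1 * (1 - p2) * p3 * (1 - po))
}

#' Specify the (((P1,P2),P3),O) quartet roles
#'
#' @param p1 Background population, `p2` the focal/admixed population,
#'   `p3` the candidate donor, `o` the outgroup.
#' @param p2,p3,o See `p1`.
#' @return A named character vector with class `quartet`.
#' @export
quartet <- function(p1, p2, p3, o) {
  q <- c(P1 = p1, P2 = p2, P3 = p3, O = o)
  abort_if(anyDuplicated(q) > 0, "quartet labels must be distinct")
  structure(q, class = "quartet")
}

# Per-site quartet table restricted to informative sites: biallelic,
# polarizable, non-missing in all four populations, abba + baba > 0.
quartet_sites <- function(freqs, q) {
  fm <- freqs_matrix(freqs, unname(q))
  p <- fm$p
  ok <- fm$sites$polarizable & rowSums(is.na(p)) == 0
  sp <- site_patterns(p[, 1], p[, 2], p[, 3], p[, 4])
  inf <- ok & (sp$abba + sp$baba) > 0
  tibble::tibble(site = fm$sites$site,
                 scaffold = fm$sites$scaffold,
                 position = fm$sites$position,
                 p1 = p[, 1], p2 = p[, 2], p3 = p[, 3], po = p[, 4],
                 abba = sp$abba, baba = sp$baba)[inf, ]
}

#' Patterson's D statistic with block-jackknife error
#'
#' `D = sum(abba - baba) / sum(abba + baba)` over informative sites, with
#' a delete-one-block jackknife standard deviation over contiguous blocks
#' of informative SNPs.
#'
#' @param freqs Frequency tibble from [estimate_frequencies()].
#' @param q A [quartet()].
#' @param block_size_snps Jackknife block size in informative SNPs
#'   (default 1000); `NULL` skips the jackknife.
#' @return One-row tibble: quartet labels, `statistic`, `value`,
#'   `jackknife_sd`, `n_informative`, `n_blocks`.
#' @export
patterson_d <- function(freqs, q, block_size_snps = 1000L) {
  qs <- quartet_sites(freqs, q)
  quartet_ratio(qs, q, "D",
                num = qs$abba - qs$baba,
                den = qs$abba + qs$baba,
                block_size_snps)
}

#' Genome-wide introgressed fraction f_hom
#'
#' `f_hom = S(P1,P2,P3,O) / S(P1,P3,P3,O)` with
#' `S = sum(abba - baba)`: the observed allele-sharing excess scaled by
#' the value it would take had the focal population been entirely
#' replaced by the (homogeneous) donor -- P3's frequency substituted in
#' the P2 slot of the denominator.
#'
#' @inheritParams patterson_d
#' @return One-row tibble as in [patterson_d()].
#' @export
f_hom <- function(freqs, q, block_size_snps = 1000L) {
  qs <- quartet_sites(freqs, q)
  den_sp <- site_patterns(qs$p1, qs$p3, qs$p3, qs$po)
  out <- quartet_ratio(qs, q, "f_hom",
                       num = qs$abba - qs$baba,
                       den = den_sp$abba - den_sp$baba,
                       block_size_snps)
  if (!is.na(out$value) && sum(den_sp$abba - den_sp$baba) <= 0) {
    warning("f_hom denominator <= 0; returning NA", call. = FALSE)
    out$value <- NA_real_
  }
  out
}

quartet_ratio <- function(qs, q, statistic, num, den, block_size_snps) {
  n_inf <- nrow(qs)
  val <- if (n_inf == 0 || sum(den) == 0) NA_real_ else
    sum(num) / sum(den)
  sd_jk <- NA_real_
  n_blocks <- NA_integer_
  if (!is.null(block_size_snps) && n_inf > 0) {
    jk <- block_jackknife_ratio(num, den, block_size_snps)
    sd_jk <- jk$sd
    n_blocks <- jk$n_blocks
  }
  tibble::tibble(P1 = q[["P1"]], P2 = q[["P2"]], P3 = q[["P3"]],
                 O = q[["O"]], statistic = statistic, value = val,
                 jackknife_sd = sd_jk, n_informative = n_inf,
                 n_blocks = n_blocks)
}

#' Delete-one-block jackknife SD of a ratio-of-sums statistic
#'
#' Blocks are contiguous runs of `block_size_snps` informative sites.
#' The SD is `sqrt((B-1)/B * sum((theta_b - mean(theta_b))^2))` over the
#' leave-one-block-out values `theta_b`.
#'
#' @param num,den Per-site numerator and denominator contributions.
#' @param block_size_snps Sites per block.
#' @return List with `sd` and `n_blocks`.
#' @export
block_jackknife_ratio <- function(num, den, block_size_snps = 1000L) {
  n <- length(num)
  blk <- (seq_len(n) - 1L) %/% as.integer(block_size_snps) + 1L
  b <- max(blk)
  abort_if(b < 10,
           paste("fewer than 10 jackknife blocks; use more data or a",
                 "smaller block size"))
  num_b <- tapply(num, blk, sum)
  den_b <- tapply(den, blk, sum)
  loo <- (sum(num_b) - num_b) / (sum(den_b) - den_b)
  list(sd = sqrt((b - 1) / b * sum((loo - mean(loo))^2)),
       n_blocks = b)
}

#' Windowed / subset introgression fraction f_d
#'
#' `f_d = S(P1,P2,P3,O) / S(P1,P_D,P_D,O)` where per site `P_D` is
#' whichever of P2, P3 carries the higher derived frequency -- the
#' dynamic donor making the estimator stable in small windows. A
#' negative numerator is reported as 0 (regions with D <= 0 carry no
#' introgression signal); a zero denominator gives `NA`.
#'
#' @param qs A quartet site table from the internal machinery, or a
#'   frequency tibble when `q` is supplied.
#' @param q A [quartet()] (when `qs` is a frequency tibble).
#' @param sites Optional site ids restricting the subset (a gene or
#'   window).
#' @return A single f_d value.
#' @export
f_d <- function(qs, q = NULL, sites = NULL) {
  if (!is.null(q)) qs <- quartet_sites(qs, q)
  if (!is.null(sites)) qs <- qs[qs$site %in% sites, ]
  f_d_from_sites(qs)
}

f_d_from_sites <- function(qs) {
  if (!nrow(qs)) return(NA_real_)
  pd <- pmax(qs$p2, qs$p3)
  den <- sum((1 - qs$p1) * pd * pd * (1 - qs$po) -
               qs$p1 * (1 - pd) * pd * (1 - qs$po))
  num <- sum(qs$abba - qs$baba)
  if (num < 0) return(0)
  if (den == 0) return(NA_real_)
  num / den
}

#' Gene-level f_d scan
#'
#' Computes f_d per gene and quartet over the informative SNPs whose
#' positions fall inside the gene interval; genes are reported only when
#' they have strictly more than `min_informative` informative SNPs in
#' that quartet.
#'
#' @param freqs Frequency tibble from [estimate_frequencies()].
#' @param genes Gene annotation tibble from [read_gff_genes()].
#' @param quartets List of [quartet()] objects.
#' @param min_informative Strict lower bound on informative SNPs per
#'   gene (default 25: a gene with exactly 25 is omitted).
#' @return Tibble: `gene_id`, `P1`, `P2`, `P3`, `O`, `f_d`,
#'   `n_informative`.
#' @export
gene_fd_scan <- function(freqs, genes, quartets, min_informative = 25L) {
  abort_if(!length(quartets), "need at least one quartet")
  if (inherits(quartets, "quartet")) quartets <- list(quartets)
  genes <- tibble::as_tibble(genes)
  out <- purrr::map_dfr(quartets, function(q) {
    qs <- quartet_sites(freqs, q)
    hits <- dplyr::inner_join(
      qs, genes,
      by = dplyr::join_by(scaffold, position >= start, position <= end))
    if (!nrow(hits)) return(tibble::tibble())
    hits |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::group_modify(~ tibble::tibble(
        f_d = f_d_from_sites(.x), n_informative = nrow(.x))) |>
      dplyr::ungroup() |>
      dplyr::mutate(P1 = q[["P1"]], P2 = q[["P2"]], P3 = q[["P3"]],
                    O = q[["O"]], .after = "gene_id")
  })
  if (!nrow(out)) {
    warning("no genes overlap any informative site", call. = FALSE)
    return(out)
  }
  dplyr::filter(out, .data$n_informative > min_informative)
}

#' Call candidate introgressed genes
#'
#' A gene is called when its f_d exceeds `multiplier` times the
#' corresponding quartet's genome-wide f_hom in every quartet supplied
#' (genes missing an estimate in any quartet cannot satisfy the rule and
#' are excluded). The rule presupposes a positive genome-wide
#' introgression scale: quartets whose f_hom is not positive -- or, when
#' a jackknife SD is available, not above `min_z` SDs -- yield no calls.
#'
#' @param gene_fd Gene table from [gene_fd_scan()].
#' @param fhom_table Tibble from [f_hom()] rows for the same quartets
#'   (columns `P1`, `P3`, `value`, optionally `jackknife_sd`).
#' @param multiplier f_d threshold multiplier (default 3).
#' @param min_z Required f_hom z-score when a jackknife SD is present
#'   (default 2).
#' @return Tibble of called genes: `gene_id`, `n_quartets`, `min_ratio`
#'   (smallest f_d / f_hom across quartets).
#' @export
call_candidates <- function(gene_fd, fhom_table, multiplier = 3,
                            min_z = 2) {
  fh <- tibble::as_tibble(fhom_table)
  n_required <- nrow(fh)
  ok <- !is.na(fh$value) & fh$value > 0
  if ("jackknife_sd" %in% names(fh))
    ok <- ok & (is.na(fh$jackknife_sd) |
                  fh$value > min_z * fh$jackknife_sd)
  if (!all(ok)) {
    message("call_candidates: no positive genome-wide f_hom scale in ",
            sum(!ok), " quartet(s); no candidates called")
    return(tibble::tibble(gene_id = character(),
                          n_quartets = integer(),
                          min_ratio = numeric()))
  }
  gene_fd |>
    dplyr::inner_join(fh[c("P1", "P3", "value")],
                      by = c("P1", "P3"), suffix = c("", "_fhom")) |>
    dplyr::mutate(ratio = .data$f_d / .data$value) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_quartets = dplyr::n(),
                     min_ratio = min(.data$ratio),
                     pass = all(.data$f_d > multiplier * .data$value)) |>
    dplyr::filter(.data$n_quartets == n_required, .data$pass) |>
    dplyr::select(-"pass")
}
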