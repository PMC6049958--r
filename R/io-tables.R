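#' Deterministic TSV output
#'
#' Writes a data frame as TSV with a header, a fixed column order (as
#' given), `NA` for missing values, and floating-point columns rendered at
#' 6 significant digits so identical analyses produce byte-identical files.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  out <- tibble::as_tibble(records)
  is_dbl <- vapply(out, is.double, logical(1))
  out[is_dbl] <- lapply(out[is_dbl], format_num)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                  progress = FALSE)
}

#' Export windows as BED
#'
#' Converts 1-based closed window spans to BED's 0-based half-open
#' intervals.
#'
#' @param windows Tibble with `scaffold`, `start_bp`, `end_bp` and
#'   optionally a `value` column written as the BED score.
#' @param path Output path.
#' @param value Optional column name used for the BED name/score field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path, value = NULL) {
  df <- tibble::tibble(chrom = windows$scaffold,
                       start = windows$start_bp - 1L,
                       end = windows$end_bp)
  if (!is.null(value)) df$name <- format_num(windows[[value]])
  readr::write_tsv(df, path, col_names = FALSE, na = "NA",
                   progress = FALSE)
  invisible(path)
}
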