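#' Read gene annotations from GFF3
#'
#' Imports features of type `gene` and returns sorted, deduplicated
#' 1-based closed intervals. Duplicated `gene_id`s are an error (the
#' gene-level scans key on them).
#'
#' @param path GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return Tibble with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, sorted by (scaffold, start).
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  abort_if(!file.exists(path), sprintf("cannot read GFF '%s'", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (!length(gr)) {
    warning("read_gff_genes: no gene features found", call. = FALSE)
    return(tibble::tibble(gene_id = character(), scaffold = character(),
                          start = integer(), end = integer(),
                          strand = character()))
  }
  ids <- gr$ID %||% gr$Name %||% gr$gene_id
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  genes <- tibble::tibble(
    gene_id = as.character(ids),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$scaffold, .data$start, .data$end)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  abort_if(length(dup) > 0,
           sprintf("duplicated gene_id in GFF: %s",
                   paste(unique(dup), collapse = ", ")))
  genes$strand[!genes$strand %in% c("+", "-")] <- "."
  genes
}

#' Write gene annotations as GFF3
#'
#' Companion writer for simulator output so annotations round-trip through
#' [read_gff_genes()].
#'
#' @param genes Tibble as returned by [read_gff_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  abort_if(any(genes$end < genes$start), "gene end < start")
  lines <- c("##gff-version 3",
             paste(genes$scaffold, "tetrascan", "gene", genes$start,
                   genes$end, ".", genes$strand %||% ".", ".",
                   paste0("ID=", genes$gene_id), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
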