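#' Read protein sequences into a tibble
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning the tabular
#' form used throughout the package: one row per record with `accession`
#' (first whitespace-delimited token of the FASTA header) and `sequence`.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param taxon_map Optional path to a two-column tab-separated file
#'   (`accession<TAB>clade`, no header) used to attach a `clade` column.
#'
#' @return A tibble with columns `accession`, `sequence`, and, when
#'   `taxon_map` is supplied, `clade` (`NA` for unmapped accessions).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MAYPGAYPGA"), fa)
#' read_fasta_tbl(fa)
read_fasta_tbl <- function(path, taxon_map = NULL) {
  set <- Biostrings::readAAStringSet(path)
  out <- tibble::tibble(
    accession = vapply(
      strsplit(names(set), "\\s+"), `[[`, character(1), 1L
    ),
    sequence = as.character(set)
  )
  if (!is.null(taxon_map)) {
    map <- read.delim(
      taxon_map, header = FALSE, col.names = c("accession", "clade"),
      colClasses = "character"
    )
    out <- dplyr::left_join(out, tibble::as_tibble(map), by = "accession")
  }
  out
}

#' Write a sequence tibble to FASTA
#'
#' @param records Tibble with columns `accession` and `sequence`.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(records, path) {
  check_cols(records, c("accession", "sequence"), "records")
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$accession))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
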