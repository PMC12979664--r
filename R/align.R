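# Homolog detection: a Smith-Waterman local-alignment identity filter
# standing in for a BLAST-vs-database search, plus an importer for external
# tabular hit lists so published hits can be consumed verbatim.

#' Local alignment with percent identity
#'
#' Optimal local (Smith-Waterman) alignment of two protein sequences under
#' either BLOSUM62 with affine gaps (default, opening 11 / extension 1) or a
#' simple match/mismatch scheme with linear gaps.  Percent identity is
#' computed BLAST-like over all alignment columns, gaps included.
#' Nonstandard letters without a substitution score (U/J/O) are mapped to X,
#' which scores as a mismatch-level residue; this policy is recorded in the
#' result.
#'
#' @param query,target Amino-acid sequences (single strings).
#' @param scoring `"blosum62"` (affine gaps) or `"simple"` (match/mismatch,
#'   linear gaps).
#' @param gap_opening,gap_extension Gap penalties (positive costs).  Defaults
#'   11/1 for `"blosum62"`; for `"simple"`, set `gap_opening = 0` and
#'   `gap_extension` to the per-gap cost to obtain linear gap scoring.
#' @param match,mismatch Scores used when `scoring = "simple"`.
#'
#' @return One-row tibble: `query`, `target` (the sequences), `score`,
#'   `percent_identity`, `target_start`, `target_end` (1-based inclusive
#'   span on the target), `aln_length` (columns incl. gaps), `n_identical`,
#'   `nonstandard_policy`.
#' @export
#' @examples
#' a <- strrep("MKV", 10)
#' align_identity(a, a)$percent_identity
align_identity <- function(query, target,
                           scoring = c("blosum62", "simple"),
                           gap_opening = NULL, gap_extension = NULL,
                           match = 2, mismatch = -1) {
  scoring <- match.arg(scoring)
  query <- check_sequence(query, "query")
  target <- check_sequence(target, "target")

  sanitize <- function(x) gsub("[UJO]", "X", x)
  q <- sanitize(query)
  t <- sanitize(target)

  if (scoring == "blosum62") {
    mat <- get_blosum62()
    if (is.null(gap_opening)) gap_opening <- 11
    if (is.null(gap_extension)) gap_extension <- 1
  } else {
    letters24 <- c(AA_STANDARD, "X", "B", "Z")
    mat <- matrix(mismatch, length(letters24), length(letters24),
      dimnames = list(letters24, letters24)
    )
    diag(mat) <- match
    if (is.null(gap_opening)) gap_opening <- 0
    if (is.null(gap_extension)) gap_extension <- 2
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  cols_p <- seq_chars(pat)
  cols_s <- seq_chars(sub)
  n_ident <- sum(cols_p == cols_s & cols_p != "-")
  n_cols <- length(cols_p)
  tibble::tibble(
    query = query, target = target,
    score = Biostrings::score(aln),
    percent_identity = if (n_cols > 0) 100 * n_ident / n_cols else 0,
    target_start = Biostrings::start(Biostrings::subject(aln)),
    target_end = Biostrings::end(Biostrings::subject(aln)),
    aln_length = n_cols, n_identical = n_ident,
    nonstandard_policy = "U/J/O mapped to X; identity over all columns incl. gaps"
  )
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Align every record against a reference CRD
#'
#' Runs [align_identity()] of each sequence in `records` against a reference
#' carbohydrate-recognition domain and appends the identity columns.
#'
#' @param records Tibble with `accession` and `sequence`.
#' @param reference Reference CRD sequence (query of the search).
#' @param ... Passed to [align_identity()].
#'
#' @return `records` with `percent_identity`, `score`, `target_start`,
#'   `target_end`, `aln_length` columns added.
#' @export
align_records <- function(records, reference, ...) {
  check_cols(records, c("accession", "sequence"), "records")
  hits <- purrr::map(
    records$sequence,
    function(s) {
      align_identity(reference, s, ...)[
        c("percent_identity", "score", "target_start", "target_end", "aln_length")
      ]
    }
  )
  dplyr::bind_cols(records, dplyr::bind_rows(hits))
}

#' Import an external tabular hit list
#'
#' Reads BLAST-style tabular output (default `outfmt 6` column order) so that
#' hits from a full database search can enter the screening funnel verbatim.
#' E-values are passed through as metadata; filtering is on identity (and
#' optionally alignment length), since no database size is available to
#' calibrate an E-value against.
#'
#' @param path Path to a tab-separated hit table without header.
#' @param col_names Column names, by default the 12 standard BLAST tabular
#'   columns.
#'
#' @return Tibble with at least `query`, `accession`, `percent_identity`,
#'   `aln_length`, `evalue`.
#' @export
read_hit_table <- function(path,
                           col_names = c(
                             "query", "accession", "percent_identity",
                             "aln_length", "mismatches", "gap_opens",
                             "query_start", "query_end", "target_start",
                             "target_end", "evalue", "bit_score"
                           )) {
  df <- read.delim(path, header = FALSE, col.names = col_names)
  tibble::as_tibble(df)
}

#' Filter hits on percent identity
#'
#' Keeps hits with `percent_identity >= identity_min` (the screening funnel's
#' "at least 21% identity" criterion) and, optionally, a minimum alignment
#' length.
#'
#' @param hits Tibble with `percent_identity` (and `aln_length` if
#'   `min_aln_length` is used).
#' @param identity_min Identity threshold in percent (kept if `>=`).
#' @param min_aln_length Minimum alignment length in columns.
#'
#' @return The filtered tibble.
#' @export
filter_hits <- function(hits, identity_min = 21, min_aln_length = 0) {
  check_cols(hits, "percent_identity", "hits")
  out <- dplyr::filter(hits, .data$percent_identity >= identity_min)
  if (min_aln_length > 0) {
    check_cols(out, "aln_length", "hits")
    out <- dplyr::filter(out, .data$aln_length >= min_aln_length)
  }
  out
}
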