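# Disordered-stretch calling, IDR composition profiling and filtering, and
# clade-level aromatic statistics: the stages of the screening funnel that
# sit downstream of homolog detection.

#' Call maximal disordered stretches from per-residue scores
#'
#' Finds, per accession, every maximal run of consecutive positions with
#' disorder score strictly greater than `threshold` and run length at least
#' `min_len` (defaults: the ">0.5 for at least 75 consecutive residues"
#' criterion).  All qualifying stretches are reported; the longest one per
#' accession is tagged `primary` (ties broken towards the N-terminus).
#'
#' @param scores Tibble with columns `accession`, `position` (1-based,
#'   consecutive within each accession), `score` in \[0, 1\].
#' @param threshold Disorder score threshold (strictly greater than).
#' @param min_len Minimum stretch length in residues.
#'
#' @return Tibble `accession`, `start`, `end` (1-based inclusive), `length`,
#'   `primary`; zero rows when nothing qualifies.
#' @export
#' @examples
#' sc <- tibble::tibble(
#'   accession = "p1", position = 1:100,
#'   score = c(rep(0.9, 80), rep(0.1, 20))
#' )
#' call_idr_stretches(sc, min_len = 75)
call_idr_stretches <- function(scores, threshold = 0.5, min_len = 75) {
  check_cols(scores, c("accession", "position", "score"), "scores")
  if (any(scores$score < 0 | scores$score > 1, na.rm = TRUE)) {
    abort("disorder scores must lie in [0, 1].")
  }
  empty <- tibble::tibble(
    accession = character(), start = integer(), end = integer(),
    length = integer(), primary = logical()
  )
  if (nrow(scores) == 0) {
    return(empty)
  }
  per_acc <- function(df) {
    df <- df[order(df$position), ]
    if (any(diff(df$position) != 1)) {
      abort(sprintf(
        "positions for accession '%s' are not consecutive.", df$accession[1]
      ))
    }
    r <- rle(df$score > threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) {
      return(NULL)
    }
    tibble::tibble(
      accession = df$accession[1],
      start = df$position[starts[keep]],
      end = df$position[ends[keep]],
      length = r$lengths[keep]
    )
  }
  out <- dplyr::bind_rows(
    empty[, 1:4],
    dplyr::bind_rows(unname(purrr::map(split(scores, scores$accession), per_acc)))
  )
  out <- out[order(out$accession, out$start), ]
  dplyr::mutate(
    dplyr::group_by(out, .data$accession),
    primary = seq_along(.data$length) == which.max(.data$length)
  ) |>
    dplyr::ungroup()
}

#' Amino-acid class composition of a sequence
#'
#' Exact counting over the residue-class partition used by the screening
#' funnel: aromatic (F+Y+W), negatively charged (D+E), positively charged
#' (K+R), proline, glycine, alanine, `other` (remaining standard residues),
#' and `nonstandard` (X/B/Z/U/J/O: excluded from every class numerator but
#' kept in the length denominator).  The eight class percentages partition
#' the sequence and sum to 100.
#'
#' @param sequence Amino-acid string.
#'
#' @return One-row tibble with `length`, class percentages `pct_aromatic`,
#'   `pct_negative`, `pct_positive`, `pct_P`, `pct_G`, `pct_A`, `pct_other`,
#'   `pct_nonstandard`, and the individual `pct_F`, `pct_Y`, `pct_W`.
#' @export
#' @examples
#' composition_profile("YYYYDAAAAA")[, c("pct_aromatic", "pct_negative")]
composition_profile <- function(sequence) {
  sequence <- check_sequence(sequence)
  chars <- seq_chars(sequence)
  n <- length(chars)
  pct <- function(set) 100 * sum(chars %in% set) / n
  tibble::tibble(
    length = n,
    pct_aromatic = pct(AA_AROMATIC),
    pct_negative = pct(AA_NEGATIVE),
    pct_positive = pct(AA_POSITIVE),
    pct_P = pct("P"),
    pct_G = pct("G"),
    pct_A = pct("A"),
    pct_other = pct(setdiff(
      AA_STANDARD, c(AA_AROMATIC, AA_NEGATIVE, AA_POSITIVE, "P", "G", "A")
    )),
    pct_nonstandard = pct(AA_NONSTANDARD),
    pct_F = pct("F"),
    pct_Y = pct("Y"),
    pct_W = pct("W")
  )
}

#' Composition profiles of called IDR stretches
#'
#' Slices each annotated stretch out of its parent sequence and profiles it
#' with [composition_profile()].
#'
#' @param annotations Stretch tibble from [call_idr_stretches()] (needs
#'   `accession`, `start`, `end`).
#' @param records Sequence tibble with `accession`, `sequence`.
#'
#' @return `annotations` with an `idr_seq` column and all composition
#'   columns appended.
#' @export
idr_composition <- function(annotations, records) {
  check_cols(annotations, c("accession", "start", "end"), "annotations")
  check_cols(records, c("accession", "sequence"), "records")
  seqs <- records$sequence[match(annotations$accession, records$accession)]
  if (anyNA(seqs)) {
    abort("some annotated accessions are missing from `records`.")
  }
  if (nrow(annotations) == 0) {
    proto <- composition_profile("A")[0, ]
    proto$length <- NULL
    return(dplyr::bind_cols(
      annotations, tibble::tibble(idr_seq = character()), proto
    ))
  }
  slices <- substr(seqs, annotations$start, annotations$end)
  comp <- dplyr::bind_rows(purrr::map(slices, composition_profile))
  comp$length <- NULL # the annotation already carries the stretch length
  dplyr::bind_cols(annotations, tibble::tibble(idr_seq = slices), comp)
}

#' Apply the aromatic/acidic composition filter
#'
#' The funnel's composition criterion: an IDR passes when its aromatic
#' content is strictly greater than `aromatic_min` percent AND its
#' negatively charged content is strictly less than `negative_max` percent
#' (defaults 8 and 3; both comparisons strict, so exactly 8% aromatic
#' fails).
#'
#' @param profiles Tibble with `pct_aromatic` and `pct_negative` (e.g. from
#'   [idr_composition()]).
#' @param aromatic_min Aromatic percentage threshold (strict `>`).
#' @param negative_max Negative-residue percentage threshold (strict `<`).
#'
#' @return `profiles` with a logical `pass_filter` column appended.
#' @export
composition_filter <- function(profiles, aromatic_min = 8, negative_max = 3) {
  check_cols(profiles, c("pct_aromatic", "pct_negative"), "profiles")
  dplyr::mutate(
    profiles,
    pass_filter = .data$pct_aromatic > aromatic_min &
      .data$pct_negative < negative_max
  )
}

#' Clade-level distribution statistics of aromatic content
#'
#' Tukey boxplot statistics of %W, %F and %Y per clade: median, quartiles
#' (linear-interpolation convention, [stats::quantile()] type 7), IQR, and
#' whiskers at the most extreme data points within 1.5 x IQR of the
#' quartiles.
#'
#' @param profiles Tibble with `clade`, `pct_F`, `pct_Y`, `pct_W`.  Rows with
#'   missing clade are dropped with a warning.
#'
#' @return Tibble `clade`, `metric` (`pct_W`/`pct_F`/`pct_Y`), `n`, `median`,
#'   `q1`, `q3`, `iqr`, `whisker_low`, `whisker_high`.
#' @export
clade_aromatic_stats <- function(profiles) {
  check_cols(profiles, c("clade", "pct_F", "pct_Y", "pct_W"), "profiles")
  if (anyNA(profiles$clade)) {
    warn("dropping rows with missing clade label.")
    profiles <- profiles[!is.na(profiles$clade), ]
  }
  long <- tidyr::pivot_longer(
    profiles[, c("clade", "pct_W", "pct_F", "pct_Y")],
    cols = c("pct_W", "pct_F", "pct_Y"),
    names_to = "metric", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, .data$clade, .data$metric),
    n = dplyr::n(),
    median = median(.data$value),
    q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
    q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
    iqr = .data$q3 - .data$q1,
    whisker_low = min(.data$value[.data$value >= .data$q1 - 1.5 * .data$iqr]),
    whisker_high = max(.data$value[.data$value <= .data$q3 + 1.5 * .data$iqr]),
    .groups = "drop"
  )
}

#' Run the full screening funnel
#'
#' Chains the screening stages: local-alignment identity against a reference
#' CRD (kept if `percent_identity >= identity_min`), disordered-stretch
#' calling (score `> threshold` for `>= min_len` consecutive residues),
#' composition profiling of the primary stretch, and the aromatic/acidic
#' composition filter.
#'
#' @param records Tibble `accession`, `sequence` (optionally `clade`).
#' @param scores Per-residue disorder scores (`accession`, `position`,
#'   `score`).
#' @param reference Reference CRD sequence for the identity stage, or `NULL`
#'   to accept externally imported `hits`.
#' @param hits Optional external hit tibble (`accession`,
#'   `percent_identity`) replacing the built-in aligner.
#' @param identity_min Identity threshold, percent (kept if `>=`).
#' @param threshold,min_len Stretch-calling parameters.
#' @param aromatic_min,negative_max Composition-filter parameters.
#'
#' @return List with `annotations` (primary-stretch composition + filter
#'   columns for every identity-passing record with a qualifying stretch),
#'   `hits` (identity stage output), and `funnel` (tibble of stage counts:
#'   input, identity_pass, idr_pass, composition_pass).
#' @export
screen_proteome <- function(records, scores, reference = NULL, hits = NULL,
                            identity_min = 21, threshold = 0.5, min_len = 75,
                            aromatic_min = 8, negative_max = 3) {
  check_cols(records, c("accession", "sequence"), "records")
  if (is.null(hits)) {
    if (is.null(reference)) {
      abort("supply either `reference` (built-in aligner) or `hits`.")
    }
    hits <- align_records(records, reference)
  } else {
    check_cols(hits, c("accession", "percent_identity"), "hits")
  }
  kept <- filter_hits(hits, identity_min = identity_min)
  surv <- records[records$accession %in% kept$accession, , drop = FALSE]
  ann <- call_idr_stretches(
    scores[scores$accession %in% surv$accession, , drop = FALSE],
    threshold = threshold, min_len = min_len
  )
  primary <- ann[ann$primary, , drop = FALSE]
  prof <- idr_composition(primary, surv)
  if ("clade" %in% names(records)) {
    prof$clade <- records$clade[match(prof$accession, records$accession)]
  }
  prof <- composition_filter(prof,
    aromatic_min = aromatic_min, negative_max = negative_max
  )
  funnel <- tibble::tibble(
    stage = c("input", "identity_pass", "idr_pass", "composition_pass"),
    n = c(
      nrow(records), nrow(kept),
      dplyr::n_distinct(ann$accession), sum(prof$pass_filter)
    )
  )
  list(annotations = prof, all_stretches = ann, hits = hits, funnel = funnel)
}
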