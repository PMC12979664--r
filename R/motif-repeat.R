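# Exact repeated-motif detection within IDRs and N-terminal conservation
# scoring.  A transparent, deterministic k-mer finder replaces probabilistic
# motif discovery: the biological quantity of interest is how often an
# aromatic-containing motif is repeated, not motif-model statistics.

#' Find exactly repeated short motifs in a sequence
#'
#' Enumerates every k-mer with `k_min <= k <= k_max` occurring at least
#' `min_count` times (overlapping occurrences are counted).  A motif is
#' suppressed when it is a substring of a longer reported motif with the
#' identical occurrence multiset (same count, positions shifted by the
#' containment offset), so each repeat block is reported once at its maximal
#' extent.  Results are ordered by count (decreasing), then motif length
#' (decreasing), then alphabetically.
#'
#' @param sequence Amino-acid string of length >= `k_min`.
#' @param k_min,k_max Motif length range (defaults 3-8).
#' @param min_count Minimum number of occurrences (default 2).
#'
#' @return Tibble `motif`, `k`, `count`, `positions` (list column of 1-based
#'   start positions), `contains_aromatic`.  Zero rows when nothing repeats.
#' @export
#' @examples
#' find_repeats("MAYPGAYPGAYPGAQQ")
find_repeats <- function(sequence, k_min = 3, k_max = 8, min_count = 2) {
  sequence <- check_sequence(sequence)
  n <- nchar(sequence)
  if (n < k_min) abort("`sequence` must be at least `k_min` residues long.")
  stopifnot(k_min >= 1, k_max >= k_min, min_count >= 2)

  cand <- list()
  for (k in seq(k_min, min(k_max, n))) {
    starts <- seq_len(n - k + 1L)
    kmers <- substring(sequence, starts, starts + k - 1L)
    tab <- split(starts, kmers)
    tab <- tab[lengths(tab) >= min_count]
    if (length(tab) > 0) {
      cand[[as.character(k)]] <- tibble::tibble(
        motif = names(tab), k = k,
        count = unname(lengths(tab)), positions = unname(tab)
      )
    }
  }
  empty <- tibble::tibble(
    motif = character(), k = integer(), count = integer(),
    positions = list(), contains_aromatic = logical()
  )
  if (length(cand) == 0) {
    return(empty)
  }
  out <- dplyr::bind_rows(cand)

  # Suppress sub-motifs whose occurrences are fully explained by a longer
  # motif: same count, and positions equal to the longer motif's positions
  # shifted by the offset of the containment.
  suppressed <- vapply(seq_len(nrow(out)), function(i) {
    m <- out$motif[i]
    pos_m <- sort(out$positions[[i]])
    longer <- which(out$k > out$k[i] & out$count == out$count[i])
    for (j in longer) {
      M <- out$motif[j]
      offsets <- gregexpr(m, M, fixed = TRUE)[[1]]
      if (offsets[1] == -1) next
      pos_j <- sort(out$positions[[j]])
      for (o in offsets) {
        if (identical(pos_m, pos_j + (o - 1L))) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
  out <- out[!suppressed, , drop = FALSE]
  if (nrow(out) == 0) {
    return(empty)
  }
  out$contains_aromatic <- stringr::str_detect(out$motif, "[FYW]")
  out[order(-out$count, -out$k, out$motif), ]
}

#' Aromatic motif-repeat load
#'
#' Total number of occurrences of aromatic-containing repeated motifs: the
#' repetition "valence" an IDR contributes through its sticker motifs.
#'
#' @param repeats Tibble from [find_repeats()].
#'
#' @return A single count.
#' @export
#' @examples
#' aromatic_repeat_load(find_repeats("MAYPGAYPGAYPGAQQ", k_min = 4, k_max = 4))
aromatic_repeat_load <- function(repeats) {
  check_cols(repeats, c("count", "contains_aromatic"), "repeats")
  sum(repeats$count[repeats$contains_aromatic])
}

#' Score conservation of an N-terminal reference fragment
#'
#' Best ungapped placement of a reference fragment (default: the conserved
#' fragment spanning residues 5-20 of human galectin-3) within the first
#' `window` residues of a target sequence, maximizing percent identity; ties
#' are broken towards the N-terminus.  When the target is shorter than the
#' fragment, identity is computed over the available overlap and the result
#' is flagged `truncated`.
#'
#' @param target Target amino-acid sequence.
#' @param reference Reference fragment (non-empty).
#' @param window The placement must fall within the first `window` residues
#'   of the target (default 30).
#'
#' @return One-row tibble `start`, `end` (1-based placement on the target),
#'   `identity` (percent of compared columns), `n_compared`, `truncated`.
#' @export
#' @examples
#' nterm_conservation(paste0("MADN", hgal3_nterm_fragment, "GGG"))
nterm_conservation <- function(target, reference = hgal3_nterm_fragment,
                               window = 30) {
  target <- check_sequence(target, "target")
  reference <- check_sequence(reference, "reference")
  n <- nchar(target)
  len <- nchar(reference)
  ref_chars <- seq_chars(reference)
  truncated <- n < len
  max_start <- max(1L, min(window - len + 1L, n - len + 1L))
  best <- NULL
  for (s in seq_len(max_start)) {
    overlap <- min(len, n - s + 1L)
    tgt_chars <- seq_chars(substr(target, s, s + overlap - 1L))
    ident <- 100 * sum(tgt_chars == ref_chars[seq_len(overlap)]) / overlap
    if (is.null(best) || ident > best$identity) {
      best <- list(start = s, overlap = overlap, identity = ident)
    }
  }
  tibble::tibble(
    start = best$start, end = best$start + best$overlap - 1L,
    identity = best$identity, n_compared = best$overlap,
    truncated = truncated || best$overlap < len
  )
}

#' Repeat profiles for a set of IDR annotations
#'
#' Applies [find_repeats()] to each annotated IDR slice and returns a tidy
#' table of motifs, with positions reported relative to the IDR start.
#'
#' @param annotations Tibble with `accession` and `idr_seq` (e.g. from
#'   [idr_composition()]).
#' @inheritParams find_repeats
#'
#' @return Tibble `accession`, `motif`, `k`, `count`, `positions`,
#'   `contains_aromatic`, `aromatic_load` (per accession).
#' @export
find_repeats_all <- function(annotations, k_min = 3, k_max = 8, min_count = 2) {
  check_cols(annotations, c("accession", "idr_seq"), "annotations")
  out <- purrr::map2(
    annotations$accession, annotations$idr_seq,
    function(acc, s) {
      reps <- find_repeats(s, k_min = k_min, k_max = k_max, min_count = min_count)
      if (nrow(reps) == 0) {
        return(NULL)
      }
      reps$accession <- acc
      reps$aromatic_load <- aromatic_repeat_load(reps)
      reps
    }
  )
  dplyr::bind_rows(
    tibble::tibble(
      motif = character(), k = integer(), count = integer(),
      positions = list(), contains_aromatic = logical(),
      accession = character(), aromatic_load = integer()
    ),
    out
  ) |>
    dplyr::relocate("accession")
}
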