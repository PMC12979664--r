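# Chemical shift perturbation (CSP) mapping and intensity-ratio profiles
# from paired HSQC peak lists.

#' Read a Sparky-style peak list
#'
#' Parses a whitespace-delimited peak list with columns assignment, w1 (15N,
#' ppm), w2 (1H, ppm), and optionally intensity (any `Assignment w1 w2 ...`
#' header line is skipped).  The residue number is extracted from the first
#' run of digits in the assignment.
#'
#' @param path Path to the peak list file.
#'
#' @return Tibble `assignment`, `residue`, `n_ppm`, `h_ppm`, `intensity`
#'   (`NA` when absent).
#' @export
read_sparky <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*Assignment", lines, ignore.case = TRUE)]
  parts <- strsplit(trimws(lines), "\\s+")
  tibble::tibble(
    assignment = vapply(parts, `[[`, character(1), 1L),
    residue = as.integer(stringr::str_extract(
      vapply(parts, `[[`, character(1), 1L), "\\d+"
    )),
    n_ppm = as.numeric(vapply(parts, `[[`, character(1), 2L)),
    h_ppm = as.numeric(vapply(parts, `[[`, character(1), 3L)),
    intensity = vapply(
      parts,
      function(p) if (length(p) >= 4) as.numeric(p[4]) else NA_real_,
      numeric(1)
    )
  )
}

match_peaklists <- function(a, b, arg_a = "a", arg_b = "b") {
  for (nm in list(list(a, arg_a), list(b, arg_b))) {
    check_cols(nm[[1]], c("assignment", "n_ppm", "h_ppm"), nm[[2]])
    if (anyDuplicated(nm[[1]]$assignment)) {
      abort(sprintf("duplicate assignments in `%s`.", nm[[2]]))
    }
  }
  dplyr::inner_join(a, b, by = "assignment", suffix = c("_a", "_b"))
}

#' Chemical shift perturbations between two states
#'
#' Matches two peak lists by assignment and computes the combined 1H/15N
#' perturbation `CSP = sqrt(ddH^2 + (alpha * ddN)^2)` per residue, with the
#' community-standard 15N scaling `alpha = 0.14` by default (the combination
#' formula and weight are package choices; both are configurable).  Residues
#' with `CSP > flag_threshold` are flagged as perturbed.
#'
#' @param a,b Peak-list tibbles (`assignment`, `n_ppm`, `h_ppm`, optionally
#'   `residue`, `intensity`); `a` is the reference state.
#' @param alpha 15N weight in the combined shift.
#' @param flag_threshold Flagging threshold in ppm (strictly greater than;
#'   default 0.01 ppm).
#'
#' @return Tibble `assignment`, `residue`, `d_h`, `d_n`, `csp`, `flagged`,
#'   one row per matched assignment.  Assignments present in only one list
#'   are reported in the `unmatched` attribute (a tibble with a `missing_in`
#'   column) and counted in attribute `n_unmatched`.
#' @export
#' @examples
#' pk <- sim_peaklists(5, shifted_subset = c(2, 4), seed = 1)
#' csp(pk$reference, pk$perturbed)
csp <- function(a, b, alpha = 0.14, flag_threshold = 0.01) {
  if (alpha < 0) abort("`alpha` must be >= 0.")
  j <- match_peaklists(a, b)
  d_h <- j$h_ppm_b - j$h_ppm_a
  d_n <- j$n_ppm_b - j$n_ppm_a
  out <- tibble::tibble(
    assignment = j$assignment,
    residue = if ("residue_a" %in% names(j)) {
      j$residue_a
    } else {
      as.integer(stringr::str_extract(j$assignment, "\\d+"))
    },
    d_h = d_h, d_n = d_n,
    csp = sqrt(d_h^2 + (alpha * d_n)^2)
  )
  out$flagged <- out$csp > flag_threshold
  un_a <- setdiff(a$assignment, b$assignment)
  un_b <- setdiff(b$assignment, a$assignment)
  unmatched <- tibble::tibble(
    assignment = c(un_a, un_b),
    missing_in = c(rep("b", length(un_a)), rep("a", length(un_b)))
  )
  attr(out, "unmatched") <- unmatched
  attr(out, "n_unmatched") <- nrow(unmatched)
  out
}

#' Per-residue intensity ratios between two states
#'
#' Matches two peak lists by assignment and returns `ratio =
#' intensity_a / intensity_b`, optionally normalized by the median ratio
#' (so a molar-ratio expectation can be compared against via
#' `expected_ratio`).  Residues with zero intensity in `b` are flagged and
#' their ratio set to `NA`.
#'
#' @param a,b Peak-list tibbles with `assignment` and `intensity`.
#' @param normalization `"none"` or `"median"`.
#' @param expected_ratio Optional scalar (e.g. a molar ratio); when given, a
#'   `below_expected` flag marks residues with ratio strictly below it.
#'
#' @return Tibble `assignment`, `residue`, `ratio`, `zero_denominator`, and
#'   `below_expected` when `expected_ratio` is supplied.
#' @export
intensity_ratio <- function(a, b, normalization = c("none", "median"),
                            expected_ratio = NULL) {
  normalization <- match.arg(normalization)
  check_cols(a, "intensity", "a")
  check_cols(b, "intensity", "b")
  j <- match_peaklists(a, b)
  zero <- j$intensity_b == 0
  ratio <- ifelse(zero, NA_real_, j$intensity_a / j$intensity_b)
  if (normalization == "median") {
    ratio <- ratio / median(ratio, na.rm = TRUE)
  }
  out <- tibble::tibble(
    assignment = j$assignment,
    residue = if ("residue_a" %in% names(j)) {
      j$residue_a
    } else {
      as.integer(stringr::str_extract(j$assignment, "\\d+"))
    },
    ratio = ratio,
    zero_denominator = zero
  )
  if (!is.null(expected_ratio)) {
    out$below_expected <- !is.na(out$ratio) & out$ratio < expected_ratio
  }
  out
}
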