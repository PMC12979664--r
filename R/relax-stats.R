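# Aggregation of residue-wise rate estimates: inverse-variance weighted
# (IVW) means, propagated condition comparisons, and the paired sign test
# on concentration-dependent R2 changes.

#' Inverse-variance weighted mean of rate estimates
#'
#' `mean = sum(x_i / se_i^2) / sum(1 / se_i^2)`;
#' `se = sqrt(1 / sum(1 / se_i^2))`.  Estimates flagged by the fitting stage
#' (`flagged == TRUE`) or with non-positive standard errors are excluded.
#'
#' @param estimates Tibble with `rate` and `se` (e.g. from [fit_rates()]);
#'   an optional `flagged` column marks estimates to drop.
#'
#' @return One-row tibble `mean`, `se`, `n_used`.
#' @export
#' @examples
#' ivw_combine(tibble::tibble(rate = c(10, 20), se = c(1, 2)))
ivw_combine <- function(estimates) {
  check_cols(estimates, c("rate", "se"), "estimates")
  keep <- is.finite(estimates$rate) & is.finite(estimates$se) & estimates$se > 0
  if ("flagged" %in% names(estimates)) {
    keep <- keep & !estimates$flagged
  }
  x <- estimates$rate[keep]
  s <- estimates$se[keep]
  if (length(x) == 0) {
    abort("no usable estimates: all flagged or with non-positive SE.")
  }
  w <- 1 / s^2
  tibble::tibble(
    mean = sum(w * x) / sum(w),
    se = sqrt(1 / sum(w)),
    n_used = length(x)
  )
}

#' Per-condition IVW aggregates of R1 and R2
#'
#' Aggregates residue-wise rate estimates into condition-level means: IVW
#' mean and SE of R2 and R1, and their ratio with the propagated SE
#' `se_r = r * sqrt((se_R2/R2)^2 + (se_R1/R1)^2)`.
#'
#' @param estimates Tibble from [fit_rates()] with columns `condition`,
#'   `rate_type` (values `"R1"`/`"R2"`), `rate`, `se`, and optionally
#'   `flagged` and `residue`.
#' @param residues Optional integer vector restricting aggregation to an
#'   explicit residue inclusion list (e.g. assigned CRD residues only).
#'
#' @return Tibble, one row per condition: `condition`, `r2`, `r2_se`, `r1`,
#'   `r1_se`, `r2_over_r1`, `r2_over_r1_se`, `n_r2`, `n_r1`.
#' @export
condition_stats <- function(estimates, residues = NULL) {
  check_cols(estimates, c("condition", "rate_type", "rate", "se"), "estimates")
  if (!is.null(residues)) {
    check_cols(estimates, "residue", "estimates")
    estimates <- estimates[estimates$residue %in% residues, , drop = FALSE]
  }
  one <- function(df) {
    agg2 <- ivw_combine(df[df$rate_type == "R2", , drop = FALSE])
    agg1 <- ivw_combine(df[df$rate_type == "R1", , drop = FALSE])
    if (agg1$mean == 0) abort("IVW mean of R1 is zero; ratio undefined.")
    ratio <- agg2$mean / agg1$mean
    tibble::tibble(
      r2 = agg2$mean, r2_se = agg2$se, r1 = agg1$mean, r1_se = agg1$se,
      r2_over_r1 = ratio,
      r2_over_r1_se = abs(ratio) *
        sqrt((agg2$se / agg2$mean)^2 + (agg1$se / agg1$mean)^2),
      n_r2 = agg2$n_used, n_r1 = agg1$n_used
    )
  }
  parts <- split(
    estimates,
    factor(estimates$condition, levels = unique(estimates$condition))
  )
  dplyr::bind_cols(
    tibble::tibble(condition = names(parts)),
    dplyr::bind_rows(unname(purrr::map(parts, one)))
  )
}

#' Compare two concentration conditions
#'
#' Absolute differences of the condition-level aggregates with standard
#' errors propagated in quadrature: `|Delta| = |m_high - m_low|`,
#' `SE = sqrt(se_high^2 + se_low^2)`, applied to R2, R1 and R2/R1.  All
#' arithmetic uses unrounded aggregates.
#'
#' @param stats Output of [condition_stats()] containing both conditions.
#' @param low,high Condition labels; default to the first and second row.
#'
#' @return One-row tibble `low`, `high`, `d_r2`, `d_r2_se`, `d_r1`,
#'   `d_r1_se`, `d_ratio`, `d_ratio_se`.
#' @export
condition_compare <- function(stats, low = stats$condition[1],
                              high = stats$condition[2]) {
  check_cols(stats, c("condition", "r2", "r2_se", "r1", "r1_se"), "stats")
  lo <- stats[stats$condition == low, , drop = FALSE]
  hi <- stats[stats$condition == high, , drop = FALSE]
  if (nrow(lo) != 1 || nrow(hi) != 1) {
    abort("`low` and `high` must each match exactly one condition row.")
  }
  tibble::tibble(
    low = low, high = high,
    d_r2 = abs(hi$r2 - lo$r2), d_r2_se = sqrt(hi$r2_se^2 + lo$r2_se^2),
    d_r1 = abs(hi$r1 - lo$r1), d_r1_se = sqrt(hi$r1_se^2 + lo$r1_se^2),
    d_ratio = abs(hi$r2_over_r1 - lo$r2_over_r1),
    d_ratio_se = sqrt(hi$r2_over_r1_se^2 + lo$r2_over_r1_se^2)
  )
}

#' Per-residue rate differences between two conditions
#'
#' Joins two residue-wise estimate tables (same construct, two conditions)
#' and returns `delta = rate_high - rate_low` with the propagated SE.
#' Flagged estimates are dropped before joining.
#'
#' @param low,high Tibbles with `residue`, `rate`, `se` (and optionally
#'   `flagged`).
#'
#' @return Tibble `residue`, `delta`, `se`.
#' @export
residue_deltas <- function(low, high) {
  clean <- function(df) {
    check_cols(df, c("residue", "rate", "se"), "estimates")
    if ("flagged" %in% names(df)) df <- df[!df$flagged, , drop = FALSE]
    df[, c("residue", "rate", "se")]
  }
  j <- dplyr::inner_join(
    clean(low), clean(high),
    by = "residue", suffix = c("_low", "_high")
  )
  tibble::tibble(
    residue = j$residue,
    delta = j$rate_high - j$rate_low,
    se = sqrt(j$se_high^2 + j$se_low^2)
  )
}

#' Paired sign test on construct differences of concentration-dependent R2
#' changes
#'
#' For two constructs with per-residue concentration-dependent R2 changes
#' (`delta` columns), computes the per-residue difference-of-differences
#' `ddr2 = delta_construct - delta_control` on the intersected residue set,
#' drops ties (`ddr2 == 0`), and tests whether positive shifts predominate
#' with an exact binomial sign test:
#' one-sided `p = P(X >= n_positive)`, `X ~ Binomial(n_nonzero, 1/2)`.
#'
#' @param delta_construct,delta_control Tibbles with `residue` and `delta`
#'   (e.g. from [residue_deltas()]).
#' @param alternative `"greater"` (one-sided, positive shift; default) or
#'   `"two.sided"`.
#'
#' @return An object of class `ddr2_sign_test` with fields `ddr2` (tibble
#'   `residue`, `ddr2`), `n_nonzero`, `n_positive`, `p_value`,
#'   `alternative`; see [tidy.ddr2_sign_test()].
#' @export
#' @examples
#' a <- tibble::tibble(residue = 1:10, delta = rep(2, 10))
#' b <- tibble::tibble(residue = 1:10, delta = rep(1, 10))
#' glance(ddr2_sign_test(a, b))
ddr2_sign_test <- function(delta_construct, delta_control,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_cols(delta_construct, c("residue", "delta"), "delta_construct")
  check_cols(delta_control, c("residue", "delta"), "delta_control")
  j <- dplyr::inner_join(
    delta_construct[, c("residue", "delta")],
    delta_control[, c("residue", "delta")],
    by = "residue", suffix = c("_a", "_b")
  )
  ddr2 <- j$delta_a - j$delta_b
  nonzero <- ddr2 != 0
  n <- sum(nonzero)
  if (n == 0) {
    abort("all paired differences are ties; the sign test is undefined.")
  }
  k <- sum(ddr2[nonzero] > 0)
  p_ge <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  p <- switch(alternative,
    greater = p_ge,
    two.sided = min(1, 2 * min(p_ge, pbinom(k, n, 0.5)))
  )
  structure(
    list(
      ddr2 = tibble::tibble(residue = j$residue, ddr2 = ddr2),
      n_nonzero = n, n_positive = k, p_value = p, alternative = alternative
    ),
    class = "ddr2_sign_test"
  )
}

#' @export
print.ddr2_sign_test <- function(x, ...) {
  cat(sprintf(
    "<ddr2_sign_test> %d of %d nonzero differences positive; %s p = %.4g\n",
    x$n_positive, x$n_nonzero, x$alternative, x$p_value
  ))
  invisible(x)
}
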