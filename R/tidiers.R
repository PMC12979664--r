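# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy a relaxation rate fit
#'
#' @param x A `rate_fit` from [fit_rate()].
#' @param ... Unused.
#'
#' @return One-row tibble `rate`, `se`, `i0`, `sigma`, `flagged`.
#' @exportS3Method generics::tidy
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(
    rate = x$rate, se = x$se, i0 = x$i0, sigma = x$sigma, flagged = x$flagged
  )
}

#' @rdname tidy.rate_fit
#' @return For `glance()`: one-row tibble of fit diagnostics (`residual_norm`,
#'   `n_points`, `n_mc`, `converged`).
#' @exportS3Method generics::glance
glance.rate_fit <- function(x, ...) {
  tibble::tibble(
    residual_norm = x$residual_norm, n_points = x$n_points,
    n_mc = x$n_mc, converged = x$converged
  )
}

#' Tidy a Bradford calibration
#'
#' @param x A `bradford_fit` from [bradford_fit()].
#' @param ... Unused.
#'
#' @return Coefficient-level tibble (`term`, `estimate`, `std.error`) for
#'   `tidy()`; one-row model summary (`slope`, `intercept`, `r_squared`,
#'   `n`, `ratio_min`, `ratio_max`) for `glance()`.
#' @exportS3Method generics::tidy
tidy.bradford_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"]
  )
}

#' @rdname tidy.bradford_fit
#' @exportS3Method generics::glance
glance.bradford_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    n = x$n, ratio_min = x$ratio_range[1], ratio_max = x$ratio_range[2]
  )
}

#' Tidy a paired sign-test result
#'
#' @param x A `ddr2_sign_test` from [ddr2_sign_test()].
#' @param ... Unused.
#'
#' @return Per-residue tibble of difference-of-differences for `tidy()`;
#'   one-row test summary (`n_nonzero`, `n_positive`, `p_value`,
#'   `alternative`) for `glance()`.
#' @exportS3Method generics::tidy
tidy.ddr2_sign_test <- function(x, ...) {
  x$ddr2
}

#' @rdname tidy.ddr2_sign_test
#' @exportS3Method generics::glance
glance.ddr2_sign_test <- function(x, ...) {
  tibble::tibble(
    n_nonzero = x$n_nonzero, n_positive = x$n_positive,
    p_value = x$p_value, alternative = x$alternative
  )
}
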