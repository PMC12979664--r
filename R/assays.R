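# Wet-lab assay computations: circular dichroism unit conversion, Bradford
# ratio calibration, agglutination supernatant fractions, and replicate
# summaries.

#' Convert CD machine units to molar extinction difference
#'
#' `delta_epsilon = theta * 0.1 * MRW / (l * C * 3298)`, where `theta` is the
#' measured ellipticity in machine units (millidegrees), `MRW` the mean
#' residue weight in Dalton (molecular weight / residue count), `l` the path
#' length in cm and `C` the protein concentration in mg/ml.  Vectorized over
#' `theta`, so a whole spectrum converts in one call.
#'
#' @param theta Ellipticity, machine units (numeric vector).
#' @param mrw Mean residue weight (Da, > 0).
#' @param l Path length (cm, > 0).
#' @param conc Protein concentration (mg/ml, > 0).
#'
#' @return Numeric vector of delta-epsilon values.
#' @export
#' @examples
#' delta_epsilon(10000, mrw = 110, l = 0.01, conc = 1)
delta_epsilon <- function(theta, mrw, l, conc) {
  if (any(c(mrw, l, conc) <= 0)) {
    abort("`mrw`, `l` and `conc` must all be positive.")
  }
  theta * 0.1 * mrw / (l * conc * 3298)
}

#' Convert a CD spectrum table
#'
#' Applies [delta_epsilon()] to the `theta` column of a spectrum tibble.
#'
#' @param spectrum Tibble with `wavelength` (nm, strictly increasing) and
#'   `theta`.
#' @inheritParams delta_epsilon
#'
#' @return `spectrum` with a `delta_epsilon` column appended.
#' @export
cd_convert <- function(spectrum, mrw, l, conc) {
  check_cols(spectrum, c("wavelength", "theta"), "spectrum")
  if (any(diff(spectrum$wavelength) <= 0)) {
    abort("`wavelength` must be strictly increasing.")
  }
  dplyr::mutate(
    spectrum,
    delta_epsilon = delta_epsilon(.data$theta, mrw, l, conc)
  )
}

#' Calibrate a Bradford assay from BSA standards
#'
#' Ordinary least-squares regression of known standard concentrations on
#' A594/A466 absorbance ratios: `conc = slope * ratio + intercept`
#' (unweighted).
#'
#' @param standards Tibble with `ratio` (A594/A466) and `conc` (known
#'   concentration); at least 2 distinct ratios.
#'
#' @return Object of class `bradford_fit` wrapping the [stats::lm()] fit,
#'   with `slope`, `intercept`, `r_squared` and the calibration range; see
#'   [tidy.bradford_fit()].
#' @export
#' @examples
#' std <- tibble::tibble(ratio = 1:5, conc = 20 * (1:5) - 10)
#' glance(bradford_fit(std))
bradford_fit <- function(standards) {
  check_cols(standards, c("ratio", "conc"), "standards")
  if (length(unique(standards$ratio)) < 2) {
    abort("Bradford calibration needs at least 2 distinct ratios.")
  }
  fit <- lm(conc ~ ratio, data = standards)
  # suppressWarnings: summary.lm warns on noiseless (exactly collinear)
  # standards, a designed use here
  structure(
    list(
      fit = fit,
      slope = coef(fit)[["ratio"]],
      intercept = coef(fit)[["(Intercept)"]],
      r_squared = suppressWarnings(summary(fit)$r.squared),
      ratio_range = range(standards$ratio),
      n = nrow(standards)
    ),
    class = "bradford_fit"
  )
}

#' @export
print.bradford_fit <- function(x, ...) {
  cat(sprintf(
    "<bradford_fit> conc = %.4g * ratio + %.4g (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n
  ))
  invisible(x)
}

#' Predict sample concentrations from a Bradford calibration
#'
#' Applies the fitted line to sample A594/A466 ratios.  Ratios more than 10%
#' outside the standards' ratio range are flagged as extrapolated (assay
#' linearity cannot be trusted there).
#'
#' @param calibration A [bradford_fit()].
#' @param samples Tibble with a `ratio` column (other columns pass through).
#'
#' @return `samples` with `conc` and `extrapolated` columns appended.
#' @export
bradford_predict <- function(calibration, samples) {
  stopifnot(inherits(calibration, "bradford_fit"))
  check_cols(samples, "ratio", "samples")
  rng <- calibration$ratio_range
  margin <- 0.1 * diff(rng)
  dplyr::mutate(
    samples,
    conc = calibration$slope * .data$ratio + calibration$intercept,
    extrapolated = .data$ratio < rng[1] - margin | .data$ratio > rng[2] + margin
  )
}

#' Supernatant fraction from an agglutination assay
#'
#' Normalizes replicate supernatant concentrations S to the total protein T:
#' `fraction = mean(S) / T` with `sd = sd(S) / T`.  Stronger agglutination
#' pulls more protein into the pellet, so a lower fraction means stronger
#' agglutination.  Replicate means exceeding T by more than `tolerance`
#' (relative) are flagged as assay anomalies.
#'
#' @param total Total protein concentration T (> 0), same units as the
#'   supernatant replicates.
#' @param supernatant Numeric vector of replicate supernatant concentrations
#'   (>= 1 value).
#' @param construct Optional construct label carried into the result.
#' @param tolerance Relative tolerance for the `S > T` anomaly flag.
#'
#' @return One-row tibble `construct`, `total`, `s_mean`, `s_sd`,
#'   `fraction`, `fraction_sd`, `n`, `anomalous`.
#' @export
#' @examples
#' agglutination_fraction(20, c(5, 5, 5), construct = "zfGal")
agglutination_fraction <- function(total, supernatant, construct = NA_character_,
                                   tolerance = 0.05) {
  if (total <= 0) abort("`total` must be positive.")
  if (length(supernatant) < 1) abort("need at least one supernatant replicate.")
  if (any(supernatant < 0)) abort("supernatant concentrations must be >= 0.")
  m <- mean(supernatant)
  s <- if (length(supernatant) > 1) sd(supernatant) else NA_real_
  tibble::tibble(
    construct = construct, total = total,
    s_mean = m, s_sd = s,
    fraction = m / total,
    fraction_sd = s / total,
    n = length(supernatant),
    anomalous = m > total * (1 + tolerance)
  )
}

#' Agglutination table for several constructs
#'
#' Applies [agglutination_fraction()] per construct to a tidy table of
#' replicate supernatant concentrations.
#'
#' @param samples Tibble with `construct` and `s_conc` (one row per
#'   replicate).
#' @param total Total protein concentration T.
#' @inheritParams agglutination_fraction
#'
#' @return Tibble with one row per construct, ordered by increasing
#'   fraction (strongest agglutination first).
#' @export
agglutination_table <- function(samples, total, tolerance = 0.05) {
  check_cols(samples, c("construct", "s_conc"), "samples")
  out <- dplyr::bind_rows(unname(purrr::map(
    split(samples, samples$construct),
    function(df) {
      agglutination_fraction(total, df$s_conc,
        construct = df$construct[1], tolerance = tolerance
      )
    }
  )))
  out[order(out$fraction), ]
}

#' Replicate mean and standard deviation
#'
#' Summarizes replicate measurements (e.g. OD600 turbidity readings or CD
#' replicates) as mean, sd and n per group.
#'
#' @param data Tibble of measurements.
#' @param value Name of the measurement column (string).
#' @param group Character vector of grouping columns.
#'
#' @return Tibble with the grouping columns plus `mean`, `sd`, `n`.
#' @export
replicate_summary <- function(data, value, group = intersect(
                                c("condition", "construct"), names(data)
                              )) {
  check_cols(data, c(value, group), "data")
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(group))),
    mean = mean(.data[[value]]),
    sd = sd(.data[[value]]),
    n = dplyr::n(),
    .groups = "drop"
  )
}
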