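# ggplot2 views of the main result types.

#' Plot a per-residue disorder profile with called stretches
#'
#' @param scores Score tibble (`accession`, `position`, `score`) for one or
#'   more accessions (facetted).
#' @param annotations Optional stretch tibble from [call_idr_stretches()]
#'   drawn as shaded intervals.
#' @param threshold Threshold line to draw.
#'
#' @return A ggplot object.
#' @export
plot_disorder_profile <- function(scores, annotations = NULL, threshold = 0.5) {
  check_cols(scores, c("accession", "position", "score"), "scores")
  p <- ggplot2::ggplot(scores, ggplot2::aes(.data$position, .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(
      yintercept = threshold, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$accession)) +
    ggplot2::labs(x = "residue", y = "disorder score") +
    ggplot2::ylim(0, 1)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    p <- p + ggplot2::geom_rect(
      data = annotations,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}

#' Plot per-residue relaxation rates by condition
#'
#' @param estimates Tibble from [fit_rates()] with `residue`, `rate`, `se`,
#'   `condition` (and optionally `rate_type`, facetted).
#'
#' @return A ggplot object with 1-sigma error bars.
#' @export
plot_rate_profile <- function(estimates) {
  check_cols(estimates, c("residue", "rate", "se", "condition"), "estimates")
  p <- ggplot2::ggplot(
    estimates,
    ggplot2::aes(.data$residue, .data$rate, colour = .data$condition)
  ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$rate - .data$se, ymax = .data$rate + .data$se
      ),
      width = 0
    ) +
    ggplot2::labs(x = "residue", y = "rate (1/s)")
  if ("rate_type" %in% names(estimates)) {
    p <- p + ggplot2::facet_wrap(
      ggplot2::vars(.data$rate_type),
      scales = "free_y", ncol = 1
    )
  }
  p
}

#' Plot a chemical shift perturbation map
#'
#' @param csp_table Tibble from [csp()].
#' @param flag_threshold Threshold line (ppm).
#'
#' @return A ggplot bar chart, perturbed residues highlighted.
#' @export
plot_csp <- function(csp_table, flag_threshold = 0.01) {
  check_cols(csp_table, c("residue", "csp", "flagged"), "csp_table")
  ggplot2::ggplot(
    csp_table,
    ggplot2::aes(.data$residue, .data$csp, fill = .data$flagged)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = flag_threshold, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(x = "residue", y = "CSP (ppm)")
}

#' Boxplot of clade-level aromatic content
#'
#' @param profiles Tibble with `clade`, `pct_F`, `pct_Y`, `pct_W` (e.g.
#'   screened annotations).
#'
#' @return A ggplot object: one panel per aromatic type, Tukey boxplots
#'   (whiskers at 1.5 x IQR) per clade.
#' @export
plot_clade_aromatics <- function(profiles) {
  check_cols(profiles, c("clade", "pct_F", "pct_Y", "pct_W"), "profiles")
  long <- tidyr::pivot_longer(
    profiles[, c("clade", "pct_W", "pct_F", "pct_Y")],
    cols = -"clade", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$clade, .data$value)) +
    ggplot2::geom_boxplot(coef = 1.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = NULL, y = "% of IDR residues")
}

#' Autoplot a relaxation rate fit
#'
#' Shows the data points and the fitted monoexponential decay.
#'
#' @param object A `rate_fit`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(
    delay_s = seq(min(df$delay_s), max(df$delay_s), length.out = 100)
  )
  grid$intensity <- object$i0 * exp(-object$rate * grid$delay_s)
  ggplot2::ggplot(df, ggplot2::aes(.data$delay_s, .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "relaxation delay (s)", y = "intensity",
      subtitle = sprintf("R = %.3f ± %.3f 1/s", object$rate, object$se)
    )
}

#' Autoplot a Bradford calibration
#'
#' @param object A `bradford_fit`.
#' @param ... Unused.
#'
#' @return A ggplot object: standards and the fitted line.
#' @exportS3Method ggplot2::autoplot
autoplot.bradford_fit <- function(object, ...) {
  df <- object$fit$model
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio, .data$conc)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "firebrick"
    ) +
    ggplot2::labs(x = "A594 / A466", y = "concentration")
}
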