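# Generators for Bradford calibration tables, agglutination supernatant
# samples, and OD600 replicate measurements, with planted ground truth.

#' Simulate Bradford and agglutination assay tables
#'
#' Standards follow `conc = slope * (A594/A466) + intercept` exactly, plus
#' optional relative Gaussian noise on the absorbances.  Agglutination
#' samples encode a chosen supernatant-over-total protein fraction `S/T` per
#' construct: stronger agglutination removes more protein from the
#' supernatant, so a lower `S/T` means stronger agglutination.
#'
#' @param slope,intercept Calibration line parameters (`slope != 0`),
#'   concentration in ug/ml per absorbance-ratio unit.
#' @param s_over_t Named numeric vector of true supernatant fractions per
#'   construct, each in \[0, 1\].
#' @param total_um Total protein concentration T of the assay (uM).
#' @param n_replicates Replicates per construct (>= 1).
#' @param noise Relative Gaussian noise sd applied to absorbances and to
#'   OD600 readings (0 = noiseless).
#' @param standard_conc Known BSA standard concentrations (ug/ml).
#' @param od600_mean Named numeric vector of true OD600 turbidity per sample
#'   condition (optional summary-assay arm).
#' @param seed Integer seed.
#'
#' @return List of tibbles: `standards` (`conc`, `a594`, `a466`, `ratio`),
#'   `samples` (`construct`, `replicate`, `a594`, `a466`, `ratio`),
#'   `od600` (`condition`, `replicate`, `od600`), and `truth` (planted
#'   slope/intercept, per-construct `s_over_t`, `total_um`).
#' @export
#' @examples
#' sim_assays(slope = 20, intercept = -10, s_over_t = c(zfGal = 0.25), seed = 1)
sim_assays <- function(slope = 20, intercept = -10,
                       s_over_t = c(hGal3 = 0.05, zfGalWY = 0.45, zfGal = 0.30),
                       total_um = 20, n_replicates = 3L, noise = 0,
                       standard_conc = c(25, 50, 100, 200, 400, 600),
                       od600_mean = NULL, seed = 1L) {
  if (slope == 0) abort("`slope` must be non-zero.")
  if (any(s_over_t < 0 | s_over_t > 1)) abort("`s_over_t` values must lie in [0, 1].")
  if (is.null(names(s_over_t))) {
    names(s_over_t) <- sprintf("construct%d", seq_along(s_over_t))
  }
  stopifnot(total_um > 0, is_count(n_replicates), n_replicates >= 1, noise >= 0)
  with_substream(seed, "assays", {
    a466 <- 0.5
    noisy <- function(x) x * (1 + rnorm(length(x), 0, noise))
    standards <- tibble::tibble(
      conc = standard_conc,
      a466 = noisy(rep(a466, length(standard_conc))),
      a594 = noisy(a466 * (standard_conc - intercept) / slope)
    )
    standards$ratio <- standards$a594 / standards$a466

    # Express the supernatant on the calibration's concentration scale via a
    # fixed uM -> ug/ml factor (arbitrary but recorded in the truth table).
    ug_per_um <- 30
    samples <- tidyr::expand_grid(
      construct = names(s_over_t), replicate = seq_len(n_replicates)
    )
    s_conc <- s_over_t[samples$construct] * total_um * ug_per_um
    samples$a466 <- noisy(rep(a466, nrow(samples)))
    samples$a594 <- noisy(a466 * (s_conc - intercept) / slope)
    samples$ratio <- samples$a594 / samples$a466

    od600 <- NULL
    if (!is.null(od600_mean)) {
      od600 <- tidyr::expand_grid(
        condition = names(od600_mean), replicate = seq_len(n_replicates)
      )
      od600$od600 <- noisy(od600_mean[od600$condition])
    }
    list(
      standards = standards, samples = samples, od600 = od600,
      truth = list(
        slope = slope, intercept = intercept, s_over_t = s_over_t,
        total_um = total_um, ug_per_um = ug_per_um, od600_mean = od600_mean
      )
    )
  })
}
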