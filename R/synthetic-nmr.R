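# Generators for relaxation decay series and paired HSQC peak lists with
# planted ground truth (self-association rate shifts, chemical shift moves).

#' Ground truth for a two-condition relaxation experiment
#'
#' Describes per-residue true monoexponential decay rates under one or more
#' sample conditions (e.g. 40 and 400 uM), the common initial intensity, the
#' noise level, and the relaxation delay grid.
#'
#' @param rates Tibble with columns `condition`, `residue`, `rate` (1/s,
#'   > 0 for decaying series).
#' @param i0 Initial intensity (arbitrary units, > 0).
#' @param noise_sigma Gaussian noise standard deviation as a fraction of
#'   `i0` (>= 0).
#' @param delays Strictly increasing relaxation delays in seconds, first
#'   delay >= 0; at least 3 points.
#'
#' @return A validated list of class `relax_truth`.
#' @export
#' @examples
#' tr <- relax_truth(
#'   rates = tibble::tibble(
#'     condition = rep(c("40uM", "400uM"), each = 3),
#'     residue = rep(1:3, 2),
#'     rate = c(17, 17.5, 16.8, 21, 21.5, 20.9)
#'   ),
#'   delays = c(0, 0.01, 0.03, 0.05, 0.09, 0.13, 0.17, 0.25)
#' )
#' head(sim_relaxation(tr, seed = 1))
relax_truth <- function(rates, i0 = 100, noise_sigma = 0.01,
                        delays = c(0, 0.01, 0.03, 0.05, 0.09, 0.13, 0.17, 0.25)) {
  check_cols(rates, c("condition", "residue", "rate"), "rates")
  if (any(rates$rate <= 0)) abort("true rates must be > 0 for decaying series.")
  if (i0 <= 0) abort("`i0` must be positive.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (length(delays) < 3 || any(diff(delays) <= 0) || delays[1] < 0) {
    abort("`delays` must be >= 3 strictly increasing values, first >= 0.")
  }
  structure(
    list(
      rates = tibble::as_tibble(rates), i0 = i0,
      noise_sigma = noise_sigma, delays = as.numeric(delays)
    ),
    class = "relax_truth"
  )
}

#' Simulate relaxation decay series from ground truth
#'
#' Intensities follow `I(t) = I0 * exp(-R * t) + N(0, noise_sigma * I0)`,
#' independently per residue, condition, delay and replicate.  Same seed,
#' same truth: identical table.
#'
#' @param truth A [relax_truth()].
#' @param seed Integer seed.
#' @param n_replicates Replicate series per residue and condition.
#'
#' @return Tidy tibble `condition`, `residue`, `replicate`, `delay_s`,
#'   `intensity`.
#' @export
sim_relaxation <- function(truth, seed = 1L, n_replicates = 1L) {
  stopifnot(inherits(truth, "relax_truth"), is_count(n_replicates), n_replicates >= 1)
  with_substream(seed, "relaxation", {
    grid <- tidyr::expand_grid(
      truth$rates,
      replicate = seq_len(n_replicates),
      delay_s = truth$delays
    )
    grid$intensity <- truth$i0 * exp(-grid$rate * grid$delay_s) +
      rnorm(nrow(grid), 0, truth$noise_sigma * truth$i0)
    keep <- intersect(
      c("condition", "rate_type", "residue", "replicate", "delay_s", "intensity"),
      names(grid)
    )
    dplyr::select(grid, dplyr::all_of(keep))
  })
}

#' Simulate paired HSQC peak lists with planted shifts
#'
#' Produces a reference peak list and a perturbed list in which only the
#' residues in `shifted_subset` move by (`d_h`, `d_n`) ppm, all peaks being
#' additionally jittered by Gaussian noise of sd `jitter_h` / `jitter_n`.
#' Assignments follow the Sparky convention `R<residue>N-H`.
#'
#' @param n_residues Number of backbone amide peaks.
#' @param shifted_subset Integer vector of residue numbers (subset of
#'   `1:n_residues`) that move between the two states.
#' @param d_h,d_n Planted shift in the 1H and 15N dimensions (ppm).
#' @param jitter_h,jitter_n Gaussian positional jitter sd (ppm) applied to
#'   both lists.
#' @param attenuated_subset Optional residues whose intensity in the second
#'   list is multiplied by `attenuation` (models exchange broadening).
#' @param attenuation Intensity factor for `attenuated_subset`.
#' @param seed Integer seed.
#'
#' @return List of two tibbles `reference` and `perturbed`, each with
#'   `assignment`, `residue`, `n_ppm`, `h_ppm`, `intensity`, plus a `truth`
#'   tibble recording the planted per-residue shifts.
#' @export
sim_peaklists <- function(n_residues, shifted_subset = integer(),
                          d_h = 0.02, d_n = 0.1,
                          jitter_h = 0, jitter_n = 0,
                          attenuated_subset = integer(), attenuation = 0.5,
                          seed = 1L) {
  stopifnot(is_count(n_residues), n_residues >= 1)
  shifted_subset <- as.integer(shifted_subset)
  if (!all(shifted_subset %in% seq_len(n_residues))) {
    abort("`shifted_subset` must be a subset of 1:n_residues.")
  }
  if (!all(attenuated_subset %in% seq_len(n_residues))) {
    abort("`attenuated_subset` must be a subset of 1:n_residues.")
  }
  with_substream(seed, "peaklists", {
    residue <- seq_len(n_residues)
    base <- tibble::tibble(
      assignment = sprintf("R%dN-H", residue),
      residue = residue,
      n_ppm = runif(n_residues, 105, 130),
      h_ppm = runif(n_residues, 6.5, 10),
      intensity = runif(n_residues, 0.5, 1.5) * 1e6
    )
    jit <- function(df) {
      df$n_ppm <- df$n_ppm + rnorm(nrow(df), 0, jitter_n)
      df$h_ppm <- df$h_ppm + rnorm(nrow(df), 0, jitter_h)
      df
    }
    reference <- jit(base)
    perturbed <- base
    moved <- perturbed$residue %in% shifted_subset
    perturbed$h_ppm[moved] <- perturbed$h_ppm[moved] + d_h
    perturbed$n_ppm[moved] <- perturbed$n_ppm[moved] + d_n
    att <- perturbed$residue %in% attenuated_subset
    perturbed$intensity[att] <- perturbed$intensity[att] * attenuation
    perturbed <- jit(perturbed)
    truth <- tibble::tibble(
      residue = residue,
      shifted = residue %in% shifted_subset,
      d_h = ifelse(residue %in% shifted_subset, d_h, 0),
      d_n = ifelse(residue %in% shifted_subset, d_n, 0),
      attenuated = residue %in% attenuated_subset
    )
    list(reference = reference, perturbed = perturbed, truth = truth)
  })
}
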