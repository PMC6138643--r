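# Protein half-life handling: conversion to first-order degradation rates and
# correction of noisy (possibly negative or huge) measured half-lives.
#
# Measured half-lives come from decay-rate estimates; when the underlying
# rate estimate is small its inverse explodes, and measurement error can even
# drive the rate (hence the reported half-life) negative.  The correction
# treats the measured degradation rate k_obs = ln(2)/observed as a Gaussian
# observation of the true rate with standard deviation sigma_k = ln(2)/300
# per minute (the rate of a 300-minute half-life, the longest reliably
# measurable one), imposes positivity of the true rate, and reports the mean
# of the normal distribution truncated to (0, Inf):
#   k_corr = k_obs + sigma_k * phi(h) / Phi(h),   h = k_obs / sigma_k,
# evaluated through log-space Mills ratios so it is stable arbitrarily far
# into either tail.  The corrected half-life is ln(2)/k_corr, always positive
# and finite.  The correction is negligible for half-lives well below 300
# minutes and pulls negative or enormous observations to finite values.

#' Degradation rate from half-life
#'
#' @param halflife Half-life in minutes, strictly positive (vectorized).
#' @return First-order degradation rate \eqn{k_d = \ln(2)/\vartheta_d}
#'   in 1/min.
#' @export
degradation_rate <- function(halflife) {
  .assert(all(halflife > 0), "half-life must be strictly positive; correct first")
  log(2) / halflife
}

#' Half-life from degradation rate
#'
#' Inverse of [degradation_rate()].
#'
#' @param rate Degradation rate in 1/min, strictly positive (vectorized).
#' @return Half-life in minutes.
#' @export
halflife_from_rate <- function(rate) {
  .assert(all(rate > 0), "degradation rate must be strictly positive")
  log(2) / rate
}

#' Correct observed protein half-lives
#'
#' Converts noisy observed half-lives (any nonzero real, negative allowed)
#' into positive, finite corrected half-lives via a truncated-normal error
#' model on the degradation rate; see the package vignette for the model.
#'
#' @param observed Observed half-life in minutes (vectorized).  May be
#'   negative or infinite; must not be exactly zero.
#' @param max_reliable Longest reliably measurable half-life in minutes
#'   (default 300); sets the error scale of the rate measurement.
#' @param error_model `"rate"` (default): the error s.d. is the degradation
#'   rate of a `max_reliable`-minute half-life, \eqn{\sigma_k =
#'   \ln(2)/300}/min.  `"inverse"`: the alternative reading
#'   \eqn{\sigma_k = 1/(300 \ln 2)}/min, for sensitivity analysis.
#' @return Corrected half-life in minutes, positive and finite.
#' @examples
#' correct_halflife(c(-100, 10, 1e6))
#' correct_halflife(Inf) # 300 * sqrt(pi/2), the half-normal limit
#' @export
correct_halflife <- function(observed, max_reliable = 300,
                             error_model = c("rate", "inverse")) {
  error_model <- match.arg(error_model)
  .assert(all(!is.na(observed)), "observed half-life must not be NA")
  .assert(all(observed != 0), "an observed half-life of exactly 0 is undefined")
  sigma <- if (error_model == "rate") log(2) / max_reliable
           else 1 / (max_reliable * log(2))
  k_obs <- log(2) / observed          # negative when the observation is negative
  h <- k_obs / sigma
  mills <- exp(dnorm(h, log = TRUE) - pnorm(h, log.p = TRUE))
  k_corr <- k_obs + sigma * mills     # mean of N(k_obs, sigma^2) on (0, Inf)
  log(2) / k_corr
}

#' Correct a half-life table
#'
#' Table version of [correct_halflife()]: adds corrected half-lives and
#' degradation rates to a tibble of observations.
#'
#' @param halflives Tibble with columns `gene`, `observed_halflife` (minutes;
#'   as from [read_halflife_tsv()]).
#' @inheritParams correct_halflife
#' @return The input with columns `corrected_halflife` (minutes) and `k_d`
#'   (1/min) added.
#' @export
correct_halflives <- function(halflives, max_reliable = 300,
                              error_model = c("rate", "inverse")) {
  .check_cols(halflives, c("gene", "observed_halflife"), "half-life table")
  halflives |>
    dplyr::mutate(
      corrected_halflife = correct_halflife(.data$observed_halflife,
                                            max_reliable = max_reliable,
                                            error_model = error_model),
      k_d = degradation_rate(.data$corrected_halflife))
}
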