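# Seeded synthetic-data generator.
#
# Each synthetic gene has sinusoidal transcription m(t) = m0 + A sin(2 pi t /
# T + phi) (always positive: A < m0), a constant half-life drawn over the
# physiological range, and a translation rate; the corresponding protein
# trajectory has the closed form implemented in analytic_periodic_protein(),
# which serves as the solver oracle.  Expression measurements are encoded as
# log2 ratios relative to the gene mean with additive Gaussian noise in log2
# space (the microarray modality); protein measurements carry bounded
# multiplicative error (up to `factor`-fold, emulating western-blot
# inaccuracy); observed half-lives emulate decay-rate measurements by
# perturbing the true degradation rate with N(0, (ln2/300)^2) and inverting,
# which reproduces the negative and enormous values seen in real half-life
# compendia.

#' Draw a cohort of synthetic genes with known kinetic ground truth
#'
#' @param n_genes Number of genes.
#' @param period Transcriptional period T in minutes (default 60).
#' @param k_trans_range Range for log-uniform translation rates
#'   (proteins/mRNA/min).
#' @param halflife_range Range for log-uniform half-lives (minutes).
#' @param m0_range Range for log-uniform baseline mRNA (molecules/cell).
#' @param amp_frac_range Range for the oscillation amplitude as a fraction of
#'   the baseline (kept below 1 so mRNA stays positive).
#' @param seed Integer seed; all randomness is drawn from it.
#' @return Tibble with columns `gene`, `k_trans`, `halflife`, `m0`,
#'   `amplitude`, `phase`, `period`.
#' @export
synthetic_genes <- function(n_genes, period = 60,
                            k_trans_range = c(0.5, 10),
                            halflife_range = c(5, 300),
                            m0_range = c(2, 50),
                            amp_frac_range = c(0.2, 0.8),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runif_log <- function(n, r) exp(runif(n, log(r[1]), log(r[2])))
  m0 <- runif_log(n_genes, m0_range)
  tibble::tibble(
    gene = sprintf("G%04d", seq_len(n_genes)),
    k_trans = runif_log(n_genes, k_trans_range),
    halflife = runif_log(n_genes, halflife_range),
    m0 = m0,
    amplitude = m0 * runif(n_genes, amp_frac_range[1], amp_frac_range[2]),
    phase = runif(n_genes, 0, 2 * pi),
    period = period)
}

#' Sinusoidal or square-wave mRNA concentration
#'
#' @param t Time in minutes (vectorized).
#' @param m0 Baseline concentration (molecules/cell).
#' @param amplitude Oscillation amplitude, `< m0`.
#' @param period Period in minutes.
#' @param phase Phase in radians.
#' @param shape `"sine"` (default) or `"square"` (same fundamental period).
#' @return mRNA concentration at `t`.
#' @export
mrna_profile <- function(t, m0, amplitude, period, phase = 0,
                         shape = c("sine", "square")) {
  shape <- match.arg(shape)
  .assert(m0 > amplitude && amplitude >= 0,
          "need m0 > amplitude >= 0 so mRNA stays positive")
  s <- sin(2 * pi * t / period + phase)
  if (shape == "square") s <- sign(s)
  m0 + amplitude * s
}

#' Simulate expression measurements and companion tables for a gene cohort
#'
#' Generates log2-ratio expression measurements at `sample_times`, the
#' averages table (true baseline mRNA and the true cycle-average protein
#' level \eqn{k_{trans} m_0 / k_d}), and an observed half-life table with
#' Belle-style rate noise.  Fully reproducible for a fixed seed.
#'
#' @param genes Tibble from [synthetic_genes()].
#' @param sample_times Measurement times in minutes (default every 5 min
#'   over one cycle, excluding the duplicate endpoint).  Times may extend
#'   over several cycles (typical for period estimation); for protein
#'   prediction the solver only uses `[0, period]`, so either restrict the
#'   times or truncate downstream.
#' @param log2_noise_sd Additive Gaussian noise s.d. in log2 space
#'   (default 0.2).
#' @param halflife_noise_sd Noise s.d. on the observed degradation rate
#'   (1/min; default `log(2)/300`, the error scale of half-life compendia).
#' @param seed Integer seed.
#' @return A list of class `synthetic_experiment`: `expression` (gene, time,
#'   log2_ratio), `averages` (gene, mean_mrna, mean_protein), `halflives`
#'   (gene, observed_halflife, true_halflife), and `truth` (the input gene
#'   table).
#' @export
simulate_expression <- function(genes, sample_times = seq(0, 55, by = 5),
                                log2_noise_sd = 0.2,
                                halflife_noise_sd = log(2) / 300,
                                seed = NULL) {
  .check_cols(genes, c("gene", "k_trans", "halflife", "m0", "amplitude",
                       "phase", "period"), "genes")
  .assert(all(sample_times >= 0), "sample_times must be non-negative")
  .assert(all(genes$m0 > genes$amplitude), "need m0 > amplitude")
  if (!is.null(seed)) set.seed(seed)

  expression <- purrr::pmap(genes, function(gene, m0, amplitude, period,
                                            phase, ...) {
    m <- mrna_profile(sample_times, m0, amplitude, period, phase)
    tibble::tibble(gene = gene, time = sample_times,
                   log2_ratio = log2(m) - mean(log2(m)))
  }) |>
    purrr::list_rbind()
  expression$log2_ratio <- expression$log2_ratio +
    rnorm(nrow(expression), 0, log2_noise_sd)

  k_d <- log(2) / genes$halflife
  averages <- tibble::tibble(gene = genes$gene,
                             mean_mrna = genes$m0,
                             mean_protein = genes$k_trans * genes$m0 / k_d)
  k_obs <- k_d + rnorm(nrow(genes), 0, halflife_noise_sd)
  halflives <- tibble::tibble(gene = genes$gene,
                              observed_halflife = log(2) / k_obs,
                              true_halflife = genes$halflife)
  structure(list(expression = expression, averages = averages,
                 halflives = halflives, truth = genes),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("Synthetic experiment: %d genes, %d time points, period %g min\n",
              nrow(x$truth), length(unique(x$expression$time)),
              x$truth$period[1]))
  invisible(x)
}

#' Closed-form periodic protein trajectory for sinusoidal transcription
#'
#' For \eqn{m(t) = m_0 + A \sin(\omega t + \phi)}, the periodic solution of
#' \eqn{dP/dt = k_{trans} m(t) - k_d P} is
#' \deqn{P(t) = k_{trans}\left[\frac{m_0}{k_d} +
#'   \frac{A}{\sqrt{k_d^2 + \omega^2}}
#'   \sin(\omega t + \phi - \arctan(\omega/k_d))\right].}
#' Serves as the independent analytic oracle for the numeric solver.
#'
#' @param t Time in minutes (vectorized).
#' @param m0 Baseline mRNA (molecules/cell).
#' @param amplitude Oscillation amplitude `A`.
#' @param omega Angular frequency in rad/min (\eqn{2\pi/T}).
#' @param phase Phase \eqn{\phi} in radians.
#' @param k_trans Translation rate (proteins/mRNA/min).
#' @param k_d Degradation rate (1/min), positive.
#' @return Protein concentration at `t` (molecules/cell).
#' @export
analytic_periodic_protein <- function(t, m0, amplitude, omega, phase,
                                      k_trans, k_d) {
  .assert(k_d > 0, "k_d must be positive")
  k_trans * (m0 / k_d + amplitude / sqrt(k_d^2 + omega^2) *
               sin(omega * t + phase - atan(omega / k_d)))
}

#' Simulate a western-blot-like measured protein profile
#'
#' Applies independent bounded multiplicative noise (log-uniform on
#' `[1/factor, factor]`, default 2-fold, the stated western-blot inaccuracy)
#' to a protein trajectory sampled at given times, then rescales to unit
#' mean (band intensities are relative).
#'
#' @param times Sampling times in minutes.
#' @param values Protein values at `times` (any positive scale).
#' @param factor Maximal fold error, `>= 1` (default 2).
#' @param seed Integer seed.
#' @return Tibble with columns `t_min`, `intensity_au` (unit mean).
#' @export
simulate_measured_protein <- function(times, values, factor = 2, seed = NULL) {
  .assert(factor >= 1, "factor must be >= 1")
  .assert(length(times) == length(values), "times and values must align")
  if (!is.null(seed)) set.seed(seed)
  u <- exp(runif(length(values), -log(factor), log(factor)))
  v <- values * u
  tibble::tibble(t_min = times, intensity_au = v / mean(v))
}
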