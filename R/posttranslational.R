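# Post-translational regulation via a time-varying half-life.
#
# A protein whose degradation is switched on/off by the cell-cycle machinery
# (Clb2-style) is modelled by a periodic two-level step function: half-life
# theta1 inside a window [t0, t0 + K] (interpreted modulo the period, closed
# at both ends) and theta2 outside it.  The kinetic recurrence generalizes to
#   R_{n+1} = ((2 - k_n dt) R_n + dt (m_{n+1} + m_n)) / (2 + k_{n+1} dt),
# with k evaluated at the interval endpoints; for theta1 = theta2 this is
# exactly the constant-k recurrence.  Fitting scans all (theta1, theta2, t0,
# K) tuples on a 1-minute grid, solves the model per tuple through the
# one-pass closed-form fixed point (compiled code), and scores the sum of
# squared differences between the unit-mean-normalized predicted and measured
# profiles at the measured times; band intensities are relative, and
# normalization also cancels k_trans, so no protein calibration is needed.

#' Periodic step-function half-life
#'
#' @param theta1 Half-life (minutes) inside the window, `>= 1`.
#' @param theta2 Half-life (minutes) outside the window, `>= 1`.
#' @param t0 Window start (minutes) in `[0, period)`.
#' @param K Window length (minutes) in `(0, period]`.
#' @param period Period T in minutes.
#' @return An object of class `step_halflife`.
#' @export
step_halflife <- function(theta1, theta2, t0, K, period) {
  .assert(theta1 >= 1 && theta2 >= 1, "step half-lives must be >= 1 minute")
  .assert(t0 >= 0 && t0 < period, "t0 must lie in [0, period)")
  .assert(K > 0 && K <= period, "K must lie in (0, period]")
  .assert(period > 0, "period must be positive")
  structure(list(theta1 = theta1, theta2 = theta2, t0 = t0, K = K,
                 period = period),
            class = "step_halflife")
}

#' @export
print.step_halflife <- function(x, ...) {
  cat(sprintf(paste0("Step half-life (T = %g min): %g min inside [%g, %g] ",
                     "(mod T), %g min outside\n"),
              x$period, x$theta1, x$t0, x$t0 + x$K, x$theta2))
  invisible(x)
}

#' Half-life at a time point under a step function
#'
#' The window `[t0, t0 + K]` is closed and wrapped modulo the period.
#'
#' @param t Time in minutes (vectorized).
#' @param s A [step_halflife()].
#' @return Half-life in minutes at each `t`.
#' @export
halflife_at <- function(t, s) {
  .assert(inherits(s, "step_halflife"), "`s` must be a step_halflife")
  tm <- t %% s$period
  w_end <- s$t0 + s$K
  eps <- 1e-9
  inside <- if (w_end <= s$period + eps) {
    tm >= s$t0 - eps & tm <= w_end + eps
  } else {
    tm >= s$t0 - eps | tm <= (w_end - s$period) + eps
  }
  ifelse(inside, s$theta1, s$theta2)
}

#' Degradation rate at a time point under a step function
#'
#' @inheritParams halflife_at
#' @return \eqn{k_d(t) = \ln(2)/\vartheta_d(t)} in 1/min.
#' @export
degradation_rate_at <- function(t, s) log(2) / halflife_at(t, s)

# kd values on the closed grid for a step_halflife
.kd_grid <- function(s, n_points, dt) {
  degradation_rate_at(seq(0, (n_points - 1) * dt, by = dt), s)
}

#' Solve the periodic model with a time-varying degradation rate
#'
#' Fixed-point iteration of the generalized trapezoidal recurrence with
#' \eqn{k_d(t) = \ln(2)/\vartheta_d(t)} evaluated at the interval endpoints.
#' With `theta1 = theta2` the recurrence constants are identical to the
#' constant-rate solver, so the output matches [solve_periodic_R()]
#' bit for bit.
#'
#' @inheritParams solve_periodic_R
#' @param s A [step_halflife()], or a numeric vector of degradation rates on
#'   the closed grid (length `T/dt + 1`).
#' @return An `r_series`; its `k_d` element is the rate vector.
#' @export
solve_periodic_R_variable <- function(mgrid, s, dt = 1, tol = 5e-10,
                                      max_sweeps = 1e6) {
  g <- .as_grid_values(mgrid)
  m <- g$m; dt <- g$dt %||% dt
  kd <- if (inherits(s, "step_halflife")) .kd_grid(s, length(m), dt)
        else as.numeric(s)
  .assert(length(kd) == length(m), "rate vector must match the grid length")
  .check_kd_dt(kd, dt)
  R0 <- 0
  for (sw in seq_len(max_sweeps)) {
    R <- .sweep_R(R0, m, kd, dt)
    res <- abs(R[length(R)] - R0)
    if (res <= tol) {
      out <- .new_r_series(R, dt, kd, iterations = sw, residual = res)
      return(out)
    }
    R0 <- R[length(R)]
  }
  stop("fixed-point iteration did not converge; try closed_form_R_variable()",
       call. = FALSE)
}

#' One-pass closed-form periodic solution with a time-varying rate
#'
#' Writes one sweep as the affine map \eqn{R(T) = A R(0) + p} with
#' \eqn{A = \prod_n a_n} and solves \eqn{R(0) = p/(1 - A)} exactly, then
#' propagates once to obtain the trajectory.  Used per tuple by the
#' grid-search fit.
#'
#' @inheritParams solve_periodic_R_variable
#' @return An `r_series`.
#' @export
closed_form_R_variable <- function(mgrid, s, dt = 1) {
  g <- .as_grid_values(mgrid)
  m <- g$m; dt <- g$dt %||% dt
  kd <- if (inherits(s, "step_halflife")) .kd_grid(s, length(m), dt)
        else as.numeric(s)
  .assert(length(kd) == length(m), "rate vector must match the grid length")
  .check_kd_dt(kd, dt)
  N <- length(m) - 1L
  A <- 1; p <- 0
  for (n in seq_len(N)) {
    denom <- 2 + kd[n + 1L] * dt
    a <- (2 - kd[n] * dt) / denom
    p <- a * p + dt / denom * (m[n + 1L] + m[n])
    A <- A * a
  }
  .assert(1 - A > .Machine$double.eps,
          "degradation rates too small for a periodic solution")
  R0 <- p / (1 - A)
  R <- .sweep_R(R0, m, kd, dt)
  .new_r_series(R, dt, kd, iterations = 1L, residual = abs(R[length(R)] - R0))
}

# map measured times onto grid indices (0-based), erroring off-grid
.measured_indices <- function(times, period, dt) {
  idx <- times / dt
  .assert(all(abs(idx - round(idx)) < 1e-6),
          "measured times must fall on the integration grid")
  idx <- as.integer(round(idx))
  .assert(all(idx >= 0 & idx <= round(period / dt)),
          "measured times must lie within [0, period]")
  idx
}

#' Fit a periodic step-function half-life to a measured protein profile
#'
#' Exhaustive grid search over all tuples (`theta1`, `theta2`, `t0`, `K`):
#' half-lives from `theta_range` (default 1--40 min step 1), window start
#' `t0` over `0..T-1` and length `K` over `1..T` (1-minute steps).  For each
#' tuple the periodic model is solved through the one-pass closed-form fixed
#' point, the predicted profile is sampled at the measured times, and both
#' profiles are normalized to unit mean before scoring, so the fit is
#' invariant to the arbitrary units of band intensities (and to `k_trans`).
#' Ties are broken deterministically toward the lexicographically smallest
#' (`theta1`, `theta2`, `t0`, `K`).
#'
#' @param mgrid mRNA concentration grid for the gene: numeric vector on the
#'   closed grid or single-gene tibble with `time`, `mrna`.
#' @param measured Measured protein profile: tibble with columns `t_min` (or
#'   `time`) and `intensity_au` (or `intensity`), at least 4 points within
#'   `[0, T]`, positive mean; times must fall on the grid.
#' @param period Period T in minutes (inferred from a tibble `mgrid`).
#' @param dt Grid step in minutes (default 1).
#' @param theta_range Candidate half-lives in minutes (default `1:40`).
#' @param t0_range,K_range Candidate window starts/lengths in minutes
#'   (defaults `0:(T-1)` and `1:T`).
#' @param score `"sse"` (default): sum of squared differences of unit-mean
#'   profiles; `"cor"`: `1 - Pearson r` as the minimized criterion.
#' @param coarse_to_fine If `TRUE`, scan a step-5 coarse grid first and
#'   refine with step 1 around the optimum (much faster, not exhaustive).
#' @param keep_surface If `TRUE`, return the full score surface (one row per
#'   tuple; large).
#' @return An object of class `step_fit`: `best` (a [step_halflife()]),
#'   `score`, `profiles` (tibble of `time`, `measured`, `predicted`, both
#'   unit-mean), `evaluations`, `score_type`, and optionally `surface`.
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
fit_step_halflife <- function(mgrid, measured, period = NULL, dt = 1,
                              theta_range = 1:40, t0_range = NULL,
                              K_range = NULL, score = c("sse", "cor"),
                              coarse_to_fine = FALSE, keep_surface = FALSE) {
  score <- match.arg(score)
  g <- .as_grid_values(mgrid)
  m <- g$m; dt <- g$dt %||% dt
  period <- period %||% ((length(m) - 1L) * dt)
  .assert(abs((length(m) - 1L) * dt - period) < 1e-8,
          "grid length inconsistent with period/dt")

  if (is.data.frame(measured)) {
    tcol <- intersect(c("t_min", "time"), names(measured))[1]
    icol <- intersect(c("intensity_au", "intensity"), names(measured))[1]
    .assert(!is.na(tcol) && !is.na(icol),
            "measured needs columns t_min/time and intensity_au/intensity")
    mt <- measured[[tcol]]; mv <- measured[[icol]]
  } else {
    stop("`measured` must be a data frame of times and intensities",
         call. = FALSE)
  }
  o <- order(mt); mt <- mt[o]; mv <- mv[o]
  .assert(length(mt) >= 4, "need at least 4 measured time points")
  .assert(mean(mv) > 0, "measured profile must have a positive mean")
  idx <- .measured_indices(mt, period, dt)
  meas_norm <- mv / mean(mv)

  t0_range <- t0_range %||% seq(0, period - dt, by = dt)
  K_range <- K_range %||% seq(dt, period, by = dt)
  .assert(all(theta_range >= 1), "candidate half-lives must be >= 1 minute")
  score_code <- if (score == "sse") 0L else 1L

  run <- function(th1, th2, t0s, Ks, surf) {
    cpp_fit_step(m, dt, as.numeric(th1), as.numeric(th2), as.numeric(t0s),
                 as.numeric(Ks), period, idx, meas_norm, score_code, surf)
  }

  if (coarse_to_fine) {
    coarsen <- function(r, step = 5) sort(unique(c(seq(min(r), max(r), by = step), max(r))))
    fit1 <- run(coarsen(theta_range), coarsen(theta_range),
                coarsen(t0_range), coarsen(K_range), FALSE)
    near <- function(centre, r) r[r >= centre - 5 & r <= centre + 5]
    fit <- run(near(fit1$theta1, theta_range), near(fit1$theta2, theta_range),
               near(fit1$t0, t0_range), near(fit1$K, K_range), keep_surface)
    evals <- fit1$evaluations + fit$evaluations
  } else {
    fit <- run(theta_range, theta_range, t0_range, K_range, keep_surface)
    evals <- fit$evaluations
  }

  best <- step_halflife(fit$theta1, fit$theta2, fit$t0, fit$K, period)
  r <- closed_form_R_variable(m, best, dt)
  pred <- r$values[idx + 1L]
  profiles <- tibble::tibble(time = mt, measured = meas_norm,
                             predicted = pred / mean(pred))
  out <- structure(list(best = best, score = fit$score, profiles = profiles,
                        evaluations = evals, score_type = score,
                        period = period, dt = dt),
                   class = "step_fit")
  if (keep_surface && !is.null(fit$surface)) out$surface <- fit$surface
  out
}

#' @export
print.step_fit <- function(x, ...) {
  cat("Step-function half-life fit\n")
  cat(sprintf("  theta1 = %g min inside [%g, %g] (mod %g), theta2 = %g min\n",
              x$best$theta1, x$best$t0, x$best$t0 + x$best$K, x$period,
              x$best$theta2))
  cat(sprintf("  score (%s): %.6g over %d measured points (%s tuples evaluated)\n",
              x$score_type, x$score, nrow(x$profiles),
              format(x$evaluations, big.mark = ",")))
  invisible(x)
}

#' @method tidy step_fit
#' @export
tidy.step_fit <- function(x, ...) {
  tibble::tibble(theta1 = x$best$theta1, theta2 = x$best$theta2,
                 t0 = x$best$t0, K = x$best$K, period = x$period,
                 score = x$score)
}

#' @method glance step_fit
#' @export
glance.step_fit <- function(x, ...) {
  tibble::tibble(score = x$score, evaluations = x$evaluations,
                 n_measured = nrow(x$profiles), score_type = x$score_type)
}

#' @method autoplot step_fit
#' @export
autoplot.step_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profiles, c("measured", "predicted"),
                              names_to = "profile", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$profile)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$profile == "predicted")) +
    ggplot2::geom_point() +
    ggplot2::annotate("rect", xmin = object$best$t0,
                      xmax = min(object$best$t0 + object$best$K, object$period),
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "red") +
    ggplot2::labs(x = "time [min]", y = "unit-mean abundance",
                  title = sprintf("theta1 = %g, theta2 = %g min, window [%g, %g]",
                                  object$best$theta1, object$best$theta2,
                                  object$best$t0, object$best$t0 + object$best$K)) +
    ggplot2::theme_minimal()
}
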