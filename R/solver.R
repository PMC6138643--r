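# Core kinetic solver.
#
# The model is dP/dt = k_trans * M(t) - k_d * P(t) with periodic boundary
# condition P(0) = P(T).  Dividing by k_trans gives the k_trans-free
# trajectory R(t) = P(t)/k_trans, which satisfies the same ODE with unit
# source.  Trapezoidal (Crank-Nicolson) integration over one step dt yields
# the recurrence
#   R(t+dt) = (2 - k_d dt)/(2 + k_d dt) * R(t)
#           + dt/(2 + k_d dt) * (M(t+dt) + M(t)),
# which is swept across one period; the periodic solution is the fixed point
# of the sweep map R(0) -> R(T), found either by fixed-point iteration
# (starting from R(0) = 0, contraction factor a^N ~ exp(-k_d T) per sweep)
# or in closed form by summing the geometric series.  k_trans then follows
# from the literature average protein level: k_trans = <P> / <R>, with
# period means taken over grid points 0..N-1 (the wrapped endpoint T
# duplicates point 0).

# one sweep of the (possibly time-varying-k) trapezoidal recurrence across
# the grid; kd has length N+1 (values at grid times), m likewise
.sweep_R <- function(R0, m, kd, dt) {
  N <- length(m) - 1L
  R <- numeric(N + 1L)
  R[1L] <- R0
  for (n in seq_len(N)) {
    R[n + 1L] <- ((2 - kd[n] * dt) * R[n] + dt * (m[n + 1L] + m[n])) /
      (2 + kd[n + 1L] * dt)
  }
  R
}

.check_kd_dt <- function(kd, dt) {
  .assert(all(kd > 0), "degradation rate must be strictly positive")
  .assert(dt > 0, "dt must be positive")
  .assert(all(kd * dt < 2),
          "k_d * dt >= 2: trapezoidal scheme not contractive; reduce dt")
}

.as_grid_values <- function(mgrid) {
  if (is.data.frame(mgrid)) {
    .check_cols(mgrid, c("time", "mrna"), "mRNA grid")
    .assert(length(unique(mgrid$gene %||% "g")) == 1,
            "mRNA grid must contain a single gene")
    mgrid <- mgrid[order(mgrid$time), ]
    dts <- diff(mgrid$time)
    .assert(max(abs(dts - dts[1])) < 1e-8, "mRNA grid must be uniform")
    list(m = mgrid$mrna, dt = dts[1])
  } else {
    list(m = as.numeric(mgrid), dt = NULL)
  }
}

.new_r_series <- function(values, dt, k_d, iterations, residual) {
  structure(list(values = values, time = seq(0, (length(values) - 1) * dt, by = dt),
                 dt = dt, period = (length(values) - 1) * dt, k_d = k_d,
                 iterations = iterations, residual = residual),
            class = "r_series")
}

#' @export
print.r_series <- function(x, ...) {
  cat(sprintf("Periodic R(t) trajectory: T = %g min, dt = %g min\n",
              x$period, x$dt))
  cat(sprintf("  sweeps: %s   residual |R(T)-R(0)|: %.3g\n",
              format(x$iterations), x$residual))
  cat(sprintf("  mean over one period: %.6g\n",
              mean(x$values[-length(x$values)])))
  invisible(x)
}

#' One step of the trapezoidal recurrence
#'
#' Advances the scaled protein trajectory \eqn{R(t) = P(t)/k_{trans}} by one
#' step `dt` given the mRNA concentrations at both ends of the interval:
#' \deqn{R(t+\Delta t) = \frac{2 - k_d \Delta t}{2 + k_d \Delta t} R(t)
#'   + \frac{\Delta t}{2 + k_d \Delta t} (M(t+\Delta t) + M(t)).}
#'
#' @param R_t Current value of R (molecules * min / cell).
#' @param m_t,m_next mRNA concentration at `t` and `t + dt` (molecules/cell).
#' @param k_d Degradation rate (1/min), with `k_d * dt < 2`.
#' @param dt Step size in minutes.
#' @return R at `t + dt`.
#' @export
step_R <- function(R_t, m_t, m_next, k_d, dt = 1) {
  .check_kd_dt(k_d, dt)
  (2 - k_d * dt) / (2 + k_d * dt) * R_t + dt / (2 + k_d * dt) * (m_next + m_t)
}

#' Solve the periodic kinetic model by fixed-point iteration
#'
#' Repeatedly sweeps the trapezoidal recurrence across one period, feeding
#' \eqn{R(T)} back as the next sweep's \eqn{R(0)} (starting from
#' \eqn{R(0) = 0}), until \eqn{|R(T) - R(0)| \le} `tol`.  The per-sweep
#' contraction factor is \eqn{a^N \approx \exp(-k_d T)}, so convergence is
#' slow for very long half-lives; [closed_form_R()] computes the same fixed
#' point in one pass and is the recommended fallback there.
#'
#' @param mgrid mRNA concentrations on the closed uniform grid `0..T` step
#'   `dt`: either a numeric vector of length `T/dt + 1` or a single-gene
#'   tibble with columns `time`, `mrna` (as from [interpolate_minute_grid()]).
#' @param k_d Degradation rate (1/min), with `k_d * dt < 2`.
#' @param dt Step size in minutes (ignored when `mgrid` is a tibble).
#' @param tol Convergence tolerance on \eqn{|R(T) - R(0)|} (default 5e-10).
#' @param max_sweeps Maximum number of sweeps before giving up.
#' @param history If `TRUE`, attach the per-sweep residual sequence as the
#'   `residuals` element (diagnostic for the contraction rate).
#' @return An object of class `r_series`: `values` (R on the grid), `time`,
#'   `dt`, `period`, `k_d`, `iterations`, `residual`.
#' @export
solve_periodic_R <- function(mgrid, k_d, dt = 1, tol = 5e-10,
                             max_sweeps = 1e6, history = FALSE) {
  g <- .as_grid_values(mgrid)
  m <- g$m; dt <- g$dt %||% dt
  .assert(length(m) >= 2, "grid needs at least 2 points")
  .check_kd_dt(k_d, dt)
  kd <- rep(k_d, length(m))
  R0 <- 0
  res_hist <- if (history) numeric(0) else NULL
  for (s in seq_len(max_sweeps)) {
    R <- .sweep_R(R0, m, kd, dt)
    res <- abs(R[length(R)] - R0)
    if (history) res_hist <- c(res_hist, res)
    if (res <= tol) {
      out <- .new_r_series(R, dt, k_d, iterations = s, residual = res)
      if (history) out$residuals <- res_hist
      return(out)
    }
    R0 <- R[length(R)]
  }
  stop(sprintf(paste0("fixed-point iteration did not converge in %d sweeps ",
                      "(contraction ~ exp(-k_d*T) = %.4g); ",
                      "use closed_form_R() for long half-lives"),
               max_sweeps, exp(-k_d * (length(m) - 1) * dt)), call. = FALSE)
}

#' Closed-form periodic starting value R(0)
#'
#' Analytic fixed point of the sweep map: with \eqn{a = (2 - k_d
#' dt)/(2 + k_d dt)}, \eqn{b = dt/(2 + k_d dt)} and \eqn{N = T/dt},
#' \deqn{R(0) = \frac{\sum_{n=0}^{N-1} a^{N-1-n}\, b\, (m_{n+1} + m_n)}
#'   {1 - a^N}.}
#' Feeding this value into one sweep reproduces \eqn{R(T) = R(0)} to machine
#' precision.
#'
#' @inheritParams solve_periodic_R
#' @return The scalar R(0) of the exact periodic solution of the recurrence.
#' @export
closed_form_R0 <- function(mgrid, k_d, dt = 1) {
  g <- .as_grid_values(mgrid)
  m <- g$m; dt <- g$dt %||% dt
  .check_kd_dt(k_d, dt)
  N <- length(m) - 1L
  a <- (2 - k_d * dt) / (2 + k_d * dt)
  b <- dt / (2 + k_d * dt)
  aN <- a^N
  .assert(1 - aN > .Machine$double.eps,
          "degradation rate too small for a periodic solution (a^N ~ 1)")
  sum(a^((N - 1L):0) * b * (m[-1L] + m[-(N + 1L)])) / (1 - aN)
}

#' Closed-form periodic solution of the recurrence
#'
#' Computes [closed_form_R0()] and propagates it across one period, giving
#' the exact periodic trajectory in a single pass (no iteration).
#'
#' @inheritParams solve_periodic_R
#' @return An `r_series` (with `iterations = 1`).
#' @export
closed_form_R <- function(mgrid, k_d, dt = 1) {
  g <- .as_grid_values(mgrid)
  m <- g$m; dt <- g$dt %||% dt
  R0 <- closed_form_R0(m, k_d, dt)
  R <- .sweep_R(R0, m, rep(k_d, length(m)), dt)
  .new_r_series(R, dt, k_d, iterations = 1L,
                residual = abs(R[length(R)] - R0))
}

#' Translation rate from the average protein level
#'
#' \eqn{k_{trans} = \langle P \rangle / \langle R \rangle}, where both means
#' are over one period (grid points `0..N-1`; the wrapped endpoint T
#' duplicates point 0).
#'
#' @param mean_protein Literature cell-cycle average protein concentration
#'   (molecules/cell), strictly positive.
#' @param r An `r_series` from [solve_periodic_R()]/[closed_form_R()], or a
#'   numeric vector of R values on the closed grid.
#' @return Translation rate in proteins per mRNA per minute.
#' @export
compute_k_trans <- function(mean_protein, r) {
  .assert(mean_protein > 0, "mean_protein must be strictly positive")
  vals <- if (inherits(r, "r_series")) r$values else as.numeric(r)
  mean_r <- mean(vals[-length(vals)])
  .assert(mean_r > 0, "mean R must be positive (is the mRNA grid all zero?)")
  mean_protein / mean_r
}

#' Scale the R trajectory to a protein time-course
#'
#' \eqn{P(t) = k_{trans} R(t)}.  By construction the mean of the result over
#' one period equals the `mean_protein` used in [compute_k_trans()].
#'
#' @param r An `r_series` or numeric vector of R values on the closed grid.
#' @param k_trans Translation rate (proteins/mRNA/min), strictly positive.
#' @param dt Grid step (ignored when `r` is an `r_series`).
#' @return Tibble with columns `time` (minutes) and `protein`
#'   (molecules/cell); attribute `"k_trans"`.
#' @export
predict_protein <- function(r, k_trans, dt = 1) {
  .assert(k_trans > 0, "k_trans must be strictly positive")
  if (inherits(r, "r_series")) {
    vals <- r$values; time <- r$time
  } else {
    vals <- as.numeric(r); time <- seq(0, (length(vals) - 1) * dt, by = dt)
  }
  out <- tibble::tibble(time = time, protein = k_trans * vals)
  attr(out, "k_trans") <- k_trans
  out
}
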