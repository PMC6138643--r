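# Periodicity statistics for unevenly sampled expression series.
#
# Two statistics are provided.  The default, "power", is the floating-mean
# (generalized) least-squares periodogram: the series is regressed on
# {1, cos(2*pi*t/T), sin(2*pi*t/T)} and the power is the chi^2-normalized
# variance reduction (N-1)/2 * R^2, whose null distribution on Gaussian white
# noise is approximately Exp(1), so that z = exp(-power) behaves like a
# p-value.  The "eq4" statistic is the amplitude-like square-root form
# P(T) = 2/((b-a) sigma^2) * sqrt(C^2 + S^2) with C, S trapezoidal-quadrature
# estimates of the cosine/sine integrals of the series over [a, b]; it is
# kept for fidelity but is not probability-calibrated.

# floating-mean least-squares power at one trial period
.ls_power <- function(times, values, period) {
  n <- length(values)
  s2 <- var(values)
  if (s2 <= 0) return(0)
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  fit <- stats::.lm.fit(X, values)
  ss0 <- s2 * (n - 1)
  rss <- sum(fit$residuals^2)
  r2 <- max(0, 1 - rss / ss0)
  (n - 1) / 2 * r2
}

# literal square-root periodogram via trapezoidal quadrature
.eq4_power <- function(times, values, period) {
  s2 <- var(values)
  if (s2 <= 0) return(0)
  a <- min(times); b <- max(times)
  w <- 2 * pi / period
  C <- .trapz(times, values * cos(w * times))
  S <- .trapz(times, values * sin(w * times))
  2 / ((b - a) * s2) * sqrt(C^2 + S^2)
}

#' Per-gene periodogram over a grid of candidate periods
#'
#' Computes, for every gene and every candidate period, a measure of how much
#' of the series' variance is explained by a sinusoid of that period, plus
#' the corresponding significance \eqn{z = \exp(-P)}.
#'
#' @param expression Long tibble with columns `gene`, `time` and one value
#'   column (`log2_ratio`, `mrna` or `value`); uneven sampling is fine.
#' @param periods Numeric vector of candidate periods in minutes (default
#'   30--150 step 1, wide enough for yeast cell-cycle data).
#' @param stat `"power"` (default) for the floating-mean least-squares
#'   periodogram whose null is approximately Exp(1), or `"eq4"` for the
#'   literal amplitude-like square-root form.  Only `"power"` makes `z`
#'   probability-like.
#' @return Tibble with columns `gene`, `period`, `power`, `z`, `constant`
#'   (`TRUE` for zero-variance series, whose power is 0 at all periods).
#' @export
periodogram <- function(expression, periods = 30:150,
                        stat = c("power", "eq4")) {
  stat <- match.arg(stat)
  .check_cols(expression, c("gene", "time"), "expression")
  value_col <- intersect(c("log2_ratio", "mrna", "value"), names(expression))[1]
  .assert(!is.na(value_col),
          "expression needs a value column: log2_ratio, mrna or value")
  .assert(all(periods > 0), "candidate periods must be positive")
  periods <- sort(periods)
  pfun <- if (stat == "power") .ls_power else .eq4_power

  per_gene <- function(df, id) {
    y <- df[[value_col]]
    t <- df$time
    if (length(y) < 4) {
      stop(sprintf("gene %s has fewer than 4 points; periodogram undefined", id),
           call. = FALSE)
    }
    if (var(y) <= 0) {
      warning(sprintf("gene %s has constant expression; power set to 0", id),
              call. = FALSE)
      return(tibble::tibble(period = periods, power = 0,
                            z = 1, constant = TRUE))
    }
    p <- vapply(periods, function(T) pfun(t, y, T), numeric(1))
    tibble::tibble(period = periods, power = p, z = exp(-p), constant = FALSE)
  }

  expression |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(~ per_gene(.x, .y$gene)) |>
    dplyr::ungroup()
}

#' Significance of a periodogram power
#'
#' Under the Gaussian null hypothesis the normalized periodogram power at a
#' fixed period is approximately exponentially distributed, so the
#' probability of observing a power this large by chance is
#' \eqn{z = \exp(-P)}.
#'
#' @param power Non-negative periodogram power (vectorized).
#' @return `z` in (0, 1], monotone decreasing in `power`.
#' @export
significance <- function(power) {
  .assert(all(is.finite(power)) && all(power >= 0),
          "power must be finite and non-negative")
  exp(-power)
}

#' Consensus period of transcriptional oscillation
#'
#' Maximum-likelihood estimate of the shared period: for each gene the log
#' likelihood of periodicity at a trial period is \eqn{-\log z = P} (the
#' floating-mean periodogram power); summing over genes gives the total log
#' likelihood of each candidate period, and the maximizing period is adopted
#' as the consensus.  Ties are broken toward the smallest period.
#'
#' @inheritParams periodogram
#' @return An object of class `consensus_period` with elements `best_period`,
#'   `likelihood` (tibble of `period`, `total_loglik`, `n_genes`), and
#'   `n_genes`.  Supports [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
consensus_period <- function(expression, periods = 30:150) {
  pg <- periodogram(expression, periods = periods, stat = "power")
  usable <- dplyr::filter(pg, !.data$constant)
  .assert(nrow(usable) > 0, "no periodic signal: all series are constant")
  lik <- usable |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(total_loglik = sum(.data$power),
                     n_genes = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$period)
  best <- lik$period[which.max(lik$total_loglik)]
  structure(list(best_period = best, likelihood = lik,
                 n_genes = length(unique(usable$gene)), periods = sort(periods)),
            class = "consensus_period")
}

#' @export
print.consensus_period <- function(x, ...) {
  cat("Consensus period of transcriptional oscillation\n")
  cat(sprintf("  genes: %d   candidate periods: %g..%g min\n",
              x$n_genes, min(x$periods), max(x$periods)))
  cat(sprintf("  best period: %g min (total log-likelihood %.4g)\n",
              x$best_period, max(x$likelihood$total_loglik)))
  invisible(x)
}

#' @method tidy consensus_period
#' @export
tidy.consensus_period <- function(x, ...) x$likelihood

#' @method glance consensus_period
#' @export
glance.consensus_period <- function(x, ...) {
  tibble::tibble(best_period = x$best_period,
                 max_loglik = max(x$likelihood$total_loglik),
                 n_genes = x$n_genes,
                 n_periods = nrow(x$likelihood))
}

#' @method autoplot consensus_period
#' @export
autoplot.consensus_period <- function(object, ...) {
  ggplot2::ggplot(object$likelihood,
                  ggplot2::aes(x = .data$period, y = .data$total_loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_period, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "candidate period [min]",
                  y = "total log-likelihood",
                  title = sprintf("Consensus period: %g min", object$best_period)) +
    ggplot2::theme_minimal()
}
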