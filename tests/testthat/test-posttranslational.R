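test_that("step half-life evaluates inside, outside and across the wrap", {
  s <- step_halflife(1, 22, 10, 20, 60)
  expect_equal(halflife_at(15, s), 1)
  expect_equal(halflife_at(40, s), 22)
  expect_equal(halflife_at(c(10, 30), s), c(1, 1)) # closed endpoints
  sw <- step_halflife(1, 22, 50, 20, 60)
  expect_equal(halflife_at(5, sw), 1)  # wrapped window [50, 70] covers 5
  expect_equal(halflife_at(25, sw), 22)
  expect_equal(degradation_rate_at(15, s), log(2))
  expect_error(step_halflife(0.5, 22, 0, 10, 60), ">= 1")
  expect_error(step_halflife(1, 22, 60, 10, 60), "t0")
})

test_that("a degenerate step function reproduces the constant-rate solver bit for bit", {
  g <- sin_grid(60, 1, 10, 5, 0.3)
  s <- step_halflife(22, 22, 17, 9, 60)
  rv <- solve_periodic_R_variable(g$m, s)
  rc <- solve_periodic_R(g$m, log(2) / 22)
  expect_identical(rv$values, rc$values)
  expect_identical(rv$iterations, rc$iterations)
})

test_that("generalized conservation holds: period mean of k(t) R(t) equals mean mRNA", {
  set.seed(41)
  for (i in 1:20) {
    m <- runif(60, 0.5, 30); m <- c(m, m[1])
    s <- step_halflife(sample(1:40, 1), sample(1:40, 1),
                       sample(0:59, 1), sample(1:60, 1), 60)
    r <- closed_form_R_variable(m, s)
    kd <- degradation_rate_at(r$time, s)
    expect_lt(abs(mean((kd * r$values)[1:60]) / mean(m[1:60]) - 1), 1e-12)
  }
})

test_that("the variable-rate solver matches the piecewise-analytic solution", {
  # constant mRNA, step k(t): the ODE solves in closed form segment by segment
  m0 <- 10; k1 <- log(2) / 1; k2 <- log(2) / 40
  seg <- function(R0, k, dur) m0 / k + (R0 - m0 / k) * exp(-k * dur)
  f_cycle <- function(R0) seg(seg(seg(R0, k2, 20), k1, 20), k2, 20)
  A <- f_cycle(1) - f_cycle(0)
  Rstar0 <- f_cycle(0) / (1 - A)
  exact <- function(t) {
    R20 <- seg(Rstar0, k2, 20); R40 <- seg(R20, k1, 20)
    ifelse(t < 20, seg(Rstar0, k2, t),
           ifelse(t <= 40, seg(R20, k1, t - 20), seg(R40, k2, t - 40)))
  }
  s <- step_halflife(1, 40, 20, 20, 60)
  errs <- sapply(c(1, 0.5, 0.25), function(dt) {
    n <- 60 / dt + 1
    r <- closed_form_R_variable(rep(m0, n), s, dt = dt)
    max(abs(r$values - exact(r$time)))
  })
  # error shrinks with dt (first order at the rate discontinuities, where the
  # endpoint-evaluated k averages across the jump)
  expect_true(all(diff(errs) < 0))
  # deep inside the short-half-life window the trajectory sits at m/k1
  r1 <- closed_form_R_variable(rep(m0, 61), s)
  expect_equal(r1$values[39], exact(38), tolerance = 1e-3)
  expect_equal(r1$values[39], m0 / k1, tolerance = 0.05)
})

test_that("noise-free grid search recovers the generating step function exactly", {
  T <- 60; t <- 0:T
  m <- mrna_profile(t, 10, 5, T, 1)
  truth <- step_halflife(1, 22, 30, 25, T)
  r <- closed_form_R_variable(m, truth)
  meas <- tibble::tibble(t_min = t, intensity_au = r$values)
  fit <- fit_step_halflife(m, meas, period = T)
  expect_equal(tidy(fit)[, 1:4],
               tibble::tibble(theta1 = 1, theta2 = 22, t0 = 30, K = 25))
  expect_lt(fit$score, 1e-18)
  # normalization invariance: scaling the measured profile selects the same
  # parameters (scores agree to rounding of the unit-mean normalization)
  meas2 <- dplyr::mutate(meas, intensity_au = intensity_au * 37.5)
  fit2 <- fit_step_halflife(m, meas2, period = T)
  expect_identical(tidy(fit)[, 1:4], tidy(fit2)[, 1:4])
  expect_lt(fit2$score, 1e-18)
  # coarse-to-fine lands on the same optimum here
  fit3 <- fit_step_halflife(m, meas, period = T, coarse_to_fine = TRUE)
  expect_identical(tidy(fit)[, 1:4], tidy(fit3)[, 1:4])
})

test_that("a constant-half-life profile is fit by an effectively constant step function", {
  T <- 60; t <- 0:T
  m <- mrna_profile(t, 10, 5, T, 1)
  rc <- closed_form_R(m, log(2) / 22)
  meas <- tibble::tibble(t_min = t, intensity_au = rc$values)
  fit <- fit_step_halflife(m, meas, period = T)
  # the selected tuple is score-equivalent to the truth ...
  s_truth <- step_halflife(22, 22, 0, T, T)
  r_best <- closed_form_R_variable(m, fit$best)
  expect_lt(fit$score, 1e-18)
  # ... and its half-life profile is constant at 22 min over the whole cycle
  expect_true(all(halflife_at(t, fit$best) == 22))
  expect_equal(r_best$values, rc$values, tolerance = 1e-12)
})

test_that("fit validates its measured profile", {
  m <- sin_grid(60)$m
  expect_error(fit_step_halflife(m, tibble::tibble(t_min = c(0, 10, 20),
                                                   intensity_au = 1:3),
                                 period = 60), "at least 4")
  expect_error(fit_step_halflife(m, tibble::tibble(t_min = c(0, 10.5, 20, 30),
                                                   intensity_au = 1:4),
                                 period = 60), "grid")
  expect_error(fit_step_halflife(m, tibble::tibble(t_min = seq(0, 30, 10),
                                                   intensity_au = c(-2, 0, 1, -1)),
                                 period = 60), "positive mean")
})
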