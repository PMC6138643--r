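test_that("step_R evaluates the printed recurrence", {
  expect_equal(step_R(0, 0, 0, k_d = 0.1), 0)
  expect_equal(step_R(0, 10, 10, k_d = 0.1, dt = 1), 20 / 2.1)
  # R* = m/k_d is the fixed point under constant forcing
  expect_equal(step_R(100, 10, 10, k_d = 0.1), 100)
  expect_error(step_R(0, 1, 1, k_d = 3, dt = 1), "not contractive")
})

test_that("constant forcing converges to m/k_d in very few sweeps", {
  m <- rep(10, 61)
  r <- solve_periodic_R(m, k_d = 0.1, dt = 1)
  # each sweep contracts by exp(-k_d T) = 0.0025, so a handful suffice
  expect_lte(r$iterations, 8)
  expect_equal(r$values, rep(100, 61), tolerance = 1e-8)
  expect_equal(closed_form_R0(m, 0.1), 100, tolerance = 1e-12)
})

test_that("solver matches the analytic sinusoid oracle at second order in dt", {
  kd <- log(2) / 22; w <- 2 * pi / 60; kt <- 3
  errs <- sapply(c(1, 0.5, 0.25), function(dt) {
    g <- sin_grid(60, dt, m0 = 10, A = 5, phase = 0.7)
    r <- solve_periodic_R(g$m, kd, dt = dt)
    max(abs(kt * r$values -
              analytic_periodic_protein(g$t, 10, 5, w, 0.7, kt, kd)))
  })
  expect_gt(errs[1] / errs[2], 3); expect_lt(errs[1] / errs[2], 5)
  expect_gt(errs[2] / errs[3], 3); expect_lt(errs[2] / errs[3], 5)
})

test_that("closed form is the fixed point of the sweep and matches iteration", {
  set.seed(21)
  for (i in 1:25) {
    m <- runif(60, 0.5, 40); m <- c(m, m[1])
    kd <- log(2) / exp(runif(1, log(5), log(120)))
    R0 <- closed_form_R0(m, kd)
    swept <- protodyn:::.sweep_R(R0, m, rep(kd, 61), 1)
    expect_lt(abs(swept[61] - R0), 1e-9 * max(1, R0))
    iter <- solve_periodic_R(m, kd, tol = 5e-10)
    rho <- exp(-kd * 60)
    # stopping at |F(R0)-R0| <= tol leaves |R0 - R*| <= tol/(1-rho),
    # plus rounding of the closed-form sum itself
    expect_lt(abs(iter$values[1] - R0), 5e-10 / (1 - rho) + 1e-9)
  }
  expect_error(closed_form_R0(rep(1, 61), k_d = 1e-17), "too small")
})

test_that("non-negative mRNA gives a non-negative periodic trajectory", {
  set.seed(22)
  for (i in 1:10) {
    m <- runif(61, 0, 30); m[61] <- m[1]
    r <- closed_form_R(m, k_d = runif(1, 0.005, 0.5))
    expect_true(all(r$values >= 0))
  }
})

test_that("k_trans scales R so the period-mean protein equals the literature mean", {
  expect_equal(compute_k_trans(1000, c(rep(500, 60), 500)), 2)
  g <- sin_grid(60, 1, 10, 5, 1.2)
  kd <- log(2) / 40
  r <- solve_periodic_R(g$m, kd)
  kt <- compute_k_trans(777, r)
  p <- predict_protein(r, kt)
  expect_equal(mean(p$protein[1:60]), 777, tolerance = 1e-12)
  # constant m: k_trans = <P> k_d / m
  rc <- solve_periodic_R(rep(8, 61), kd)
  expect_equal(compute_k_trans(100, rc), 100 * kd / 8, tolerance = 1e-8)
  # linearity
  expect_equal(predict_protein(r, 2 * kt)$protein, 2 * p$protein)
  expect_error(compute_k_trans(-1, r), "positive")
  expect_error(compute_k_trans(10, rep(0, 61)), "all zero|positive")
})

test_that("fixed-point iteration reports non-convergence for negligible degradation", {
  m <- sin_grid(60)$m
  expect_error(solve_periodic_R(m, k_d = 1e-7, max_sweeps = 10),
               "closed_form_R")
})
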