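test_that("periodogram peaks at the true period of a sampled sinusoid", {
  t <- seq(0, 119, by = 5)
  expr <- tibble::tibble(gene = "g", time = t,
                         log2_ratio = cos(2 * pi * t / 60))
  pg <- periodogram(expr, periods = 40:90)
  expect_equal(pg$period[which.max(pg$power)], 60)
  # the literal amplitude-like statistic peaks nearby but suffers spectral
  # leakage over a non-integer number of cycles
  pg4 <- periodogram(expr, periods = 40:90, stat = "eq4")
  expect_lte(abs(pg4$period[which.max(pg4$power)] - 60), 5)
})

test_that("periodogram power is scale invariant and zero for constant series", {
  t <- sort(runif(20, 0, 120))
  y <- sin(2 * pi * t / 60) + rnorm(20, sd = 0.3)
  e1 <- tibble::tibble(gene = "g", time = t, log2_ratio = y)
  e2 <- tibble::tibble(gene = "g", time = t, log2_ratio = 7 * y)
  expect_equal(periodogram(e1, periods = 50:70)$power,
               periodogram(e2, periods = 50:70)$power,
               tolerance = 1e-10)
  # the literal square-root form scales as 1/c: amplitude over variance
  expect_equal(periodogram(e2, periods = 50:70, stat = "eq4")$power,
               periodogram(e1, periods = 50:70, stat = "eq4")$power / 7,
               tolerance = 1e-10)
  flat <- tibble::tibble(gene = "g", time = t, log2_ratio = rep(1.3, 20))
  expect_warning(pg <- periodogram(flat, periods = 50:70), "constant")
  expect_true(all(pg$power == 0) && all(pg$z == 1) && all(pg$constant))
})

test_that("significance is the exponential of minus the power", {
  expect_equal(significance(0), 1)
  expect_equal(significance(log(2)), 0.5)
  expect_equal(significance(10), exp(-10))
  expect_error(significance(-1), "non-negative")
  p <- seq(0, 20, length.out = 50)
  expect_true(all(diff(significance(p)) < 0))
})

test_that("consensus period recovers the shared period from gene cohorts", {
  set.seed(31)
  t <- seq(0, 119, by = 5)
  mk <- function(id, periodic) {
    y <- if (periodic) sin(2 * pi * t / 60 + runif(1, 0, 2 * pi))
         else rnorm(length(t), sd = 0.5)
    tibble::tibble(gene = id, time = t, log2_ratio = y)
  }
  clean <- purrr::map(sprintf("p%02d", 1:50), mk, periodic = TRUE) |>
    purrr::list_rbind()
  cp <- consensus_period(clean, periods = 40:90)
  expect_equal(cp$best_period, 60)

  # flat-noise genes shift the likelihood roughly uniformly, not the argmax
  noisy <- purrr::map(sprintf("n%02d", 1:50), mk, periodic = FALSE) |>
    purrr::list_rbind()
  cp2 <- consensus_period(dplyr::bind_rows(clean, noisy), periods = 40:90)
  expect_equal(cp2$best_period, 60)

  # a single gene's consensus is its own argmax
  one <- dplyr::filter(clean, gene == "p01")
  pg <- periodogram(one, periods = 40:90)
  cp3 <- consensus_period(one, periods = 40:90)
  expect_equal(cp3$best_period, pg$period[which.max(pg$power)])

  expect_error(suppressWarnings(consensus_period(
    tibble::tibble(gene = "g", time = t, log2_ratio = rep(1, length(t))))),
    "no periodic signal")

  # accessors
  expect_s3_class(tidy(cp), "tbl_df")
  expect_equal(glance(cp)$best_period, 60)
  expect_s3_class(autoplot(cp), "ggplot")
})

test_that("argmax error shrinks below the grid spacing as the grid refines", {
  t <- seq(0, 119, by = 5)
  expr <- tibble::tibble(gene = "g", time = t,
                         log2_ratio = sin(2 * pi * t / 57))
  for (step in c(2, 0.5)) {
    pg <- periodogram(expr, periods = seq(40, 90, by = step))
    expect_lt(abs(pg$period[which.max(pg$power)] - 57), step + 1e-9)
  }
})
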