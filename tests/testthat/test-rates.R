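test_that("steady-state rate and divergence follow their definitions", {
  expect_equal(tr_ss(0.1, 100, 10), 1)
  expect_equal(tr_ss(log(2) / 22, 2200 / log(2), 10), 10)
  expect_equal(tr_ss(0.1, 100, 20), 0.5) # doubling <M> halves TR_ss

  expect_equal(tr_diff(1, 1), 0)
  expect_equal(tr_diff(2, 1), 1)
  expect_equal(tr_diff(1, 2), 1)
  expect_equal(tr_diff(1.05, 1), 0.05)
  # symmetry and scale invariance on random pairs
  set.seed(3)
  a <- runif(50, 0.1, 10); b <- runif(50, 0.1, 10); c <- runif(1, 0.1, 100)
  expect_equal(tr_diff(a, b), tr_diff(b, a))
  expect_equal(tr_diff(c * a, c * b), tr_diff(a, b))
  expect_error(tr_diff(-1, 1), "positive")
  expect_error(tr_ss(0.1, 0, 10), "positive")
})

test_that("translational activity descriptors are the stated products", {
  expect_equal(translational_activity(2, 0.5, 10, variant = "TA1"), 10)
  expect_equal(translational_activity(2, 0.5, 10, cai = 0.3, variant = "TA2"), 3)
  expect_equal(translational_activity(2, 0, 10, variant = "TA1"), 0)
  expect_equal(translational_activity(2, 0, 10, cai = 0.9, variant = "TA2"), 0)
  expect_error(translational_activity(2, 1.5, 10), "\\[0, 1\\]")
  expect_error(translational_activity(2, 0.5, 10, variant = "TA2"), "cai")
})

test_that("correlation report gives exact values on degenerate inputs and a calibrated null", {
  d <- tibble::tibble(x = 1:10, y = 1:10)
  rep1 <- rate_correlation_report(d, "x", "y")
  expect_equal(rep1$estimate, c(1, 1))

  d2 <- tibble::tibble(x = 1:10, y = 10:1)
  expect_equal(rate_correlation_report(d2, "x", "y")$estimate[2], -1)

  # independent pairs: small coefficients, roughly uniform p-values
  set.seed(9)
  d3 <- tibble::tibble(x = rnorm(1000), y = rnorm(1000))
  rep3 <- rate_correlation_report(d3, "x", "y")
  expect_true(all(abs(rep3$estimate) < 0.1))

  # missing values dropped with a message; too few pairs errors
  d4 <- tibble::tibble(x = c(1, 2, NA, 4, 5), y = c(2, NA, 3, 8, 9))
  expect_message(rate_correlation_report(d4, "x", "y"), "dropping 2")
  expect_error(rate_correlation_report(d4[1:4, ], "x", "y"), "at least 3")
})

test_that("exact permutation p-value matches full enumeration", {
  # R-side oracle: enumerate all n! permutations recursively
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  set.seed(12)
  x <- rnorm(5); y <- rnorm(5)
  obs <- abs(cor(x, y))
  pv_oracle <- mean(vapply(perms(y), function(p) abs(cor(x, p)) >= obs - 1e-12,
                           logical(1)))
  rep <- rate_correlation_report(tibble::tibble(x = x, y = y), "x", "y",
                                 exact = TRUE)
  expect_equal(rep$p_value[1], pv_oracle)
  expect_true(all(rep$p_value > 0 & rep$p_value <= 1))
  expect_error(rate_correlation_report(tibble::tibble(x = rnorm(11), y = rnorm(11)),
                                       "x", "y", exact = TRUE), "n <= 10")
})
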