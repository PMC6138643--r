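test_that("simulation is reproducible and encodes flat genes as zero ratios", {
  genes <- synthetic_genes(5, seed = 10)
  s1 <- simulate_expression(genes, seed = 11)
  s2 <- simulate_expression(genes, seed = 11)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$halflives, s2$halflives)

  flat <- dplyr::mutate(synthetic_genes(2, seed = 1), amplitude = 0)
  s3 <- simulate_expression(flat, log2_noise_sd = 0, seed = 2)
  expect_equal(s3$expression$log2_ratio, rep(0, nrow(s3$expression)))
})

test_that("noise-free expression decodes back to the generating mRNA profile", {
  genes <- synthetic_genes(4, seed = 20)
  sim <- simulate_expression(genes, log2_noise_sd = 0, seed = 21)
  conc <- log2_to_concentration(sim$expression, sim$averages)
  truth <- purrr::pmap(genes, function(gene, m0, amplitude, period, phase, ...) {
    tibble::tibble(gene = gene,
                   m = mrna_profile(seq(0, 55, 5), m0, amplitude, period, phase))
  }) |> purrr::list_rbind()
  expect_equal(conc$mrna, truth$m, tolerance = 1e-10)
})

test_that("observed half-lives emulate rate-space noise including sign flips", {
  genes <- synthetic_genes(500, halflife_range = c(100, 500), seed = 30)
  sim <- simulate_expression(genes, seed = 31)
  obs <- sim$halflives$observed_halflife
  # long-lived proteins + rate noise produce some negative observations
  expect_gt(sum(obs < 0), 0)
  # the implied rate error is Gaussian with the stated scale
  resid <- log(2) / obs - log(2) / sim$halflives$true_halflife
  expect_lt(abs(mean(resid)), 3 * (log(2) / 300) / sqrt(500))
  expect_lt(abs(sd(resid) / (log(2) / 300) - 1), 0.15)
})

test_that("the analytic oracle obeys its limiting forms", {
  kd <- log(2) / 22
  # zero amplitude: steady state k_trans * m0 / k_d
  expect_equal(analytic_periodic_protein(c(0, 13, 60), 10, 0, 2 * pi / 60, 0, 3, kd),
               rep(3 * 10 / kd, 3))
  # quasi-static limit: oscillation amplitude approaches k_trans * A / k_d
  amp <- function(w) {
    t <- seq(0, 2 * pi / w, length.out = 400)
    p <- analytic_periodic_protein(t, 10, 5, w, 0, 1, kd)
    (max(p) - min(p)) / 2
  }
  expect_equal(amp(1e-5), 5 / kd, tolerance = 1e-3)
})

test_that("measured-protein noise is bounded, unit-mean and seeded", {
  p <- analytic_periodic_protein(seq(0, 55, 5), 10, 5, 2 * pi / 60, 0, 2,
                                 log(2) / 22)
  clean <- simulate_measured_protein(seq(0, 55, 5), p, factor = 1, seed = 1)
  expect_equal(clean$intensity_au, p / mean(p))
  noisy <- simulate_measured_protein(seq(0, 55, 5), p, factor = 2, seed = 2)
  ratio <- (noisy$intensity_au * mean(p)) / p # up to a common rescale
  ratio <- ratio / exp(mean(log(ratio)))
  expect_true(all(ratio > 1 / 4 & ratio < 4))
  expect_identical(noisy,
                   simulate_measured_protein(seq(0, 55, 5), p, factor = 2, seed = 2))
})

test_that("temporal mRNA-protein correlation increases for short-lived proteins", {
  # fast-degrading proteins track their mRNA; long-lived ones are buffered
  set.seed(51)
  genes <- synthetic_genes(60, halflife_range = c(1, 300), seed = 51)
  prof_cor <- purrr::pmap_dbl(genes, function(m0, amplitude, period, phase,
                                              halflife, k_trans, ...) {
    t <- seq(0, period, by = 1)
    m <- mrna_profile(t, m0, amplitude, period, phase)
    p <- analytic_periodic_protein(t, m0, amplitude, 2 * pi / period, phase,
                                   k_trans, log(2) / halflife)
    cor(m, p, method = "spearman")
  })
  expect_gt(cor(prof_cor, 1 / genes$halflife, method = "spearman"), 0)
})
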