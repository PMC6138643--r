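# shared fixtures, all generated in code

# sinusoidal mRNA on the closed minute grid 0..period
sin_grid <- function(period = 60, dt = 1, m0 = 10, A = 5, phase = 0) {
  t <- seq(0, period, by = dt)
  list(t = t, m = m0 + A * sin(2 * pi * t / period + phase))
}

# write a wide expression TSV (gene column + minute columns)
write_expr_tsv <- function(mat_rows, times, path = tempfile(fileext = ".tsv")) {
  hdr <- paste(c("gene", times), collapse = "\t")
  rows <- vapply(names(mat_rows), function(g) {
    paste(c(g, mat_rows[[g]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# brute-force truncated-normal mean oracle by dense quadrature
truncnorm_mean_quad <- function(mu, sigma) {
  f <- function(x) x * dnorm(x, mu, sigma)
  g <- function(x) dnorm(x, mu, sigma)
  upper <- max(mu + 12 * sigma, 12 * sigma)
  num <- stats::integrate(f, 0, upper, rel.tol = 1e-12, abs.tol = 0)$value
  den <- stats::integrate(g, 0, upper, rel.tol = 1e-12, abs.tol = 0)$value
  num / den
}

# minutes (grid points 0..period-1) where the step function takes its
# shorter half-life; empty when the two levels coincide
short_halflife_minutes <- function(s) {
  hl <- halflife_at(seq(0, s$period - 1), s)
  if (s$theta1 == s$theta2) return(integer(0))
  which(hl == min(hl)) - 1L
}

# uneven sampling times with gaps drawn uniformly in [gap_min, gap_max]
uneven_times <- function(span, gap_min = 5, gap_max = 10) {
  ts <- 0
  while (max(ts) < span) ts <- c(ts, max(ts) + runif(1, gap_min, gap_max))
  ts[ts <= span]
}
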