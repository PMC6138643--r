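# internal helpers

# trapezoidal quadrature over possibly uneven abscissae
.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n])) / 2
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  .assert(length(miss) == 0,
          sprintf("%s must have column(s): %s", what, paste(miss, collapse = ", ")))
}

# number of whole dt steps in period; errors unless dt divides the period
.n_steps <- function(period, dt) {
  n <- period / dt
  .assert(abs(n - round(n)) < 1e-8, "`dt` must divide the period exactly")
  as.integer(round(n))
}
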