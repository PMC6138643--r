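# Translation-rate comparison: the steady-state estimate TR_ss = k_d <P>/<M>
# versus the time-course estimate TR_tc (the k_trans returned by the periodic
# solver), and their normalized divergence TR_diff.

#' Steady-state translation rate
#'
#' Under the steady-state assumption \eqn{dP/dt = 0}, the translation rate is
#' \eqn{TR_{ss} = k_d \langle P \rangle / \langle M \rangle}.
#'
#' @param k_d Degradation rate (1/min), positive (vectorized).
#' @param mean_protein,mean_mrna Average protein / mRNA concentrations
#'   (molecules/cell), positive.
#' @return Translation rate in proteins per mRNA per minute.
#' @export
tr_ss <- function(k_d, mean_protein, mean_mrna) {
  .assert(all(k_d > 0) && all(mean_protein > 0) && all(mean_mrna > 0),
          "k_d, mean_protein and mean_mrna must all be strictly positive")
  k_d * mean_protein / mean_mrna
}

#' Relative divergence between two translation-rate estimates
#'
#' \eqn{TR_{diff} = |TR_{ss} - TR_{tc}| / \min(TR_{ss}, TR_{tc})}: zero iff
#' the two estimates agree, symmetric in its arguments, invariant to a common
#' scale factor.
#'
#' @param tr_ss,tr_tc Translation rates (proteins/mRNA/min), positive
#'   (vectorized).
#' @return Dimensionless non-negative divergence.
#' @export
tr_diff <- function(tr_ss, tr_tc) {
  .assert(all(tr_ss > 0) && all(tr_tc > 0),
          "translation rates must be strictly positive")
  abs(tr_ss - tr_tc) / pmin(tr_ss, tr_tc)
}

#' Translational-activity descriptors
#'
#' Composite descriptors proposed as proxies for the translation rate:
#' `TA1 = density * occupancy * mrna` and `TA2 = TA1 * cai`.
#'
#' @param density Ribosome density (ribosomes per 100 nt), non-negative.
#' @param occupancy Ribosome occupancy, a fraction in `[0, 1]`.
#' @param mrna mRNA concentration (molecules/cell), non-negative.
#' @param cai Codon adaptation index (dimensionless), required for `"TA2"`.
#' @param variant `"TA1"` or `"TA2"`.
#' @return The descriptor value (vectorized).
#' @export
translational_activity <- function(density, occupancy, mrna, cai = NULL,
                                   variant = c("TA1", "TA2")) {
  variant <- match.arg(variant)
  .assert(all(occupancy >= 0 & occupancy <= 1), "occupancy must lie in [0, 1]")
  .assert(all(density >= 0) && all(mrna >= 0),
          "density and mrna must be non-negative")
  ta <- density * occupancy * mrna
  if (variant == "TA2") {
    .assert(!is.null(cai), "TA2 requires `cai`")
    .assert(all(cai >= 0), "cai must be non-negative")
    ta <- ta * cai
  }
  ta
}

#' Package per-gene translation rates from a proteome prediction
#'
#' Extracts the steady-state and time-course translation rates computed by
#' [predict_proteome()] and flags genes whose estimates diverge by more than
#' `threshold` (default 0.1).
#'
#' @param prediction A `proteome_prediction` from [predict_proteome()].
#' @param threshold Divergence cut-off on `tr_diff` for the `divergent` flag.
#' @return Tibble with columns `gene`, `tr_ss`, `tr_tc`, `tr_diff`,
#'   `divergent`.
#' @export
translation_rates <- function(prediction, threshold = 0.1) {
  .assert(inherits(prediction, "proteome_prediction"),
          "`prediction` must come from predict_proteome()")
  prediction$genes |>
    dplyr::transmute(.data$gene, .data$tr_ss, .data$tr_tc, .data$tr_diff,
                     divergent = .data$tr_diff > threshold)
}

#' Correlation report for paired per-gene quantities
#'
#' Pearson and Spearman correlations (with p-values) between two columns of
#' a per-gene table, after dropping incomplete pairs.  P-values use the
#' t approximation (Pearson) and the large-sample normal approximation
#' (Spearman); with `exact = TRUE` and at most 10 complete pairs, a
#' two-sided exact permutation p-value over all n! orderings is computed
#' instead.
#'
#' @param data A data frame; each row is one gene/pair.
#' @param x,y Names (strings) of the two numeric columns to correlate.
#' @param exact Use the exact permutation null (only for n <= 10).
#' @return Tibble with columns `method`, `estimate`, `p_value`, `n`.
#' @export
rate_correlation_report <- function(data, x, y, exact = FALSE) {
  .check_cols(data, c(x, y), "data")
  xs <- data[[x]]; ys <- data[[y]]
  keep <- is.finite(xs) & is.finite(ys)
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(sprintf("dropping %d incomplete pair(s)", dropped))
  }
  xs <- xs[keep]; ys <- ys[keep]
  n <- length(xs)
  .assert(n >= 3, "need at least 3 complete pairs")
  if (exact) {
    .assert(n <= 10, "exact permutation p-values only for n <= 10")
    rp <- cor(xs, ys)
    rs <- cor(xs, ys, method = "spearman")
    pp <- cpp_perm_pvalue(xs, ys)
    ps <- cpp_perm_pvalue(rank(xs), rank(ys))
    return(tibble::tibble(method = c("pearson", "spearman"),
                          estimate = c(rp, rs), p_value = c(pp, ps), n = n))
  }
  ct_p <- cor.test(xs, ys, method = "pearson")
  ct_s <- suppressWarnings(cor.test(xs, ys, method = "spearman", exact = FALSE))
  tibble::tibble(method = c("pearson", "spearman"),
                 estimate = c(unname(ct_p$estimate), unname(ct_s$estimate)),
                 p_value = c(ct_p$p.value, ct_s$p.value),
                 n = n)
}
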