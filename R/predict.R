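#' Predict protein abundance time-courses for a gene cohort
#'
#' End-to-end driver: intersects the three input tables, converts log2 ratios
#' to mRNA concentration grids, corrects half-lives, solves the periodic
#' kinetic model per gene, derives translation rates, and packages
#' per-gene diagnostics.  Genes that cannot be processed are recorded with a
#' reason, never silently dropped: every input gene appears either in the
#' result or in `skipped`.
#'
#' @param expression Long tibble `gene`, `time`, `log2_ratio` (as from
#'   [read_expression_tsv()]).
#' @param averages Tibble `gene`, `mean_mrna`, `mean_protein` (molecules/cell).
#' @param halflives Tibble `gene`, `observed_halflife` (minutes), or with a
#'   precomputed `corrected_halflife` column (then used as-is).
#' @param period Period T in minutes, or `"auto"` to estimate the consensus
#'   period from the expression data via [consensus_period()].
#' @param dt Integration step in minutes (default 1; must divide `period`).
#' @param tol Fixed-point convergence tolerance on \eqn{|R(T)-R(0)|}
#'   (default 5e-10).
#' @param method `"fixed_point"` (default) or `"closed_form"` (one-pass exact
#'   fixed point; use for very long half-lives).
#' @param max_sweeps Sweep budget for the fixed-point iteration.
#' @param max_reliable Error scale for half-life correction (minutes).
#' @param tr_threshold Divergence cut-off for the `divergent` flag.
#' @param periods Candidate period grid for `period = "auto"`.
#' @param truncate Drop expression measurements beyond the period explicitly
#'   (see [interpolate_minute_grid()]).
#' @return An object of class `proteome_prediction`: `timecourse` (tibble
#'   `gene`, `time`, `mrna`, `protein`), `genes` (per-gene parameters and
#'   diagnostics), `skipped` (tibble `gene`, `reason`), `period`, `dt`,
#'   `tol`.  Supports [tidy()], [glance()], [autoplot()].
#' @export
predict_proteome <- function(expression, averages, halflives,
                             period = "auto", dt = 1, tol = 5e-10,
                             method = c("fixed_point", "closed_form"),
                             max_sweeps = 1e6, max_reliable = 300,
                             tr_threshold = 0.1, periods = 30:150,
                             truncate = FALSE) {
  method <- match.arg(method)
  .check_cols(expression, c("gene", "time", "log2_ratio"), "expression")
  .check_cols(averages, c("gene", "mean_mrna", "mean_protein"), "averages")
  .check_cols(halflives, "gene", "halflives")

  if (identical(period, "auto")) {
    period <- consensus_period(expression, periods = periods)$best_period
    message(sprintf("consensus period: %g min", period))
  }
  .assert(is.numeric(period) && period > 0, "period must be positive")
  .n_steps(period, dt)

  if (!"corrected_halflife" %in% names(halflives)) {
    .check_cols(halflives, "observed_halflife", "halflives")
    halflives <- correct_halflives(halflives, max_reliable = max_reliable)
  }
  if (!"k_d" %in% names(halflives)) {
    halflives$k_d <- degradation_rate(halflives$corrected_halflife)
  }

  genes_in <- unique(expression$gene)
  skipped <- tibble::tibble(gene = character(), reason = character())
  note <- function(g, why) {
    tibble::tibble(gene = g, reason = rep(why, length(g)))
  }
  miss_avg <- setdiff(genes_in, averages$gene)
  miss_hl <- setdiff(setdiff(genes_in, miss_avg), halflives$gene)
  skipped <- dplyr::bind_rows(skipped,
                              note(miss_avg, "no average concentrations"),
                              note(miss_hl, "no half-life"))
  usable <- setdiff(genes_in, skipped$gene)
  .assert(length(usable) > 0, "empty gene intersection across the input tables")

  expr <- dplyr::filter(expression, .data$gene %in% usable)
  conc <- log2_to_concentration(expr, averages)
  grid <- interpolate_minute_grid(conc, period = period, dt = dt,
                                  truncate = truncate)
  avg <- dplyr::filter(averages, .data$gene %in% usable)
  hl <- dplyr::filter(halflives, .data$gene %in% usable)

  params <- dplyr::inner_join(avg, hl, by = "gene")
  solve_one <- function(m, k_d) {
    if (method == "closed_form") closed_form_R(m, k_d, dt)
    else solve_periodic_R(m, k_d, dt = dt, tol = tol, max_sweeps = max_sweeps)
  }

  rows <- list(); tcs <- list(); fails <- list()
  for (g in usable) {
    gi <- params[params$gene == g, ]
    m <- grid$mrna[grid$gene == g]
    res <- tryCatch({
      r <- solve_one(m, gi$k_d)
      k_trans <- compute_k_trans(gi$mean_protein, r)
      trss <- tr_ss(gi$k_d, gi$mean_protein, gi$mean_mrna)
      list(
        row = tibble::tibble(
          gene = g, halflife = gi$corrected_halflife, k_d = gi$k_d,
          k_trans = k_trans, tr_ss = trss, tr_tc = k_trans,
          tr_diff = tr_diff(trss, k_trans),
          mean_mrna = gi$mean_mrna, mean_protein = gi$mean_protein,
          grid_mean_mrna = mean(m[-length(m)]),
          iterations = r$iterations, residual = r$residual),
        tc = tibble::tibble(gene = g, time = r$time, mrna = m,
                            protein = k_trans * r$values))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails[[g]] <- note(g, paste("solver failed:", res))
    } else {
      rows[[g]] <- res$row; tcs[[g]] <- res$tc
    }
  }
  skipped <- dplyr::bind_rows(skipped, purrr::list_rbind(fails))
  .assert(length(rows) > 0, "no gene could be solved")
  genes_tbl <- purrr::list_rbind(rows) |>
    dplyr::mutate(divergent = .data$tr_diff > tr_threshold)

  structure(list(timecourse = purrr::list_rbind(tcs), genes = genes_tbl,
                 skipped = skipped, period = period, dt = dt, tol = tol,
                 method = method, tr_threshold = tr_threshold),
            class = "proteome_prediction")
}

#' @export
print.proteome_prediction <- function(x, ...) {
  cat("Proteome dynamics prediction\n")
  cat(sprintf("  period: %g min   dt: %g min   solver: %s (tol %.1g)\n",
              x$period, x$dt, x$method, x$tol))
  cat(sprintf("  genes predicted: %d   skipped: %d\n",
              nrow(x$genes), nrow(x$skipped)))
  cat(sprintf("  divergent translation rates (tr_diff > %.3g): %d\n",
              x$tr_threshold, sum(x$genes$divergent)))
  invisible(x)
}

#' @method tidy proteome_prediction
#' @export
tidy.proteome_prediction <- function(x, ...) x$timecourse

#' @method glance proteome_prediction
#' @export
glance.proteome_prediction <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$genes), n_skipped = nrow(x$skipped),
                 period = x$period, dt = x$dt,
                 median_tr_diff = median(x$genes$tr_diff),
                 n_divergent = sum(x$genes$divergent),
                 max_residual = max(x$genes$residual))
}

#' @param object A `proteome_prediction`.
#' @param genes Genes to plot (default: up to 9).
#' @param ... Unused.
#' @rdname predict_proteome
#' @method autoplot proteome_prediction
#' @export
autoplot.proteome_prediction <- function(object, genes = NULL, ...) {
  sel <- genes %||% head(object$genes$gene, 9)
  df <- object$timecourse |>
    dplyr::filter(.data$gene %in% sel) |>
    tidyr::pivot_longer(c("mrna", "protein"), names_to = "species",
                        values_to = "value") |>
    dplyr::group_by(.data$gene, .data$species) |>
    dplyr::mutate(value = .data$value / mean(.data$value)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "time [min]", y = "relative concentration (unit mean)") +
    ggplot2::theme_minimal()
}
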