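#' Run the full prediction pipeline on input files
#'
#' File-level orchestrator: reads the three input tables, runs
#' [predict_proteome()], and writes a run directory with the predicted
#' time-courses, per-gene rates and diagnostics, the skipped-gene table, and
#' a machine-readable manifest.  Outputs are deterministic for identical
#' inputs and configuration.
#'
#' @param expression_file TSV of log2 expression ratios (first column `gene`,
#'   remaining headers minutes).
#' @param averages_file TSV with `gene`, `mean_mrna`, `mean_protein`.
#' @param halflife_file TSV with `gene`, `observed_halflife_min`.
#' @param out_dir Output directory (created if needed).
#' @inheritParams predict_proteome
#' @param quiet Suppress progress messages.
#' @return The `proteome_prediction`, invisibly.  Side effects: writes
#'   `predictions.tsv` (`gene`, `t_min`, `protein_molecules_per_cell`),
#'   `rates.tsv`, `genes.tsv` (full per-gene diagnostics), `skipped.tsv`,
#'   and `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(expression_file, averages_file, halflife_file,
                         out_dir, period = "auto", dt = 1, tol = 5e-10,
                         method = "fixed_point", max_reliable = 300,
                         tr_threshold = 0.1, periods = 30:150,
                         truncate = TRUE, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else message
  expression <- read_expression_tsv(expression_file)
  averages <- read_averages_tsv(averages_file)
  halflives <- read_halflife_tsv(halflife_file)
  say(sprintf("read %d genes (expression), %d (averages), %d (half-lives)",
              length(unique(expression$gene)), nrow(averages), nrow(halflives)))

  pred <- predict_proteome(expression, averages, halflives, period = period,
                           dt = dt, tol = tol, method = method,
                           max_reliable = max_reliable,
                           tr_threshold = tr_threshold, periods = periods,
                           truncate = truncate)
  # genes dropped at read time (too few measurements) count as skipped too
  skipped <- dplyr::bind_rows(attr(expression, "skipped"), pred$skipped)
  say(sprintf("predicted %d genes, skipped %d", nrow(pred$genes), nrow(skipped)))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(
    dplyr::transmute(pred$timecourse, .data$gene, t_min = .data$time,
                     protein_molecules_per_cell = .data$protein),
    file.path(out_dir, "predictions.tsv"))
  readr::write_tsv(
    dplyr::transmute(pred$genes, .data$gene, .data$tr_ss, .data$tr_tc,
                     .data$tr_diff, .data$divergent),
    file.path(out_dir, "rates.tsv"))
  readr::write_tsv(pred$genes, file.path(out_dir, "genes.tsv"))
  readr::write_tsv(skipped, file.path(out_dir, "skipped.tsv"))

  manifest <- list(
    package = "protodyn",
    version = as.character(utils::packageVersion("protodyn")),
    config = list(expression_file = expression_file,
                  averages_file = averages_file,
                  halflife_file = halflife_file,
                  period = pred$period, dt = dt, tol = tol, method = method,
                  max_reliable = max_reliable, tr_threshold = tr_threshold,
                  truncate = truncate),
    n_genes_in = length(unique(expression$gene)) + nrow(attr(expression, "skipped")),
    n_predicted = nrow(pred$genes),
    n_skipped = nrow(skipped),
    n_divergent = sum(pred$genes$divergent),
    max_residual = max(pred$genes$residual),
    max_iterations = max(pred$genes$iterations))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(pred)
}
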