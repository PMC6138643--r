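#' Read a gene-expression time-course table
#'
#' Reads a tab-delimited expression matrix whose first column is `gene` and
#' whose remaining column headers are time points in minutes; cell values are
#' log2 expression ratios.  Empty cells mark missing measurements and are
#' dropped from that gene's series.  Genes left with fewer than two valid
#' points are skipped (reported via a message and recorded in the `"skipped"`
#' attribute of the result).
#'
#' @param path Path to the TSV file.
#' @return A tibble in long form with columns `gene`, `time` (minutes) and
#'   `log2_ratio`, ordered by gene then time.  The attribute `"skipped"` holds
#'   a tibble of skipped genes with reasons.
#' @export
read_expression_tsv <- function(path) {
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  .assert(length(hdr) >= 3, "expression table needs a gene column and at least 2 time columns")
  .assert(identical(hdr[1], "gene"),
          sprintf("malformed header: first column must be 'gene', got '%s'", hdr[1]))
  times <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(times)) {
    bad <- hdr[-1][is.na(times)]
    stop(sprintf("malformed header: non-numeric time column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  .assert(!anyDuplicated(times), "malformed header: duplicate time columns")
  .assert(all(times >= 0), "malformed header: negative time points")

  raw <- readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                         col_types = readr::cols(gene = readr::col_character(),
                                                 .default = readr::col_double()),
                         name_repair = "minimal")
  names(raw) <- c("gene", as.character(times))
  dup <- duplicated(raw$gene)
  if (any(dup)) {
    ids <- unique(raw$gene[dup])
    lines <- which(raw$gene %in% ids) + 1L # +1 for the header line
    stop(sprintf("duplicate gene id(s) %s at line(s) %s",
                 paste(ids, collapse = ", "), paste(lines, collapse = ", ")),
         call. = FALSE)
  }

  long <- tidyr::pivot_longer(raw, -"gene", names_to = "time",
                              values_to = "log2_ratio") |>
    dplyr::mutate(time = as.numeric(.data$time)) |>
    dplyr::filter(!is.na(.data$log2_ratio)) |>
    dplyr::arrange(.data$gene, .data$time)

  counts <- dplyr::count(long, .data$gene)
  short <- counts$gene[counts$n < 2]
  skipped <- tibble::tibble(gene = short,
                            reason = rep("fewer than 2 valid measurements",
                                         length(short)))
  no_data <- setdiff(raw$gene, counts$gene)
  if (length(no_data) > 0) {
    skipped <- dplyr::bind_rows(
      skipped, tibble::tibble(gene = no_data, reason = "no valid measurements"))
  }
  if (nrow(skipped) > 0) {
    message(sprintf("skipped %d gene(s) with fewer than 2 valid measurements: %s",
                    nrow(skipped), paste(skipped$gene, collapse = ", ")))
    long <- dplyr::filter(long, !(.data$gene %in% skipped$gene))
  }
  attr(long, "skipped") <- skipped
  long
}

#' Read a table of per-gene average mRNA and protein concentrations
#'
#' @param path Path to a TSV with columns `gene`, `mean_mrna`, `mean_protein`
#'   (both in molecules per cell, both strictly positive).
#' @return A tibble with those columns.
#' @export
read_averages_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(gene = readr::col_character(),
                                                .default = readr::col_double()))
  .check_cols(df, c("gene", "mean_mrna", "mean_protein"), "averages table")
  .assert(!anyDuplicated(df$gene), "duplicate gene ids in averages table")
  .assert(all(df$mean_mrna > 0 & df$mean_protein > 0, na.rm = TRUE),
          "mean_mrna and mean_protein must be strictly positive")
  tibble::as_tibble(df[c("gene", "mean_mrna", "mean_protein")])
}

#' Read a table of observed protein half-lives
#'
#' Observed half-lives may be negative or very large: they are raw estimates
#' from decay-rate measurements and are corrected downstream by
#' [correct_halflives()].
#'
#' @param path Path to a TSV with columns `gene` and `observed_halflife_min`
#'   (or `observed_halflife`), in minutes.
#' @return A tibble with columns `gene`, `observed_halflife`.
#' @export
read_halflife_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(gene = readr::col_character(),
                                                .default = readr::col_double()))
  if ("observed_halflife_min" %in% names(df) && !"observed_halflife" %in% names(df)) {
    df$observed_halflife <- df$observed_halflife_min
  }
  .check_cols(df, c("gene", "observed_halflife"), "half-life table")
  .assert(!anyDuplicated(df$gene), "duplicate gene ids in half-life table")
  tibble::as_tibble(df[c("gene", "observed_halflife")])
}

#' Convert log2 expression ratios to mRNA concentrations
#'
#' Rescales each gene's measured log2 ratios \eqn{L_i(t)} to absolute mRNA
#' concentrations using its literature cell-cycle average \eqn{\langle M_i
#' \rangle} (molecules/cell):
#' \deqn{M_i(t) = 2^{L_i(t)} \cdot \langle M_i \rangle / \langle 2^{L_i} \rangle,}
#' where \eqn{\langle 2^{L_i} \rangle} is the arithmetic mean of
#' \eqn{2^{L_i(t)}} over that gene's measured points.  By construction the
#' arithmetic mean of the output over the measured points equals
#' `mean_mrna` exactly.
#'
#' @param expression Long tibble with columns `gene`, `time`, `log2_ratio`
#'   (as from [read_expression_tsv()]).
#' @param averages Tibble with columns `gene`, `mean_mrna` (molecules/cell).
#' @return Tibble with columns `gene`, `time`, `mrna` (molecules/cell).
#' @export
log2_to_concentration <- function(expression, averages) {
  .check_cols(expression, c("gene", "time", "log2_ratio"), "expression")
  .check_cols(averages, c("gene", "mean_mrna"), "averages")
  .assert(all(is.finite(expression$log2_ratio)),
          "non-finite log2 ratio encountered; drop or fix before converting")
  .assert(all(averages$mean_mrna > 0), "mean_mrna must be strictly positive")
  miss <- setdiff(unique(expression$gene), averages$gene)
  .assert(length(miss) == 0,
          sprintf("no average mRNA concentration for gene(s): %s",
                  paste(head(miss, 5), collapse = ", ")))
  expression |>
    dplyr::inner_join(averages[c("gene", "mean_mrna")], by = "gene") |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(mrna = 2^.data$log2_ratio * .data$mean_mrna /
                    mean(2^.data$log2_ratio)) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "time", "mrna")
}

# Piecewise-linear interpolation of one periodic series onto the closed grid
# 0..period step dt.  Measurements need not reach either end of [0, period]:
# the series is treated as periodic, so the segments before the first and
# after the last measured point interpolate against the wrapped neighbours
# (t_last - T, v_last) and (t_first + T, v_first).  Consequently the value at
# t = 0 equals the value at t = T exactly.
.wrap_interpolate <- function(times, values, period, dt) {
  n_steps <- .n_steps(period, dt)
  o <- order(times)
  times <- times[o]; values <- values[o]
  .assert(length(unique(times)) >= 2, "need at least 2 distinct time points")
  .assert(min(diff(times)) >= dt - 1e-9,
          "`dt` must not exceed the smallest sampling interval")
  xt <- times; xv <- values
  if (times[1] > 0) {
    xt <- c(times[length(times)] - period, xt)
    xv <- c(values[length(values)], xv)
  }
  if (times[length(times)] < period) {
    xt <- c(xt, times[1] + period)
    xv <- c(xv, values[1])
  }
  grid <- seq(0, period, by = dt)
  approx(xt, xv, xout = grid, method = "linear", ties = "ordered")$y
}

#' Interpolate concentration series onto a minute-resolution periodic grid
#'
#' Linearly interpolates each gene's measured concentrations onto the closed
#' uniform grid \eqn{t = 0, dt, \ldots, T}.  The series is treated as
#' periodic with period `period`: beyond the last (and before the first)
#' measured time, interpolation wraps around to the first (last) measured
#' value shifted by one period, so the grid value at \eqn{T} equals the value
#' at 0.  Measured points that fall on the grid are reproduced exactly.
#'
#' @param concentration Tibble with columns `gene`, `time`, `mrna`
#'   (as from [log2_to_concentration()]).
#' @param period Period T in minutes.  Must be a multiple of `dt` and at
#'   least the largest measured time (unless `truncate = TRUE`).
#' @param dt Grid step in minutes (default 1).  Must not exceed the smallest
#'   sampling interval.
#' @param truncate If `TRUE`, measurements beyond `period` are explicitly
#'   dropped (with a message) before interpolation; if `FALSE` (default) such
#'   measurements are an error, so truncation is never silent.
#' @return Tibble with columns `gene`, `time`, `mrna` on the grid; each gene
#'   contributes `period/dt + 1` rows.
#' @export
interpolate_minute_grid <- function(concentration, period, dt = 1,
                                    truncate = FALSE) {
  .check_cols(concentration, c("gene", "time", "mrna"), "concentration")
  .assert(period > 0 && dt > 0, "period and dt must be positive")
  .n_steps(period, dt)
  beyond <- concentration$time > period + 1e-9
  if (any(beyond)) {
    if (!truncate) {
      stop(sprintf(paste0("measurements beyond the period (max time %.6g > T = %.6g); ",
                          "use truncate = TRUE to drop them explicitly"),
                   max(concentration$time), period), call. = FALSE)
    }
    message(sprintf("truncating %d measurement(s) beyond t = %.6g min",
                    sum(beyond), period))
    concentration <- concentration[!beyond, ]
  }
  concentration |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(~ tibble::tibble(
      time = seq(0, period, by = dt),
      mrna = .wrap_interpolate(.x$time, .x$mrna, period, dt))) |>
    dplyr::ungroup()
}
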