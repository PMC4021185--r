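#' Column means and medians of a metric table
#'
#' The summary row of a per-method metric table: the plain mean and median
#' of each numeric metric column over the listed methods.
#'
#' @param metrics tibble with a `method` column and numeric metric columns.
#' @param exclude methods to leave out of the summary (e.g. a baseline).
#' @return tibble: metric, mean, median.
#' @export
summarise_metrics <- function(metrics, exclude = NULL) {
  m <- metrics[!(metrics$method %in% exclude), , drop = FALSE]
  cols <- names(m)[vapply(m, is.numeric, logical(1))]
  purrr::map(cols, function(col) {
    tibble::tibble(metric = col, mean = mean(m[[col]]), median = median(m[[col]]))
  }) |> purrr::list_rbind()
}

#' Baseline comparison of per-method metrics
#'
#' For each non-baseline method and metric, the absolute improvement of the
#' baseline over that method (`delta` = baseline - method) and the relative
#' improvement in percent (`pct_delta` = 100 * delta / method value).
#'
#' @param metrics tibble with a `method` column and numeric metric columns.
#' @param baseline name of the baseline method (e.g. the new predictor).
#' @return a `radt_comparison` tibble: metric, method, value, delta,
#'   pct_delta.
#' @export
compare_to_baseline <- function(metrics, baseline) {
  if (!baseline %in% metrics$method) {
    abort(sprintf("baseline '%s' absent from the metric table", baseline))
  }
  cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  base <- metrics[metrics$method == baseline, , drop = FALSE]
  rest <- metrics[metrics$method != baseline, , drop = FALSE]
  out <- purrr::map(cols, function(col) {
    tibble::tibble(metric = col, method = rest$method, value = rest[[col]],
                   delta = base[[col]] - rest[[col]],
                   pct_delta = 100 * (base[[col]] - rest[[col]]) / rest[[col]])
  }) |> purrr::list_rbind()
  attr(out, "baseline") <- baseline
  class(out) <- c("radt_comparison", class(out))
  out
}

#' Summary columns of a baseline comparison
#'
#' Per metric: the mean and median of the competing methods' values and of
#' the baseline's absolute improvements, the relative improvement of the
#' average (100 x mean delta / mean competitor value - the ratio of means,
#' which is how an "average % improvement" over a panel of competitors is
#' conventionally quoted), and the median of the per-method percentage
#' improvements.
#'
#' @param comparison a [compare_to_baseline()] result.
#' @return tibble: metric, mean_value, median_value, mean_delta,
#'   median_delta, avg_pct_delta, median_pct_delta.
#' @export
summarise_comparison <- function(comparison) {
  comparison |>
    dplyr::group_by(metric = .data$metric) |>
    dplyr::summarise(
      mean_value = mean(.data$value),
      median_value = median(.data$value),
      mean_delta = mean(.data$delta),
      median_delta = median(.data$delta),
      avg_pct_delta = 100 * mean(.data$delta) / mean(.data$value),
      median_pct_delta = median(.data$pct_delta),
      .groups = "drop"
    )
}
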