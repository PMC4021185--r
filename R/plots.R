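# ggplot2 views of the result objects.

#' @export
autoplot.radt_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("tpr", "tnr"),
                              names_to = "rate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fraction, y = .data$value,
                                     colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "crossing"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "positive fraction in training set", y = "rate",
                  colour = NULL,
                  title = "Class-distribution sweep",
                  subtitle = sprintf("TPr/TNr crossing at %.2f",
                                     attr(object, "crossing"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.radt_removal <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$step, y = .data$mean_mcc_after)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "removal step", y = "mean MCC of remaining proteins",
                  title = "Iterative removal of worst-scoring proteins") +
    ggplot2::theme_minimal()
  tracked <- attr(object, "tracked")
  if (!is.null(tracked) && nrow(tracked) > 0) {
    p <- p + ggplot2::geom_line(
      data = tracked,
      ggplot2::aes(x = .data$step, y = .data$mcc, group = .data$protein_id),
      colour = "grey70", linewidth = 0.3)
  }
  p
}

#' @export
autoplot.radt_lopo <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$protein_id, .data$mcc),
                                   y = .data$mcc)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_mcc"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-protein MCC",
                  title = "Leave-one-protein-out cross-validation",
                  subtitle = sprintf("mean MCC %.3f", attr(object, "mean_mcc"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.radt_ga <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation, y = .data$elite_mean)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generation", y = "elite mean MCC",
                  title = "Genetic feature-subset search") +
    ggplot2::theme_minimal()
}
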