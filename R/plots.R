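# Learning-curve and metric plots.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline labs
#'   theme_minimal autoplot facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Learning curves of a single active-learning run
#'
#' @param object A `som_al_run`.
#' @param metrics Metric columns to draw (default MCC and positive label
#'   ratio).
#' @param ... Unused.
#' @return A ggplot: metric vs fraction of the active-learning set used.
#' @export
autoplot.som_al_run <- function(object, metrics = c("val_mcc", "positive_label_ratio"),
                                ...) {
  h <- object$history
  long <- tidyr::pivot_longer(h[, c("frac_data", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long <- filter(long, !is.na(.data$value))
  ggplot(long, aes(x = .data$frac_data, y = .data$value, colour = .data$metric)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "fraction of active-learning set used", y = NULL,
         title = sprintf("%s sampling, batch %d", object$config$strategy,
                         object$config$batch_size)) +
    theme_minimal()
}

#' Mean learning curves of an AL experiment
#'
#' Draws the metric against the fraction of the pool used, one curve per
#' strategy, averaged over folds and seeds.
#'
#' @param experiment Result of [run_al_experiment()].
#' @param metric Metric column (default `"val_mcc"`).
#' @return A ggplot.
#' @export
plot_learning_curves <- function(experiment, metric = "val_mcc") {
  curves <- al_learning_curves(experiment)
  agg <- curves |>
    group_by(.data$strategy, .data$frac_data) |>
    summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot(agg, aes(x = .data$frac_data, y = .data$value, colour = .data$strategy)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "fraction of active-learning set used", y = metric) +
    theme_minimal()
}
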