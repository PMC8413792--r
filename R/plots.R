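#' Heatmap of a connection matrix
#'
#' @param cm A `connection_matrix`.
#' @return A ggplot object.
#' @export
plot_connection_matrix <- function(cm) {
  n <- nrow(cm$r)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$r <- as.vector(cm$r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "channel", y = "channel", fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.connection_matrix <- function(object, ...) {
  plot_connection_matrix(object)
}

#' Task-state profile of a global network metric
#'
#' Mean and standard deviation of a metric across subjects, by task state and
#' sleep state (the layout of the study's global-connectivity figures).
#'
#' @param metrics Long metrics tibble from [run_pipeline()].
#' @param scheme Thresholding scheme to show.
#' @param metric Metric name (`"D"`, `"WD"`, `"C"`, `"E"`).
#' @param parameter Optional threshold parameter to filter on.
#' @return A ggplot object.
#' @export
plot_metric_profile <- function(metrics, scheme = "surrogate", metric = "D",
                                parameter = NULL) {
  df <- metrics[metrics$scheme == scheme & metrics$metric == metric, ]
  if (!is.null(parameter)) df <- df[df$parameter == parameter, ]
  summ <- df |>
    dplyr::group_by(.data$sleep_state, .data$task_state) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$task_state, y = .data$mean,
                                     colour = .data$sleep_state,
                                     group = .data$sleep_state)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "task state", y = paste(scheme, metric),
                  colour = "sleep state") +
    ggplot2::theme_minimal()
}

#' Channel-wise contrast map
#'
#' t-statistics of the task-minus-rest (or sleep-deprivation) contrast per
#' channel, marking channels significant before FDR correction.
#'
#' @param map Output of [channelwise_contrast_map()].
#' @param alpha Significance threshold for the uncorrected marking.
#' @return A ggplot object.
#' @export
plot_contrast_map <- function(map, alpha = 0.05) {
  map$significant <- map$p < alpha
  ggplot2::ggplot(map, ggplot2::aes(x = factor(.data$channel),
                                    y = .data$statistic,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "channel", y = "t statistic",
                  fill = paste0("p < ", alpha, " (uncorrected)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6, angle = 90))
}
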