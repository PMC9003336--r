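#' Plot a sweep result
#'
#' Mean accuracy against the swept variable, one curve per method, with the
#' 95% interval ribbon where replication produced one.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- tidy(object)
  lab <- c(horizon = "classification horizon (ms)",
           n_sensors = "number of sensors",
           n_dropped = "number of dropped sensors")
  xlab <- lab[[attr(object, "variable")]] %||% attr(object, "variable")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$accuracy,
                                        colour = .data$method,
                                        fill = .data$method))
  if (any(is.finite(df$lower))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                               ymax = .data$upper),
                                  alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = xlab, y = "classification accuracy",
                  colour = "method", fill = "method") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a sensor confusion matrix
#'
#' @param object A `sensor_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sensor_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$probability)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Plot the MM/NMM accuracy ratio of a sweep
#'
#' @param x A `sweep_result` containing both methods.
#' @return A ggplot object.
#' @export
plot_accuracy_ratio <- function(x) {
  r <- attr(x, "ratio") %||% accuracy_ratio(x)
  ggplot2::ggplot(r$by_value, ggplot2::aes(x = .data$value,
                                           y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = attr(x, "variable"), y = "accuracy ratio MM / NMM") +
    ggplot2::theme_minimal()
}
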