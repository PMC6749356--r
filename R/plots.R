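#' Plot a confusion-matrix heatmap
#'
#' @param object a `har_eval` from [evaluate_classifier()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.har_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("accuracy %.2f%%", 100 * object$accuracy)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the compression-degree sweep
#'
#' Median test error per compression degree with the 0.25-0.75 quartile
#' band over the repetitions.
#'
#' @param object a `har_sweep` from [zeta_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.har_sweep <- function(object, ...) {
  s <- tidy(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$zeta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25_test_error,
                                      ymax = .data$q75_test_error),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_test_error),
                       color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_test_error)) +
    ggplot2::labs(x = "compression degree (retained fraction)",
                  y = "test error",
                  title = "error vs. training-set compression") +
    ggplot2::theme_minimal()
}

#' Plot recording channels over time
#'
#' @param rec a recording or extended recording.
#' @param channels channel names to draw.
#' @param from,to optional time window in seconds.
#' @return A ggplot object with one facet per channel, shaded by label.
#' @export
plot_recording <- function(rec, channels = c("ax", "ay", "az"),
                           from = NULL, to = NULL) {
  df <- as_tibble(rec)
  if (!is.null(from)) df <- df[df$t >= from, ]
  if (!is.null(to)) df <- df[df$t <= to, ]
  long <- tidyr::pivot_longer(df[c("t", "label", channels)],
                              dplyr::all_of(channels),
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = channels)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     color = .data$label)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, color = "activity") +
    ggplot2::theme_minimal()
}
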