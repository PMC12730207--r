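# ggplot2 display methods for filterbanks and evaluation results.

#' Plot gammatone filterbank magnitude responses
#'
#' @param object a `gammatone_fb` from [gammatone_bank()].
#' @param db show magnitudes in dB.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gammatone_fb <- function(object, db = TRUE, ...) {
  resp <- bank_response(object)
  if (db) resp$magnitude <- 20 * log10(pmax(resp$magnitude, 1e-6))
  ggplot2::ggplot(resp, ggplot2::aes(.data$freq, .data$magnitude,
                                     group = .data$filter,
                                     colour = factor(.data$filter))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = if (db) c(-60, 5) else NULL) +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = if (db) "Magnitude (dB)" else "Magnitude",
                  title = sprintf("Gammatone filterbank (N = %d, ERB-spaced)", object$N))
}

#' @rdname autoplot.gammatone_fb
#' @export
autoplot.triangular_fb <- function(object, ...) {
  resp <- bank_response(object)
  ggplot2::ggplot(resp, ggplot2::aes(.data$freq, .data$magnitude,
                                     group = .data$filter,
                                     colour = factor(.data$filter))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Weight",
                  title = sprintf("Triangular filterbank (N = %d, mel-spaced)", object$N))
}

#' Confusion-matrix heatmap for an evaluation report
#'
#' @param object an `eval_report` from [compute_metrics()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "prediction", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$prediction, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  title = sprintf("Accuracy %.1f%%", 100 * object$accuracy)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Metric curves for a protocol report
#'
#' Accuracy and macro metrics against frame-group size (frame modes), with
#' the frame- and vocalization-level points at the ends.
#'
#' @param object a `protocol_report` from [run_protocol()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.protocol_report <- function(object, ...) {
  df <- object$repeats |>
    tidyr::pivot_longer(c("accuracy", "macro_precision", "macro_recall", "macro_f1"),
                        names_to = "metric", values_to = "value")
  if (any(df$granularity == "group")) {
    df <- df[df$granularity == "group", ]
    ggplot2::ggplot(df, ggplot2::aes(.data$group_size, 100 * .data$value,
                                     colour = .data$metric)) +
      ggplot2::stat_summary(fun = mean, geom = "line") +
      ggplot2::stat_summary(fun = mean, geom = "point") +
      ggplot2::labs(x = "Frames per voting group", y = "Metric (%)",
                    title = sprintf("Mode %s: effect of group voting", object$mode))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(factor(.data$`repeat`), 100 * .data$value,
                                     fill = .data$metric)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "Repeat", y = "Metric (%)",
                    title = sprintf("Mode %s: per-repeat metrics", object$mode))
  }
}
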