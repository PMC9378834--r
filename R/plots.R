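#' Plot the panel-size selection curve
#'
#' Evaluation index sqrt(PPV x NPV) against odd panel size n, with the
#' selected size highlighted.
#'
#' @param object An `ssc_selection` from [select_classifier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ssc_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$eval_index)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = df$n) +
    ggplot2::labs(x = "panel size n (odd)",
                  y = expression(sqrt(PPV %*% NPV)),
                  title = sprintf("Panel selection: n = %d chosen",
                                  object$chosen_n)) +
    ggplot2::theme_minimal()
}

#' Plot vote-fraction scores by class
#'
#' Histogram of the per-sample vote fraction (reversed votes / usable
#' panel), optionally split by truth label; the 0.5 majority threshold is
#' marked.
#'
#' @param predictions Tibble from [classify_matrix()].
#' @param truth Optional tibble with `sample_id`, `label`.
#' @return A ggplot object.
#' @export
plot_vote_scores <- function(predictions, truth = NULL) {
  df <- predictions
  if (!is.null(truth)) {
    df$class <- truth$label[match(df$sample_id, truth$sample_id)]
  } else {
    df$class <- df$label
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = 1 / max(df$n_usable),
                            position = "identity", alpha = 0.6,
                            boundary = 0) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "fraction of panel pairs voting reversed",
                  y = "samples", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of reversal screening
#'
#' Case reversal rate against -log10 BH q-value for every tested stable
#' pair, with the candidate-selection thresholds drawn.
#'
#' @param stats A `pair_stats` tibble with `q_value` and `reversal_rate`.
#' @param q_threshold,reversal_threshold Thresholds to draw (defaults 0.05
#'   and 0.70).
#' @return A ggplot object.
#' @export
plot_reversal <- function(stats, q_threshold = 0.05,
                          reversal_threshold = 0.70) {
  df <- as_tibble(stats)
  df$selected <- df$q_value < q_threshold &
    !is.na(df$reversal_rate) & df$reversal_rate >= reversal_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reversal_rate,
                                   y = -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = reversal_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(q_threshold),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "case reversal rate m2 / (m1 + m2)",
                  y = expression(-log[10] ~ q)) +
    ggplot2::theme_minimal()
}
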