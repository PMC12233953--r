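#' Plot block-switch-aligned accuracy
#'
#' @param acc Output of [block_switch_aligned_accuracy()] (optionally
#'   row-bound across agents with a `label` column).
#' @return A ggplot.
#' @export
plot_block_switch_accuracy <- function(acc) {
  p <- ggplot2::ggplot(acc, ggplot2::aes(x = .data$offset,
                                         y = .data$p_correct))
  if ("label" %in% names(acc)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$label))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "trials from block switch", y = "P(correct choice)") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Plot stay probability by two-outcome history
#'
#' @param stay Output of [stay_probability_by_2history()].
#' @return A ggplot.
#' @export
plot_stay_by_history <- function(stay) {
  stay$history <- factor(stay$history, levels = c("RR", "UR", "RU", "UU"))
  ggplot2::ggplot(stay, ggplot2::aes(x = .data$history, y = .data$p_stay)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "outcome history (t-2, t-1, same port)",
                  y = "P(stay)") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' Plot switch probability by three-trial outcome history
#'
#' @param sw Output of [switch_probability_by_history()].
#' @param min_n Hide codes observed fewer than `min_n` times.
#' @return A ggplot.
#' @export
plot_switch_by_history <- function(sw, min_n = 10L) {
  sw <- sw[sw$n >= min_n, ]
  sw <- sw[order(sw$p_switch), ]
  sw$hist3 <- factor(sw$hist3, levels = sw$hist3)
  ggplot2::ggplot(sw, ggplot2::aes(x = .data$hist3, y = .data$p_switch)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "outcome history (t-3, t-2, t-1)", y = "P(switch)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of a model-identification confusion matrix
#'
#' @param object A `bb_confusion` from [identification_study()].
#' @param ... Unused.
#' @return A ggplot tile map of P(best-fit model | generating model).
#' @export
autoplot.bb_confusion <- function(object, ...) {
  d <- tidy(object)
  d$gen_model <- factor(d$gen_model, levels = rev(rownames(object$matrix)))
  d$fit_model <- factor(d$fit_model, levels = colnames(object$matrix))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fit_model, y = .data$gen_model,
                                  fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "best-fitting model", y = "generating model",
                  fill = "P")
}

#' Truth-vs-estimate scatter of a parameter-recovery study
#'
#' @param object A `bb_recovery` from [parameter_recovery()].
#' @param ... Unused.
#' @return A ggplot, one facet per parameter, outliers marked.
#' @export
autoplot.bb_recovery <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$truth, y = .data$estimate,
                               colour = .data$outlier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(title = object$model, x = "true parameter",
                  y = "estimate")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
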