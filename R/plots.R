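# ggplot2 visualizations for result objects.

#' Plot an ROC curve
#'
#' @param object A `pp_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pp_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

cost_plot <- function(trace, title) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$epoch, y = .data$cost)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Epoch", y = "Mean cost", title = title) +
    ggplot2::theme_minimal()
}

#' Plot a training cost curve
#'
#' @param object A fitted `fpn_detector` or `mafvit_alstm`.
#' @param ... Unused.
#' @export
autoplot.fpn_detector <- function(object, ...) {
  cost_plot(object$cost, "Detector training cost")
}

#' @rdname autoplot.fpn_detector
#' @export
autoplot.mafvit_alstm <- function(object, ...) {
  cost_plot(object$cost, "Classifier training cost")
}

#' Plot an optimizer convergence trace
#'
#' @param object A `pp_optim` from [eigbo_optimize()].
#' @param ... Unused.
#' @export
autoplot.pp_optim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace[, c("iteration", "best", "mean")],
                              c("best", "mean"), names_to = "series",
                              values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(best = "#2166ac",
                                            mean = "#b2182b")) +
    ggplot2::labs(x = "Iteration", y = "Fitness (1/accuracy + 1/IoU)",
                  title = sprintf("%s convergence", object$variant)) +
    ggplot2::theme_minimal()
}

#' Plot a multiclass confusion matrix
#'
#' @param m Matrix from [multiclass_confusion()].
#' @return A ggplot tile map.
#' @export
plot_confusion <- function(m) {
  df <- as.data.frame(as.table(m))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(x = "Predicted class", y = "True class") +
    ggplot2::theme_minimal()
}
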