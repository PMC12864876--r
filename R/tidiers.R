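# broom-style tidiers for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for pestpyramid objects
#'
#' `tidy()` returns the per-epoch (or per-iteration) trace of a fitted
#' object; `glance()` a one-row summary.
#'
#' @param x A fitted `fpn_detector`, `mafvit_alstm`, `pp_optim` or a
#'   `pp_run_report`.
#' @param ... Unused.
#' @name pestpyramid-tidiers
NULL

#' @rdname pestpyramid-tidiers
#' @export
tidy.fpn_detector <- function(x, ...) x$cost

#' @rdname pestpyramid-tidiers
#' @export
glance.fpn_detector <- function(x, ...) {
  tibble::tibble(hidden_width = x$config$hidden_width,
                 learning_rate = x$config$learning_rate,
                 epochs = nrow(x$cost),
                 initial_cost = x$cost$cost[1],
                 final_cost = x$cost$cost[nrow(x$cost)])
}

#' @rdname pestpyramid-tidiers
#' @export
tidy.mafvit_alstm <- function(x, ...) x$cost

#' @rdname pestpyramid-tidiers
#' @export
glance.mafvit_alstm <- function(x, ...) {
  tibble::tibble(hidden_width = x$config$hidden_width,
                 learning_rate = x$config$learning_rate,
                 n_classes = x$config$n_classes,
                 epochs = nrow(x$cost),
                 initial_cost = x$cost$cost[1],
                 final_cost = x$cost$cost[nrow(x$cost)])
}

#' @rdname pestpyramid-tidiers
#' @export
tidy.pp_optim <- function(x, ...) x$trace

#' @rdname pestpyramid-tidiers
#' @export
glance.pp_optim <- function(x, ...) {
  tibble::tibble(variant = x$variant, population = x$population,
                 iterations = x$iterations, best_fitness = x$best$fitness,
                 !!!as.list(x$best$genes))
}

#' @rdname pestpyramid-tidiers
#' @export
tidy.pp_run_report <- function(x, ...) {
  det <- tidyr::pivot_longer(x$detection$report, dplyr::everything(),
                             names_to = "metric", values_to = "value")
  det$stage <- "detection"
  cls <- tidyr::pivot_longer(x$classification$macro, dplyr::everything(),
                             names_to = "metric", values_to = "value")
  cls$stage <- "classification"
  extra <- tibble::tibble(
    stage = c("detection", "classification", "classification"),
    metric = c("mean_matched_iou", "overall_accuracy", "macro_auc"),
    value = c(x$detection$mean_iou, x$classification$accuracy, x$macro_auc))
  dplyr::bind_rows(det[, c("stage", "metric", "value")],
                   cls[, c("stage", "metric", "value")], extra)
}

#' @rdname pestpyramid-tidiers
#' @export
glance.pp_run_report <- function(x, ...) {
  tibble::tibble(det_sensitivity = x$detection$sensitivity,
                 mean_matched_iou = x$detection$mean_iou,
                 macro_accuracy = x$classification$accuracy,
                 macro_auc = x$macro_auc,
                 n_crops_evaluated = x$classification$n_evaluated)
}
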