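# Detection/classification metric suite: confusion-count ratios (accuracy,
# count-IoU/CSI, sensitivity, precision, FNR, NPV, MCC, bookmaker
# informedness), geometric box IoU with greedy detection matching,
# multiclass confusion matrices with one-vs-rest reduction, ROC/AUC, and
# k-fold index partitions.

#' Confusion counts
#'
#' The TP/TN/FP/FN quadruple from which every scalar metric derives.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return A `confusion_counts` object.
#' @export
#' @examples
#' accuracy(confusion_counts(50, 40, 5, 5))  # 0.9
confusion_counts <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  structure(list(tp = as.numeric(tp), tn = as.numeric(tn),
                 fp = as.numeric(fp), fn = as.numeric(fn)),
            class = "confusion_counts")
}

undefined_metric <- function(name) {
  stop(structure(class = c("pp_undefined_metric", "error", "condition"),
                 list(message = paste0(name, " is undefined: zero denominator"),
                      call = NULL)))
}

#' @rdname confusion_counts
#' @param c A [confusion_counts()] object.
#' @export
accuracy <- function(c) {
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot <= 0) undefined_metric("accuracy")
  (c$tp + c$tn) / tot
}

#' Count-based intersection over union (identical to the critical success
#' index)
#' @param c A [confusion_counts()] object.
#' @export
iou_counts <- function(c) {
  den <- c$tp + c$fp + c$fn
  if (den <= 0) undefined_metric("iou")
  c$tp / den
}

#' @rdname iou_counts
#' @export
csi <- function(c) {
  den <- c$tp + c$fn + c$fp
  if (den <= 0) undefined_metric("csi")
  c$tp / den
}

#' Scalar confusion-count metrics
#'
#' `sensitivity()` (recall, TP/(TP+FN)), `precision()` (TP/(TP+FP)),
#' `fnr()` (FN/(TP+FN), the complement of sensitivity), `npv()`
#' (TN/(TN+FN)) and `specificity()` (TN/(TN+FP)).
#'
#' @param c A [confusion_counts()] object.
#' @return A real in `[0, 1]`; an error of class `pp_undefined_metric` when
#'   the denominator is zero.
#' @export
sensitivity <- function(c) {
  den <- c$tp + c$fn
  if (den <= 0) undefined_metric("sensitivity")
  c$tp / den
}

#' @rdname sensitivity
#' @export
precision <- function(c) {
  den <- c$tp + c$fp
  if (den <= 0) undefined_metric("precision")
  c$tp / den
}

#' @rdname sensitivity
#' @export
fnr <- function(c) {
  den <- c$tp + c$fn
  if (den <= 0) undefined_metric("fnr")
  c$fn / den
}

#' @rdname sensitivity
#' @export
npv <- function(c) {
  den <- c$tn + c$fn
  if (den <= 0) undefined_metric("npv")
  c$tn / den
}

#' @rdname sensitivity
#' @export
specificity <- function(c) {
  den <- c$tn + c$fp
  if (den <= 0) undefined_metric("specificity")
  c$tn / den
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; by the standard
#' convention the value is 0 whenever any factor of the radicand vanishes.
#'
#' @param c A [confusion_counts()] object.
#' @export
mcc <- function(c) {
  tot <- c$tp + c$tn + c$fp + c$fn
  if (tot <= 0) undefined_metric("mcc")
  f1 <- c$tp + c$fp; f2 <- c$tp + c$fn; f3 <- c$tn + c$fp; f4 <- c$tn + c$fn
  if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0) return(0)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(f1 * f2 * f3 * f4)
}

#' Bookmaker informedness
#'
#' Sensitivity plus specificity.  The literal reported form omits the
#' conventional `- 1` of standard informedness; set `subtract_one = TRUE`
#' for the standard definition (range `[-1, 1]`).
#'
#' @param c A [confusion_counts()] object.
#' @param subtract_one Use the standard informedness convention?
#' @export
bookmaker <- function(c, subtract_one = FALSE) {
  b <- sensitivity(c) + specificity(c)
  if (subtract_one) b - 1 else b
}

#' Full metric report for one confusion quadruple
#'
#' @param c A [confusion_counts()] object.
#' @param bm_subtract_one Passed to [bookmaker()].
#' @return A one-row tibble with accuracy, iou, sensitivity, precision, fnr,
#'   npv, csi, mcc, specificity and bm; metrics with a zero denominator are
#'   `NA`.
#' @export
metric_report <- function(c, bm_subtract_one = FALSE) {
  safe <- function(f, ...) tryCatch(f(c, ...), pp_undefined_metric = function(e) NA_real_)
  tibble::tibble(
    accuracy = safe(accuracy), iou = safe(iou_counts),
    sensitivity = safe(sensitivity), precision = safe(precision),
    fnr = safe(fnr), npv = safe(npv), csi = safe(csi), mcc = safe(mcc),
    specificity = safe(specificity),
    bm = tryCatch(bookmaker(c, bm_subtract_one),
                  pp_undefined_metric = function(e) NA_real_)
  )
}

#' Geometric IoU of two pixel boxes
#'
#' Boxes are `c(x_min, y_min, x_max, y_max)`, 0-based, half-open.
#' Degenerate (zero-area) boxes yield 0 with a warning.
#'
#' @param a,b Numeric boxes.
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
box_iou <- function(a, b) {
  area <- function(x) max(0, x[3] - x[1]) * max(0, x[4] - x[2])
  aa <- area(a); ab <- area(b)
  if (aa == 0 || ab == 0) {
    warning("degenerate zero-area box; IoU set to 0", call. = FALSE)
    return(0)
  }
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / (aa + ab - inter)
}

#' Match detections to ground truth boxes
#'
#' Greedy matching in descending score order: each ground-truth box may be
#' claimed at most once, a claimed pair counts as TP when its IoU reaches
#' the threshold, unmatched predictions are FP and unclaimed ground truths
#' FN.  TN is structurally zero for detection.
#'
#' @param pred Tibble/data frame with `x_min`, `y_min`, `x_max`, `y_max`,
#'   `score`.
#' @param gt Tibble/data frame with box corner columns.
#' @param iou_threshold IoU acceptance threshold in `(0, 1)`.
#' @return List with `counts` ([confusion_counts()]), `mean_iou` (mean IoU
#'   over matched pairs; `NA` if none) and `matches` (tibble of
#'   `pred_index`, `gt_index`, `iou`).
#' @export
match_detections <- function(pred, gt, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must lie in (0, 1)", call. = FALSE)
  np <- nrow(pred); ng <- nrow(gt)
  ord <- if (np) order(pred$score, decreasing = TRUE) else integer(0)
  gt_taken <- rep(FALSE, ng)
  matches <- list()
  tp <- 0L
  for (i in ord) {
    pb <- c(pred$x_min[i], pred$y_min[i], pred$x_max[i], pred$y_max[i])
    best <- 0; best_j <- 0L
    for (j in seq_len(ng)) {
      if (gt_taken[j]) next
      gb <- c(gt$x_min[j], gt$y_min[j], gt$x_max[j], gt$y_max[j])
      ov <- box_iou(pb, gb)
      if (ov > best) { best <- ov; best_j <- j }
    }
    if (best_j > 0L && best >= iou_threshold) {
      gt_taken[best_j] <- TRUE
      tp <- tp + 1L
      matches[[tp]] <- tibble::tibble(pred_index = i, gt_index = best_j,
                                      iou = best)
    }
  }
  matches <- if (tp) dplyr::bind_rows(matches) else
    tibble::tibble(pred_index = integer(0), gt_index = integer(0),
                   iou = numeric(0))
  list(counts = confusion_counts(tp, 0L, np - tp, ng - tp),
       mean_iou = if (tp) mean(matches$iou) else NA_real_,
       matches = matches)
}

#' Multiclass confusion matrix
#'
#' @param true_labels,pred_labels Integer labels in `[0, K)`.
#' @param K Number of classes.
#' @return A K x K integer matrix, rows = true class, columns = predicted.
#' @export
multiclass_confusion <- function(true_labels, pred_labels, K) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors must have equal length", call. = FALSE)
  if (any(true_labels < 0 | true_labels >= K | pred_labels < 0 |
          pred_labels >= K))
    stop("labels must lie in [0, K)", call. = FALSE)
  m <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (i in seq_along(true_labels)) {
    m[true_labels[i] + 1L, pred_labels[i] + 1L] <-
      m[true_labels[i] + 1L, pred_labels[i] + 1L] + 1L
  }
  m
}

#' One-vs-rest reduction of a multiclass confusion matrix
#'
#' @param m Matrix from [multiclass_confusion()].
#' @param k Class index in `[0, K)`.
#' @return [confusion_counts()] for class `k` against the rest.
#' @export
per_class_counts <- function(m, k) {
  i <- k + 1L
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  confusion_counts(tp, tn, fp, fn)
}

#' Macro-averaged metric report over all classes
#'
#' The macro report is the unweighted mean of the per-class one-vs-rest
#' reports (`NA` entries dropped); `micro` pools the per-class counts first.
#'
#' @param m Matrix from [multiclass_confusion()].
#' @param average `"macro"` or `"micro"`.
#' @param bm_subtract_one Passed to [bookmaker()].
#' @return A one-row tibble as in [metric_report()].
#' @export
macro_report <- function(m, average = c("macro", "micro"),
                         bm_subtract_one = FALSE) {
  average <- match.arg(average)
  K <- nrow(m)
  if (average == "micro") {
    cs <- lapply(seq_len(K) - 1L, per_class_counts, m = m)
    pooled <- confusion_counts(sum(vapply(cs, `[[`, 0, "tp")),
                               sum(vapply(cs, `[[`, 0, "tn")),
                               sum(vapply(cs, `[[`, 0, "fp")),
                               sum(vapply(cs, `[[`, 0, "fn")))
    return(metric_report(pooled, bm_subtract_one))
  }
  reports <- dplyr::bind_rows(lapply(seq_len(K) - 1L, function(k)
    metric_report(per_class_counts(m, k), bm_subtract_one)))
  dplyr::summarise(reports, dplyr::across(dplyr::everything(),
                                          ~ mean(.x, na.rm = TRUE)))
}

#' ROC curve and trapezoidal AUC
#'
#' Thresholds are the unique scores in descending order (tied scores form a
#' single step); the curve runs from (0, 0) to (1, 1) and the AUC is the
#' trapezoidal area, equal to the normalized Mann-Whitney U statistic.
#'
#' @param scores Real prediction scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical).
#' @return A `pp_roc`: list with `curve` (tibble `threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("roc_curve requires both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  steps <- which(diff(s) != 0)
  cuts <- c(steps, length(s))  # last index of each tied score group
  tpr <- c(0, cumsum(y)[cuts] / np)
  fpr <- c(0, cumsum(1 - y)[cuts] / nn)
  thr <- c(Inf, s[cuts])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc), class = "pp_roc")
}

#' Seed-deterministic k-fold partition
#'
#' @param n Number of items.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Shuffle seed.
#' @return List of `k` disjoint 1-based index vectors partitioning
#'   `1..n`, sizes differing by at most one.
#' @export
kfold_indices <- function(n, k, seed = 1L) {
  if (k < 2L || k > n) stop("need 2 <= k <= n", call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n))
  # assign shuffled items round-robin so fold sizes differ by at most one
  fold <- integer(n)
  fold[idx] <- rep(seq_len(k), length.out = n)
  split(seq_len(n), fold)
}
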