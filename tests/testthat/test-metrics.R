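test_that("confusion-count metrics match direct arithmetic on worked examples", {
  c1 <- confusion_counts(50, 40, 5, 5)
  expect_equal(accuracy(c1), 0.9)
  expect_equal(iou_counts(c1), 50 / 60)
  expect_equal(sensitivity(c1), 50 / 55)
  expect_equal(precision(c1), 50 / 55)
  expect_equal(npv(c1), 40 / 45)
  expect_equal(csi(c1), 50 / 60)
  expect_equal(mcc(c1), (50 * 40 - 25) / sqrt(55 * 55 * 45 * 45))
  expect_equal(bookmaker(c1), 50 / 55 + 40 / 45)
  expect_equal(bookmaker(c1, subtract_one = TRUE), 50 / 55 + 40 / 45 - 1)

  perfect <- confusion_counts(1, 1, 0, 0)
  expect_equal(accuracy(perfect), 1)
  expect_equal(mcc(perfect), 1)
  expect_equal(bookmaker(perfect), 2)
  expect_equal(bookmaker(perfect, subtract_one = TRUE), 1)
  expect_equal(accuracy(confusion_counts(0, 0, 1, 1)), 0)
  expect_equal(mcc(confusion_counts(1, 1, 1, 1)), 0)
})

test_that("undefined denominators raise a typed error carrying the metric name", {
  zero <- confusion_counts(0, 0, 0, 0)
  expect_error(accuracy(zero), class = "pp_undefined_metric")
  expect_error(sensitivity(confusion_counts(0, 5, 3, 0)),
               class = "pp_undefined_metric")
  expect_error(npv(confusion_counts(3, 0, 1, 0)), "npv")
  rep <- metric_report(zero)
  expect_true(all(is.na(rep)))
})

test_that("box IoU matches a pixel-counting oracle and is symmetric", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_warning(v <- box_iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "degenerate")
  expect_equal(v, 0)

  # oracle: enumerate integer pixels on the half-open grid
  pix <- function(b) {
    if (b[3] <= b[1] || b[4] <= b[2]) return(character(0))
    g <- expand.grid(x = b[1]:(b[3] - 1), y = b[2]:(b[4] - 1))
    paste(g$x, g$y)
  }
  set.seed(1)
  for (rep in 1:25) {
    a <- { x <- sort(sample(0:8, 2)); y <- sort(sample(0:8, 2))
           c(x[1], y[1], x[2] + 1, y[2] + 1) }
    b <- { x <- sort(sample(0:8, 2)); y <- sort(sample(0:8, 2))
           c(x[1], y[1], x[2] + 1, y[2] + 1) }
    pa <- pix(a); pb <- pix(b)
    oracle <- length(intersect(pa, pb)) / length(union(pa, pb))
    expect_equal(box_iou(a, b), oracle)
    expect_equal(box_iou(a, b), box_iou(b, a))
  }
})

test_that("greedy detection matching follows the score order and threshold", {
  gt <- tibble::tibble(x_min = c(0, 10), y_min = c(0, 10),
                       x_max = c(4, 14), y_max = c(4, 14))
  pred <- dplyr::mutate(gt, score = c(1, 0.9))
  m <- match_detections(pred, gt, 0.5)
  expect_equal(m$counts$tp, 2)
  expect_equal(m$counts$fp, 0)
  expect_equal(m$counts$fn, 0)
  expect_equal(m$counts$tn, 0)
  expect_equal(m$mean_iou, 1)

  empty <- pred[0, ]
  m2 <- match_detections(empty, gt, 0.5)
  expect_equal(m2$counts$fn, 2)

  # one prediction at IoU 1/3 below the 0.5 threshold
  p3 <- tibble::tibble(x_min = 1, y_min = 0, x_max = 3, y_max = 2, score = 1)
  g3 <- tibble::tibble(x_min = 0, y_min = 0, x_max = 2, y_max = 2)
  m3 <- match_detections(p3, g3, 0.5)
  expect_equal(c(m3$counts$tp, m3$counts$fp, m3$counts$fn), c(0, 1, 1))
})

test_that("multiclass confusion reduces to valid per-class counts", {
  expect_equal(diag(multiclass_confusion(c(0, 1, 2), c(0, 1, 2), 3)),
               c(`0` = 1L, `1` = 1L, `2` = 1L), ignore_attr = TRUE)
  set.seed(4)
  truth <- sample(0:2, 30, replace = TRUE)
  pred <- sample(0:2, 30, replace = TRUE)
  m <- multiclass_confusion(truth, pred, 3)
  expect_equal(sum(m), 30)
  for (k in 0:2) {
    cc <- per_class_counts(m, k)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 30)
    # brute-force tally
    expect_equal(cc$tp, sum(truth == k & pred == k))
    expect_equal(cc$fn, sum(truth == k & pred != k))
    expect_equal(cc$fp, sum(truth != k & pred == k))
  }
  mac <- macro_report(m)
  expect_true(all(mac$accuracy >= 0 & mac$accuracy <= 1))
  expect_error(multiclass_confusion(c(0, 3), c(0, 1), 3), "labels")

  # binary case reduces to plain confusion counts
  t2 <- c(0, 0, 1, 1, 1); p2 <- c(0, 1, 1, 1, 0)
  m2 <- multiclass_confusion(t2, p2, 2)
  cc2 <- per_class_counts(m2, 1)
  expect_equal(c(cc2$tp, cc2$tn, cc2$fp, cc2$fn), c(2, 1, 1, 1))
})

test_that("ROC AUC equals the pairwise Mann-Whitney statistic and pROC agrees", {
  set.seed(8)
  for (rep in 1:5) {
    n <- 40
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + labels
    r <- roc_curve(scores, labels)
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
    proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                               quiet = TRUE)))
    expect_equal(r$auc, proc_auc, tolerance = 1e-9)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    # invariance under a strictly monotone transform
    expect_equal(roc_curve(exp(2 * scores), labels)$auc, r$auc)
  }
  sep <- roc_curve(c(3, 2, 1, 0), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(roc_curve(c(3, 2, 1, 0), c(0, 0, 1, 1))$auc, 0)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("k-fold indices partition the data with near-equal sizes", {
  f <- kfold_indices(10, 5, seed = 1)
  expect_equal(lengths(f), rep(2L, 5), ignore_attr = TRUE)
  f2 <- kfold_indices(10, 3, seed = 1)
  expect_setequal(as.integer(lengths(f2)), c(4L, 3L, 3L))
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(5:40, 1); k <- sample(2:min(6, n), 1)
    ff <- kfold_indices(n, k, seed = rep)
    expect_setequal(unlist(ff), seq_len(n))
    expect_equal(sum(lengths(ff)), n)
    expect_lte(diff(range(lengths(ff))), 1L)
  }
  expect_error(kfold_indices(3, 5), "k <= n")
  expect_identical(kfold_indices(20, 4, seed = 7), kfold_indices(20, 4, seed = 7))
})
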