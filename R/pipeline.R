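# End-to-end orchestration: generate (or read) scenes, train the detector,
# crop, train the classifier, evaluate, and emit the analysis artifacts
# (k-fold tables, cost traces, confusion matrices, per-class ROC).

#' Pipeline run configuration
#'
#' The default profile is the package's standard desk-scale study
#' condition: 64 x 64 scenes, 3 classes, 200 train / 50 test scenes.  The
#' global `seed` determines the synthetic data, both model initializations
#' and the optimizer stream.
#'
#' @param scene A [scene_config()] (its seed is overridden by `seed`).
#' @param n_total Total number of scenes.
#' @param train_fraction Train share of scenes.
#' @param detector A [detector_config()].
#' @param classifier A [classifier_config()].
#' @param optimizer Optional budget list for [tune_pipeline()], or `NULL`
#'   for no tuning.
#' @param out_dir Optional artifact directory.
#' @param seed Global seed.
#' @export
run_config <- function(scene = scene_config(), n_total = 250L,
                       train_fraction = 0.8, detector = detector_config(),
                       classifier = classifier_config(), optimizer = NULL,
                       out_dir = NULL, seed = 1L) {
  scene$seed <- as.integer(seed)
  detector$seed <- as.integer(seed + 1L)
  classifier$seed <- as.integer(seed + 2L)
  structure(list(scene = scene, n_total = as.integer(n_total),
                 train_fraction = train_fraction, detector = detector,
                 classifier = classifier, optimizer = optimizer,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

gt_crops <- function(scenes, pad = 0.1) {
  crops <- list(); labels <- integer(0)
  for (sc in scenes) {
    a <- sc$annotations
    for (r in seq_len(nrow(a))) {
      crops[[length(crops) + 1L]] <- crop_detection(
        sc$image, c(a$x_min[r], a$y_min[r], a$x_max[r], a$y_max[r]), pad)
      labels <- c(labels, a$class_id[r])
    }
  }
  list(crops = crops, labels = labels)
}

# detect / match / classify over test scenes; the core evaluation loop
evaluate_joint <- function(det, cls, test_scenes, iou_threshold = 0.5) {
  K <- cls$config$n_classes
  tp <- 0L; fp <- 0L; fn <- 0L
  ious <- numeric(0)
  truth <- integer(0); pred <- integer(0)
  scores <- matrix(numeric(0), ncol = K)
  det_rows <- list()
  for (si in seq_along(test_scenes)) {
    sc <- test_scenes[[si]]
    d <- detect(sc$image, det)
    m <- match_detections(d, sc$annotations, iou_threshold)
    tp <- tp + m$counts$tp; fp <- fp + m$counts$fp; fn <- fn + m$counts$fn
    ious <- c(ious, m$matches$iou)
    if (nrow(d)) det_rows[[length(det_rows) + 1L]] <-
      dplyr::mutate(d, scene = sc$index, .before = 1L)
    for (r in seq_len(nrow(m$matches))) {
      pr <- m$matches$pred_index[r]; gr <- m$matches$gt_index[r]
      crop <- crop_detection(sc$image, as.numeric(
        d[pr, c("x_min", "y_min", "x_max", "y_max")]))
      p <- classify(crop, cls)
      truth <- c(truth, sc$annotations$class_id[gr])
      pred <- c(pred, which.max(p) - 1L)
      scores <- rbind(scores, p)
    }
  }
  detection_counts <- confusion_counts(tp, 0L, fp, fn)
  confusion <- if (length(truth))
    multiclass_confusion(truth, pred, K) else matrix(0L, K, K)
  roc <- list(); aucs <- numeric(0)
  for (k in seq_len(K) - 1L) {
    lab <- truth == k
    if (length(truth) && any(lab) && any(!lab)) {
      r <- roc_curve(scores[, k + 1L], lab)
      roc[[paste0("class_", k)]] <- r
      aucs <- c(aucs, r$auc)
    }
  }
  list(
    detection = list(counts = detection_counts,
                     report = metric_report(detection_counts),
                     mean_iou = if (length(ious)) mean(ious) else NA_real_,
                     sensitivity = if (tp + fn > 0) tp / (tp + fn) else
                       NA_real_),
    classification = list(
      confusion = confusion,
      macro = macro_report(confusion),
      per_class = dplyr::bind_rows(lapply(seq_len(K) - 1L, function(k)
        dplyr::mutate(metric_report(per_class_counts(confusion, k)),
                      class_id = k, .before = 1L))),
      accuracy = if (length(truth)) mean(truth == pred) else NA_real_,
      n_evaluated = length(truth)),
    roc = roc,
    macro_auc = if (length(aucs)) mean(aucs) else NA_real_,
    detections = if (length(det_rows)) dplyr::bind_rows(det_rows) else
      tibble::tibble(scene = integer(0), x_min = numeric(0),
                     y_min = numeric(0), x_max = numeric(0),
                     y_max = numeric(0), score = numeric(0)),
    predictions = tibble::tibble(true_class = truth, pred_class = pred)
  )
}

joint_on_scenes <- function(train_scenes, test_scenes, config) {
  det <- stage("train_detector",
               train_detector(list(train = train_scenes), config$detector))
  tc <- stage("crops", gt_crops(train_scenes))
  cls_cfg <- config$classifier
  cls <- stage("train_classifier",
               train_classifier(tc$crops, tc$labels, cls_cfg))
  ev <- stage("evaluate", evaluate_joint(det, cls, test_scenes))
  ev$cost <- list(detector = det$cost, classifier = cls$cost)
  ev$models <- list(detector = det, classifier = cls)
  ev
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$detections, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(report$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$classification$confusion),
                   file.path(out_dir, "confusion_matrix.csv"))
  utils::write.csv(report$cost$detector,
                   file.path(out_dir, "cost_detector.csv"), row.names = FALSE)
  utils::write.csv(report$cost$classifier,
                   file.path(out_dir, "cost_classifier.csv"),
                   row.names = FALSE)
  for (nm in names(report$roc)) {
    utils::write.csv(report$roc[[nm]]$curve,
                     file.path(out_dir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    detection = c(as.list(report$detection$report),
                  mean_iou = report$detection$mean_iou),
    classification = c(as.list(report$classification$macro),
                       accuracy = report$classification$accuracy),
    macro_auc = report$macro_auc
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' Run the full joint detection + classification workflow
#'
#' Generates the synthetic split, trains the detector, trains the
#' classifier on ground-truth crops, then detects on every test scene,
#' matches detections to ground truth, classifies the matched crops and
#' assembles the evaluation report.  Unmatched (false-positive) detections
#' count only toward detection FP; they carry no class label.
#'
#' @param config A [run_config()].
#' @return A `pp_run_report`: detection counts/report/mean IoU,
#'   classification confusion matrix, macro and per-class reports,
#'   per-class ROC with macro AUC, cost traces, raw detection and
#'   prediction tables, and the trained models.
#' @export
run_joint <- function(config = run_config()) {
  split <- stage("generate_data",
                 generate_dataset(config$scene, config$n_total,
                                  config$train_fraction))
  report <- joint_on_scenes(split$train, split$test, config)
  if (!is.null(config$out_dir))
    stage("artifacts", write_report_artifacts(report, config$out_dir))
  structure(report, class = "pp_run_report")
}

#' K-fold evaluation of the joint pipeline
#'
#' Partitions all scenes into `k` seed-deterministic folds, trains on
#' `k - 1` folds and evaluates on the held-out fold.  A fold whose training
#' part misses a class is flagged and skipped rather than aborting the run.
#'
#' @param config A [run_config()].
#' @param k Number of folds.
#' @return List with `reports` (per-fold `pp_run_report`-like lists) and
#'   `summary` (tibble: fold, detection sensitivity and mean IoU,
#'   classification macro accuracy).
#' @export
run_kfold <- function(config = run_config(), k = 5L) {
  scenes <- lapply(seq_len(config$n_total) - 1L,
                   function(i) generate_scene(config$scene, i))
  folds <- kfold_indices(length(scenes), k, seed = config$seed)
  reports <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_scenes <- scenes[folds[[f]]]
    train_scenes <- scenes[-folds[[f]]]
    classes_present <- unique(unlist(lapply(train_scenes,
                                            function(s) s$annotations$class_id)))
    if (length(classes_present) < config$classifier$n_classes) {
      warning(sprintf("fold %d misses a class in training; skipped", f),
              call. = FALSE)
      rows[[f]] <- tibble::tibble(fold = f, flagged = TRUE,
                                  det_sensitivity = NA_real_,
                                  mean_iou = NA_real_,
                                  macro_accuracy = NA_real_)
      next
    }
    rep_f <- joint_on_scenes(train_scenes, test_scenes, config)
    reports[[f]] <- rep_f
    rows[[f]] <- tibble::tibble(
      fold = f, flagged = FALSE,
      det_sensitivity = rep_f$detection$sensitivity,
      mean_iou = rep_f$detection$mean_iou,
      macro_accuracy = rep_f$classification$accuracy)
  }
  list(reports = reports, summary = dplyr::bind_rows(rows))
}

#' Ablation study over classifier components
#'
#' Trains four classifier variants on identical ground-truth crops and
#' seed — plain LSTM (no attention), attention-only (mean-pooled tokens,
#' no LSTM), fused attention + LSTM without adaptive gating, and the full
#' model — and tabulates their accuracy on held-out ground-truth crops,
#' isolating the classification stage from detector noise.
#'
#' @param config A [run_config()].
#' @return Tibble with `variant` and `accuracy`.
#' @export
run_ablation <- function(config = run_config()) {
  split <- generate_dataset(config$scene, config$n_total,
                            config$train_fraction)
  tr <- gt_crops(split$train)
  te <- gt_crops(split$test)
  variants <- list(
    plain_lstm = list(use_attention = FALSE, use_lstm = TRUE,
                      adaptive = FALSE),
    attention_only = list(use_attention = TRUE, use_lstm = FALSE,
                          adaptive = FALSE),
    no_adaptive_gating = list(use_attention = TRUE, use_lstm = TRUE,
                              adaptive = FALSE),
    full = list(use_attention = TRUE, use_lstm = TRUE, adaptive = TRUE)
  )
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    cfg <- config$classifier
    cfg$use_attention <- v$use_attention
    cfg$use_lstm <- v$use_lstm
    cfg$adaptive <- v$adaptive
    acc <- tryCatch({
      m <- train_classifier(tr$crops, tr$labels, cfg)
      preds <- vapply(te$crops, function(cr) which.max(classify(cr, m)) - 1L,
                      0L)
      mean(preds == te$labels)
    }, error = function(e) NA_real_)
    tibble::tibble(variant = nm, accuracy = acc)
  })
  dplyr::bind_rows(rows)
}

#' Paired with/without-optimization comparison
#'
#' Runs the scaled-down pipeline once with the search-space midpoint genes
#' and once with EIGBO-RE-tuned genes on the same split and seed, and
#' reports the paired accuracy / IoU / objective values.
#'
#' @param config A [run_config()]; `config$optimizer` supplies the tuning
#'   budget (see [tune_pipeline()]).
#' @return List with `comparison` (two-row tibble), `tuned` (the
#'   `pp_optim`) and `genes` (default and tuned gene vectors).
#' @export
run_with_without_optimization <- function(config = run_config()) {
  budget <- config$optimizer %||% list()
  split <- generate_dataset(config$scene, config$n_total,
                            config$train_fraction)
  space <- default_search_space()
  midpoint <- (space$lower + space$upper) / 2
  midpoint <- ifelse(space$kind == "integer", floor(midpoint + 0.5), midpoint)
  b <- utils::modifyList(list(n_train = 24L, n_val = 8L, epochs_det = 2L,
                              epochs_cls = 2L), budget)
  tuned <- stage("tune", tune_pipeline(split, budget, seed = config$seed))
  eval_set <- function(genes) {
    n_tr <- min(b$n_train, length(split$train))
    det <- train_detector(list(train = split$train[seq_len(n_tr)]),
                          detector_config(hidden_width = genes[1],
                                          learning_rate = genes[2],
                                          epochs = b$epochs_det,
                                          seed = config$seed))
    tc <- gt_crops(split$train[seq_len(n_tr)])
    cls <- train_classifier(tc$crops, tc$labels,
                            classifier_config(hidden_width = genes[3],
                                              learning_rate = genes[4],
                                              epochs = b$epochs_cls,
                                              n_classes =
                                                config$classifier$n_classes,
                                              seed = config$seed))
    evaluate_genes(det, cls, split$test)
  }
  res_default <- stage("evaluate_default", eval_set(midpoint))
  res_tuned <- stage("evaluate_tuned", eval_set(tuned$best$genes))
  comparison <- tibble::tibble(
    setting = c("default_midpoint", "eigbo_re_tuned"),
    fpn_hidden = c(midpoint[1], tuned$best$genes[1]),
    fpn_lr = c(midpoint[2], tuned$best$genes[2]),
    lstm_hidden = c(midpoint[3], tuned$best$genes[3]),
    lstm_lr = c(midpoint[4], tuned$best$genes[4]),
    accuracy = c(res_default$accuracy, res_tuned$accuracy),
    iou = c(res_default$iou, res_tuned$iou),
    objective = c(res_default$objective, res_tuned$objective)
  )
  list(comparison = comparison, tuned = tuned,
       genes = list(default = midpoint, tuned = tuned$best$genes))
}

#' @export
print.pp_run_report <- function(x, ...) {
  cat("<pp_run_report>\n")
  cat(sprintf("  detection: sensitivity %.3f, mean matched IoU %.3f\n",
              x$detection$sensitivity, x$detection$mean_iou))
  cat(sprintf("  classification: accuracy %.3f over %d matched crops\n",
              x$classification$accuracy, x$classification$n_evaluated))
  if (is.finite(x$macro_auc))
    cat(sprintf("  macro one-vs-rest AUC: %.3f\n", x$macro_auc))
  invisible(x)
}
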