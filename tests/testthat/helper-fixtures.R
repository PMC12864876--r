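# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# small 32x32 scenes: fast to train on, still divisible by 32
tiny_scene_cfg <- function(seed = 11L) {
  scene_config(image_height = 32L, image_width = 32L, n_classes = 3L,
               pests_per_image = c(1L, 2L), pest_scale = c(8L, 12L),
               seed = seed)
}

tiny_split <- function() {
  if (is.null(.fixtures$tiny_split)) {
    .fixtures$tiny_split <- generate_dataset(tiny_scene_cfg(), 16L, 0.75)
  }
  .fixtures$tiny_split
}

tiny_crops <- function() {
  if (is.null(.fixtures$tiny_crops)) {
    split <- tiny_split()
    crops <- list(); labels <- integer(0)
    for (sc in c(split$train, split$test)) {
      a <- sc$annotations
      for (r in seq_len(nrow(a))) {
        crops[[length(crops) + 1L]] <- crop_detection(
          sc$image, c(a$x_min[r], a$y_min[r], a$x_max[r], a$y_max[r]))
        labels <- c(labels, a$class_id[r])
      }
    }
    .fixtures$tiny_crops <- list(crops = crops, labels = labels)
  }
  .fixtures$tiny_crops
}

# central-difference numeric gradient for tape checks
numeric_grad <- function(fn, x, eps = 1e-6) {
  g <- array(0, dim = dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

# independent plain-arithmetic metric oracle (NA where undefined)
oracle_metrics <- function(tp, tn, fp, fn) {
  tot <- tp + tn + fp + fn
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_o <- if (tot == 0) NA_real_ else {
    f <- c(tp + fp, tp + fn, tn + fp, tn + fn)
    if (any(f == 0)) 0 else (tp * tn - fp * fn) / sqrt(prod(f))
  }
  bm_o <- if (tp + fn > 0 && tn + fp > 0)
    tp / (tp + fn) + tn / (tn + fp) else NA_real_
  list(
    accuracy = sdiv(tp + tn, tot),
    iou = sdiv(tp, tp + fp + fn),
    sensitivity = sdiv(tp, tp + fn),
    precision = sdiv(tp, tp + fp),
    fnr = sdiv(fn, tp + fn),
    npv = sdiv(tn, tn + fn),
    csi = sdiv(tp, tp + fn + fp),
    mcc = mcc_o,
    specificity = sdiv(tn, tn + fp),
    bm = bm_o
  )
}

metric_or_na <- function(f, c, ...) {
  tryCatch(f(c, ...), pp_undefined_metric = function(e) NA_real_)
}

# textbook LSTM step, independently coded (no adaptive shift)
reference_lstm_step <- function(input, state, params) {
  sig <- function(z) 1 / (1 + exp(-z))
  act <- function(g, f) as.vector(g$W_y %*% input + g$W_f %*% state$hidden +
                                    g$b)
  f_g <- sig(act(params$forget))
  i_g <- sig(act(params$input))
  o_g <- sig(act(params$output))
  cand <- tanh(act(params$candidate))
  cell <- f_g * state$cell + i_g * cand
  list(hidden = o_g * tanh(cell), cell = cell)
}
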