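# Pest localization: a small strided convolutional backbone, a feature
# pyramid (top-down upsample-and-add merge with 1x1 lateral projections),
# sigmoid-gated adaptive per-level fusion ("AdaUp"), and a dense anchor-free
# detection head (objectness logit + 4 box offsets per cell).

FPN_STRIDES <- c(4L, 8L, 16L, 32L)

#' Detector configuration
#'
#' `hidden_width` is the tunable channel width shared by the backbone and
#' pyramid; `learning_rate` is the tunable gene in `[0.01, 0.99]`, mapped
#' multiplicatively onto a base step size (effective rate = gene x 0.01)
#' before being handed to the optimizer.
#'
#' @param hidden_width Channel width in `[5, 255]`.
#' @param learning_rate Learning-rate gene in `[0.01, 0.99]`.
#' @param epochs Training epochs (upper bound 250).
#' @param score_threshold Objectness threshold applied at inference.
#' @param nms_iou Non-maximum-suppression IoU threshold.
#' @param adaup_init Initial value of the per-level fusion gates (their
#'   sigmoid scales each pyramid level); exposed to the tuner.
#' @param pos_weight Weight multiplier for positive cells in the objectness
#'   loss, balancing the sparse positives against the dense background.
#' @param seed Training seed.
#' @return A `detector_config` object.
#' @export
detector_config <- function(hidden_width = 16L, learning_rate = 0.5,
                            epochs = 12L, score_threshold = 0.5,
                            nms_iou = 0.2, adaup_init = 0,
                            pos_weight = 12, seed = 1L) {
  cfg <- list(hidden_width = as.integer(hidden_width),
              learning_rate = as.numeric(learning_rate),
              epochs = as.integer(epochs),
              score_threshold = as.numeric(score_threshold),
              nms_iou = as.numeric(nms_iou),
              adaup_init = as.numeric(adaup_init),
              pos_weight = as.numeric(pos_weight),
              seed = as.integer(seed))
  if (cfg$hidden_width < 5L || cfg$hidden_width > 255L)
    stop("hidden_width must lie in [5, 255]", call. = FALSE)
  if (cfg$learning_rate < 0.01 || cfg$learning_rate > 0.99)
    stop("learning_rate must lie in [0.01, 0.99]", call. = FALSE)
  if (cfg$epochs < 1L || cfg$epochs > 250L)
    stop("epochs must lie in [1, 250]", call. = FALSE)
  structure(cfg, class = "detector_config")
}

# ---- array <-> channels x pixels layout ------------------------------------

arr_to_chw <- function(a) {
  h <- dim(a)[1]; w <- dim(a)[2]; nc <- dim(a)[3]
  out <- matrix(0, nc, h * w)
  for (ch in seq_len(nc)) out[ch, ] <- as.vector(t(a[, , ch]))
  out
}

chw_to_arr <- function(m, h, w) {
  nc <- nrow(m)
  a <- array(0, dim = c(h, w, nc))
  for (ch in seq_len(nc)) a[, , ch] <- matrix(m[ch, ], h, w, byrow = TRUE)
  a
}

#' Nearest-neighbour x2 upsampling of a 2-D map
#'
#' Each entry is duplicated into a 2x2 block; the operator used by the
#' pyramid's top-down merge.
#'
#' @param m A numeric matrix.
#' @export
upsample_nearest2 <- function(m) {
  m[rep(seq_len(nrow(m)), each = 2L), rep(seq_len(ncol(m)), each = 2L),
    drop = FALSE]
}

# ---- parameter construction ------------------------------------------------

mk_param <- function(nr, nc, sd) ad_param(matrix(stats::rnorm(nr * nc, 0, sd), nr, nc))
mk_bias <- function(nr) ad_param(matrix(0, nr, 1L))

init_detector_params <- function(w, adaup_init) {
  he <- function(fanin) sqrt(2 / fanin)
  list(
    stem_W = mk_param(w, 27L, he(27)), stem_b = mk_bias(w),
    c1_W = mk_param(w, 9L * w, he(9 * w)), c1_b = mk_bias(w),
    c2_W = mk_param(w, 9L * w, he(9 * w)), c2_b = mk_bias(w),
    c3_W = mk_param(w, 9L * w, he(9 * w)), c3_b = mk_bias(w),
    c4_W = mk_param(w, 9L * w, he(9 * w)), c4_b = mk_bias(w),
    l1_W = mk_param(w, w, he(w)), l1_b = mk_bias(w),
    l2_W = mk_param(w, w, he(w)), l2_b = mk_bias(w),
    l3_W = mk_param(w, w, he(w)), l3_b = mk_bias(w),
    l4_W = mk_param(w, w, he(w)), l4_b = mk_bias(w),
    gates = ad_param(matrix(adaup_init, 4L, 1L)),
    head_W = mk_param(w, 9L * w, he(9 * w)), head_b = mk_bias(w),
    out_W = mk_param(5L, w, 0.01), out_b = mk_bias(5L)
  )
}

conv_node <- function(x, W, b, h, w, k, stride, pad = (k - 1L) %/% 2L) {
  cols <- ad_im2col(x, h, w, k, stride, pad)
  ad_add_rowbias(ad_matmul(W, cols), b)
}

# forward pass on ad nodes; x is a (3 x H*W) node
det_forward_nodes <- function(params, x, h, w) {
  s0 <- ad_relu(conv_node(x, params$stem_W, params$stem_b, h, w, 3L, 2L))
  h0 <- h %/% 2L; w0 <- w %/% 2L
  c1 <- ad_relu(conv_node(s0, params$c1_W, params$c1_b, h0, w0, 3L, 2L))
  h1 <- h0 %/% 2L; w1 <- w0 %/% 2L
  c2 <- ad_relu(conv_node(c1, params$c2_W, params$c2_b, h1, w1, 3L, 2L))
  h2 <- h1 %/% 2L; w2 <- w1 %/% 2L
  c3 <- ad_relu(conv_node(c2, params$c3_W, params$c3_b, h2, w2, 3L, 2L))
  h3 <- h2 %/% 2L; w3 <- w2 %/% 2L
  c4 <- ad_relu(conv_node(c3, params$c4_W, params$c4_b, h3, w3, 3L, 2L))
  h4 <- h3 %/% 2L; w4 <- w3 %/% 2L
  # lateral 1x1 projections
  d1 <- ad_add_rowbias(ad_matmul(params$l1_W, c1), params$l1_b)
  d2 <- ad_add_rowbias(ad_matmul(params$l2_W, c2), params$l2_b)
  d3 <- ad_add_rowbias(ad_matmul(params$l3_W, c3), params$l3_b)
  d4 <- ad_add_rowbias(ad_matmul(params$l4_W, c4), params$l4_b)
  # top-down merge: D_j = Upsample(D_p) + D_h, coarse to fine
  p4 <- d4
  p3 <- ad_add(ad_upsample2(p4, h4, w4), d3)
  p2 <- ad_add(ad_upsample2(p3, h3, w3), d2)
  p1 <- ad_add(ad_upsample2(p2, h2, w2), d1)
  pyr <- list(p1, p2, p3, p4)
  dims <- list(c(h1, w1), c(h2, w2), c(h3, w3), c(h4, w4))
  # AdaUp: sigmoid-gated per-level scaling before the shared head
  levels <- vector("list", 4L)
  for (l in 1:4) {
    gate <- ad_sigmoid(ad_slice_cols(ad_transpose(params$gates), l))
    gated <- ad_scale_node(pyr[[l]], gate)
    hh <- dims[[l]][1]; ww <- dims[[l]][2]
    hd <- ad_relu(conv_node(gated, params$head_W, params$head_b, hh, ww, 3L, 1L))
    out <- ad_add_rowbias(ad_matmul(params$out_W, hd), params$out_b)
    levels[[l]] <- list(out = out, h = hh, w = ww, stride = FPN_STRIDES[l])
  }
  list(levels = levels, pyramid = pyr, dims = dims)
}

# ---- public structural operations -----------------------------------------

#' Bottom-up backbone forward pass
#'
#' Runs the strided convolutional backbone on one image, producing four
#' feature maps at strides 4, 8, 16 and 32.  Image height and width must be
#' divisible by 32.
#'
#' @param image A height x width x 3 array in `[0, 1]`.
#' @param model A trained or freshly initialized `fpn_detector`.
#' @return List of four arrays (H/4, W/4, C) ... (H/32, W/32, C).
#' @export
backbone_forward <- function(image, model) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (h %% 32L != 0L || w %% 32L != 0L)
    stop("image height and width must be divisible by 32", call. = FALSE)
  tape_off()
  p <- model$params
  x <- ad_const(arr_to_chw(image))
  s0 <- ad_relu(conv_node(x, p$stem_W, p$stem_b, h, w, 3L, 2L))
  c1 <- ad_relu(conv_node(s0, p$c1_W, p$c1_b, h %/% 2L, w %/% 2L, 3L, 2L))
  c2 <- ad_relu(conv_node(c1, p$c2_W, p$c2_b, h %/% 4L, w %/% 4L, 3L, 2L))
  c3 <- ad_relu(conv_node(c2, p$c3_W, p$c3_b, h %/% 8L, w %/% 8L, 3L, 2L))
  c4 <- ad_relu(conv_node(c3, p$c4_W, p$c4_b, h %/% 16L, w %/% 16L, 3L, 2L))
  maps <- list(val(c1), val(c2), val(c3), val(c4))
  divs <- c(4L, 8L, 16L, 32L)
  lapply(1:4, function(i) chw_to_arr(maps[[i]], h %/% divs[i], w %/% divs[i]))
}

#' Top-down pyramid merge
#'
#' Implements the upsample-and-add merge: the topmost level is its lateral
#' projection alone; every finer level is the nearest-neighbour x2
#' upsampling of the previously merged coarser map plus its own lateral
#' projection.
#'
#' @param bottom_up List of feature maps (H x W x C arrays), ordered fine to
#'   coarse, each level half the spatial size of the previous.
#' @param laterals Optional list of projection matrices
#'   (`channels_common` x C); `NULL` uses identity laterals (all levels must
#'   then share a channel count).
#' @return List of merged maps, same order and spatial sizes as the input,
#'   all with `channels_common` channels.
#' @export
#' @examples
#' coarse <- array(2, dim = c(1, 1, 1))
#' fine <- array(3, dim = c(2, 2, 1))
#' fpn_merge(list(fine, coarse))[[1]][, , 1]  # all entries 5
fpn_merge <- function(bottom_up, laterals = NULL) {
  n <- length(bottom_up)
  if (n < 2L) stop("fpn_merge needs at least two levels", call. = FALSE)
  proj <- lapply(seq_len(n), function(i) {
    m <- arr_to_chw(bottom_up[[i]])
    if (is.null(laterals)) m else {
      if (ncol(laterals[[i]]) != nrow(m))
        stop("lateral projection has mismatched channels", call. = FALSE)
      laterals[[i]] %*% m
    }
  })
  cc <- unique(vapply(proj, nrow, 0L))
  if (length(cc) != 1L)
    stop("projected levels disagree on channels_common", call. = FALSE)
  dims <- lapply(bottom_up, function(a) dim(a)[1:2])
  merged <- vector("list", n)
  merged[[n]] <- proj[[n]]
  for (i in (n - 1L):1L) {
    hp <- dims[[i + 1L]][1]; wp <- dims[[i + 1L]][2]
    up <- val(ad_upsample2(ad_const(merged[[i + 1L]]), hp, wp))
    if (ncol(up) != ncol(proj[[i]]))
      stop("levels are not dyadically nested", call. = FALSE)
    merged[[i]] <- up + proj[[i]]
  }
  lapply(seq_len(n), function(i) chw_to_arr(merged[[i]], dims[[i]][1],
                                            dims[[i]][2]))
}

#' Sigmoid-gated adaptive fusion of pyramid levels
#'
#' Each level is scaled by the sigmoid of its gate before the detection
#' head; a gate of 0 halves a level, a large positive gate leaves it
#' unchanged, a large negative gate suppresses it.
#'
#' @param pyramid List of feature maps (arrays).
#' @param gates Numeric vector, one gate per level.
#' @return List of gated maps.
#' @export
adaup_fuse <- function(pyramid, gates) {
  if (length(gates) != length(pyramid))
    stop("need exactly one gate per pyramid level", call. = FALSE)
  lapply(seq_along(pyramid), function(i)
    pyramid[[i]] / (1 + exp(-gates[i])))
}

#' Decode / encode anchor-free cell predictions
#'
#' For a cell at row `i`, column `j` (0-based) of a level with the given
#' stride, the predicted box has center
#' `((j + 0.5) * stride + dx, (i + 0.5) * stride + dy)` and size
#' `stride * exp(dw)` by `stride * exp(dh)`, where the pixel offsets
#' `dx = tx * stride`, `dy = ty * stride` come from the raw offsets
#' `t = c(tx, ty, tw, th)`.  `encode_cell()` is the exact inverse.
#'
#' @param t Length-4 raw offset vector.
#' @param stride Level stride in pixels.
#' @param i,j 0-based cell row and column.
#' @return `decode_cell()`: a box `c(x_min, y_min, x_max, y_max)`;
#'   `encode_cell()`: a length-4 offset vector.
#' @export
decode_cell <- function(t, stride, i, j) {
  cx <- (j + 0.5) * stride + t[1] * stride
  cy <- (i + 0.5) * stride + t[2] * stride
  bw <- stride * exp(t[3]); bh <- stride * exp(t[4])
  c(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
}

#' @rdname decode_cell
#' @param box A box `c(x_min, y_min, x_max, y_max)`.
#' @export
encode_cell <- function(box, stride, i, j) {
  bw <- box[3] - box[1]; bh <- box[4] - box[2]
  cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
  c((cx - (j + 0.5) * stride) / stride,
    (cy - (i + 0.5) * stride) / stride,
    log(bw / stride), log(bh / stride))
}

# ---- training targets ------------------------------------------------------

# positive-cell assignment: cell center inside a gt box at levels whose
# stride lies within [object_size / 8, object_size]; smallest box wins
level_targets <- function(annotations, h, w) {
  out <- vector("list", 4L)
  boxes <- annotations
  sizes <- if (nrow(boxes)) sqrt((boxes$x_max - boxes$x_min) *
                                   (boxes$y_max - boxes$y_min)) else numeric(0)
  areas <- if (nrow(boxes)) (boxes$x_max - boxes$x_min) *
    (boxes$y_max - boxes$y_min) else numeric(0)
  for (l in 1:4) {
    s <- FPN_STRIDES[l]
    hh <- h %/% s; ww <- w %/% s
    ncell <- hh * ww
    pos <- matrix(0, 1L, ncell)
    tgt <- matrix(0, 4L, ncell)
    if (nrow(boxes)) {
      jj <- (seq_len(ncell) - 1L) %% ww
      ii <- (seq_len(ncell) - 1L) %/% ww
      cx <- (jj + 0.5) * s; cy <- (ii + 0.5) * s
      assigned_area <- rep(Inf, ncell)
      for (b in seq_len(nrow(boxes))) {
        if (s < sizes[b] / 8 || s > sizes[b]) next
        inside <- cx >= boxes$x_min[b] & cx < boxes$x_max[b] &
          cy >= boxes$y_min[b] & cy < boxes$y_max[b]
        take <- inside & areas[b] < assigned_area
        if (!any(take)) next
        assigned_area[take] <- areas[b]
        pos[1L, take] <- 1
        bw <- boxes$x_max[b] - boxes$x_min[b]
        bh <- boxes$y_max[b] - boxes$y_min[b]
        bcx <- (boxes$x_min[b] + boxes$x_max[b]) / 2
        bcy <- (boxes$y_min[b] + boxes$y_max[b]) / 2
        tgt[1L, take] <- (bcx - cx[take]) / s
        tgt[2L, take] <- (bcy - cy[take]) / s
        tgt[3L, take] <- log(bw / s)
        tgt[4L, take] <- log(bh / s)
      }
    }
    out[[l]] <- list(pos = pos, tgt = tgt)
  }
  out
}

det_loss_nodes <- function(fwd, targets, pos_weight) {
  losses <- vector("list", 0L)
  for (l in 1:4) {
    lev <- fwd$levels[[l]]
    tg <- targets[[l]]
    # lev$out is 5 x ncell; row 1 is the objectness logit, rows 2:5 offsets
    out_t <- ad_transpose(lev$out)                      # ncell x 5
    logits <- ad_transpose(ad_slice_cols(out_t, 1L))    # 1 x ncell
    offs <- ad_transpose(ad_slice_cols(out_t, 2:5))     # 4 x ncell
    wts <- 1 + (pos_weight - 1) * tg$pos
    losses[[length(losses) + 1L]] <-
      ad_bce_logits(logits, ad_const(tg$pos), ad_const(wts))
    if (any(tg$pos > 0)) {
      mask <- matrix(rep(tg$pos, each = 4L), nrow = 4L)
      losses[[length(losses) + 1L]] <-
        ad_smooth_l1(offs, ad_const(tg$tgt), ad_const(mask))
    }
  }
  total <- losses[[1]]
  for (i in seq_along(losses)[-1]) total <- ad_add(total, losses[[i]])
  total
}

#' Train the FPN detector
#'
#' Per-image gradient steps with Adam at the effective rate
#' `learning_rate x 0.01`: weighted binary cross-entropy on the dense
#' objectness map (cells whose center falls inside a ground-truth box are
#' positive) plus smooth-L1 on the box offsets at positive cells.
#' Seed-reproducible; aborts with a diagnostic on a non-finite loss.
#'
#' @param split A `scene_split` (only the train part is used).
#' @param config A [detector_config()].
#' @return An `fpn_detector`: list with `params`, `config`, `cost` (tibble
#'   `epoch`, `cost` of per-epoch mean loss) and `trained = TRUE`.
#' @export
train_detector <- function(split, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  scenes <- split$train
  if (length(scenes) == 0L) stop("train split is empty", call. = FALSE)
  h <- dim(scenes[[1]]$image)[1]; w <- dim(scenes[[1]]$image)[2]
  if (h %% 32L != 0L || w %% 32L != 0L)
    stop("scene height and width must be divisible by 32", call. = FALSE)
  withr::with_seed(config$seed, {
    params <- init_detector_params(config$hidden_width, config$adaup_init)
    plist <- params[!vapply(params, is.null, TRUE)]
    xs <- lapply(scenes, function(sc) arr_to_chw(sc$image))
    tgts <- lapply(scenes, function(sc) level_targets(sc$annotations, h, w))
    lr <- config$learning_rate * 0.01
    cost <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(scenes))
      tot <- 0
      for (i in ord) {
        tape_reset()
        zero_grads(plist)
        fwd <- det_forward_nodes(params, ad_const(xs[[i]]), h, w)
        loss <- det_loss_nodes(fwd, tgts[[i]], config$pos_weight)
        if (!is.finite(loss$value))
          stop(sprintf("detector training diverged at epoch %d (loss = %g)",
                       ep, loss$value), call. = FALSE)
        backward(loss)
        adam_step(plist, lr)
        tot <- tot + loss$value
      }
      cost[ep] <- tot / length(scenes)
    }
    tape_off()
    structure(list(params = params, config = config,
                   cost = tibble::tibble(epoch = seq_len(config$epochs),
                                         cost = cost),
                   trained = TRUE),
              class = "fpn_detector")
  })
}

nms_boxes <- function(det, nms_iou) {
  keep <- logical(nrow(det))
  ord <- order(det$score, decreasing = TRUE)
  for (i in ord) {
    bi <- c(det$x_min[i], det$y_min[i], det$x_max[i], det$y_max[i])
    ok <- TRUE
    for (j in which(keep)) {
      bj <- c(det$x_min[j], det$y_min[j], det$x_max[j], det$y_max[j])
      if (box_iou(bi, bj) > nms_iou) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  det[keep, , drop = FALSE]
}

#' Detect pests in one image
#'
#' Forward pass through the trained detector; cells with sigmoid objectness
#' at or above the score threshold are decoded into boxes, clipped to the
#' image, and filtered by non-maximum suppression.
#'
#' @param image A height x width x 3 array.
#' @param model A trained `fpn_detector`.
#' @param score_threshold,nms_iou Optional overrides of the model config.
#' @return Tibble `x_min`, `y_min`, `x_max`, `y_max`, `score`, sorted by
#'   descending score.
#' @export
detect <- function(image, model, score_threshold = NULL, nms_iou = NULL) {
  if (!isTRUE(model$trained))
    stop("model has not been trained; call train_detector() first",
         call. = FALSE)
  st <- score_threshold %||% model$config$score_threshold
  ni <- nms_iou %||% model$config$nms_iou
  h <- dim(image)[1]; w <- dim(image)[2]
  tape_off()
  fwd <- det_forward_nodes(model$params, ad_const(arr_to_chw(image)), h, w)
  rows <- list()
  for (l in 1:4) {
    lev <- fwd$levels[[l]]
    o <- val(lev$out)
    prob <- 1 / (1 + exp(-o[1L, ]))
    sel <- which(prob >= st)
    if (!length(sel)) next
    s <- lev$stride; ww <- lev$w
    for (ci in sel) {
      jj <- (ci - 1L) %% ww; ii <- (ci - 1L) %/% ww
      box <- decode_cell(o[2:5, ci], s, ii, jj)
      box <- c(max(0, box[1]), max(0, box[2]), min(w, box[3]), min(h, box[4]))
      if (box[3] <= box[1] || box[4] <= box[2]) next
      rows[[length(rows) + 1L]] <-
        tibble::tibble(x_min = box[1], y_min = box[2], x_max = box[3],
                       y_max = box[4], score = prob[ci])
    }
  }
  if (!length(rows))
    return(tibble::tibble(x_min = numeric(0), y_min = numeric(0),
                          x_max = numeric(0), y_max = numeric(0),
                          score = numeric(0)))
  det <- dplyr::bind_rows(rows)
  det <- nms_boxes(det, ni)
  dplyr::arrange(det, dplyr::desc(.data$score))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fpn_detector <- function(x, ...) {
  cat(sprintf("<fpn_detector> width %d, %d epoch(s), final cost %.4f\n",
              x$config$hidden_width, nrow(x$cost),
              x$cost$cost[nrow(x$cost)]))
  invisible(x)
}
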