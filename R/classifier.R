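# Pest classification of detected crops: patch embedding at multiple input
# scales, per-scale multi-head self-attention, softmax-weighted cross-scale
# fusion with one further attention block, and an adaptive LSTM that
# consumes the fused token sequence.  The LSTM's input gate is shifted by
# the logit of a per-token significance score (the mean attention each
# token receives in the fusion block), so tokens the transformer deems
# relevant write more strongly to memory.

#' Classifier configuration
#'
#' `hidden_width` (LSTM hidden units) and `learning_rate` (gene mapped onto
#' an effective rate of gene x 0.01) are the two tunable genes; the
#' remaining fields fix the transformer geometry.  `use_attention`,
#' `use_lstm` and `adaptive` switch off components for ablation studies.
#'
#' @param hidden_width LSTM hidden units in `[5, 255]`.
#' @param learning_rate Learning-rate gene in `[0.01, 0.99]`.
#' @param epochs Training epochs (upper bound 250).
#' @param n_classes Number of pest classes.
#' @param d Token embedding dimension (divisible by `n_heads`).
#' @param patch_size Patch side in pixels.
#' @param crop_size Side of the square resized crop (divisible by
#'   `patch_size`).
#' @param scales Input side lengths; each scale is the crop resized to that
#'   side and patch-embedded separately.
#' @param n_heads Attention heads.
#' @param use_attention,use_lstm,adaptive Ablation switches.
#' @param seed Training seed.
#' @export
classifier_config <- function(hidden_width = 32L, learning_rate = 0.2,
                              epochs = 6L, n_classes = 3L, d = 32L,
                              patch_size = 8L, crop_size = 32L,
                              scales = c(32L, 16L), n_heads = 2L,
                              use_attention = TRUE, use_lstm = TRUE,
                              adaptive = TRUE, seed = 1L) {
  cfg <- list(hidden_width = as.integer(hidden_width),
              learning_rate = as.numeric(learning_rate),
              epochs = as.integer(epochs), n_classes = as.integer(n_classes),
              d = as.integer(d), patch_size = as.integer(patch_size),
              crop_size = as.integer(crop_size), scales = as.integer(scales),
              n_heads = as.integer(n_heads),
              use_attention = isTRUE(use_attention),
              use_lstm = isTRUE(use_lstm), adaptive = isTRUE(adaptive),
              seed = as.integer(seed))
  if (cfg$hidden_width < 5L || cfg$hidden_width > 255L)
    stop("hidden_width must lie in [5, 255]", call. = FALSE)
  if (cfg$learning_rate < 0.01 || cfg$learning_rate > 0.99)
    stop("learning_rate must lie in [0.01, 0.99]", call. = FALSE)
  if (cfg$epochs < 1L || cfg$epochs > 250L)
    stop("epochs must lie in [1, 250]", call. = FALSE)
  if (cfg$d %% cfg$n_heads != 0L)
    stop("d must be divisible by n_heads", call. = FALSE)
  if (any(cfg$scales %% cfg$patch_size != 0L))
    stop("every scale must be divisible by patch_size", call. = FALSE)
  if (cfg$n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  structure(cfg, class = "classifier_config")
}

# ---- crop extraction -------------------------------------------------------

# bilinear sample of one channel at continuous (row, col) grids
sample_bilinear <- function(ch, ys, xs) {
  h <- nrow(ch); w <- ncol(ch)
  ys <- pmin(pmax(ys, 1), h); xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  fy <- ys - y0; fx <- xs - x0
  n <- length(ys); m <- length(xs)
  Y0 <- rep(y0, times = m); X0 <- rep(x0, each = n)
  FY <- rep(fy, times = m); FX <- rep(fx, each = n)
  a <- ch[cbind(Y0, X0)]; b <- ch[cbind(Y0, X0 + 1L)]
  cc <- ch[cbind(Y0 + 1L, X0)]; d <- ch[cbind(Y0 + 1L, X0 + 1L)]
  matrix(a * (1 - FY) * (1 - FX) + b * (1 - FY) * FX +
           cc * FY * (1 - FX) + d * FY * FX, nrow = n)
}

#' Crop a detection box out of an image with context padding
#'
#' The box is expanded by `pad` of its size on each side, clipped to the
#' image, and bilinearly resized to a square `out_size` crop.
#'
#' @param image Height x width x 3 array.
#' @param box `c(x_min, y_min, x_max, y_max)`, 0-based half-open.
#' @param pad Relative context padding (default 10%).
#' @param out_size Output side in pixels.
#' @return An `out_size` x `out_size` x 3 array.
#' @export
crop_detection <- function(image, box, pad = 0.1, out_size = 32L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  bw <- box[3] - box[1]; bh <- box[4] - box[2]
  x0 <- max(0, box[1] - pad * bw); x1 <- min(w, box[3] + pad * bw)
  y0 <- max(0, box[2] - pad * bh); y1 <- min(h, box[4] + pad * bh)
  xs <- seq(x0 + 0.5 * (x1 - x0) / out_size, x1 - 0.5 * (x1 - x0) / out_size,
            length.out = out_size) + 0.5
  ys <- seq(y0 + 0.5 * (y1 - y0) / out_size, y1 - 0.5 * (y1 - y0) / out_size,
            length.out = out_size) + 0.5
  out <- array(0, dim = c(out_size, out_size, 3))
  for (ch in 1:3) out[, , ch] <- sample_bilinear(image[, , ch], ys, xs)
  out
}

resize_square <- function(crop, side) {
  if (dim(crop)[1] == side) return(crop)
  xs <- seq(0.5, dim(crop)[2] - 0.5, length.out = side) + 0.5
  ys <- seq(0.5, dim(crop)[1] - 0.5, length.out = side) + 0.5
  out <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) out[, , ch] <- sample_bilinear(crop[, , ch], ys, xs)
  out
}

# flatten a (side x side x 3) crop into a T x (patch^2 * 3) patch matrix,
# patches in row-major order
patch_matrix <- function(crop, patch_size) {
  side <- dim(crop)[1]
  np <- side %/% patch_size
  out <- matrix(0, np * np, patch_size * patch_size * 3L)
  t_i <- 0L
  for (pi in seq_len(np)) {
    for (pj in seq_len(np)) {
      t_i <- t_i + 1L
      ys <- ((pi - 1L) * patch_size + 1L):(pi * patch_size)
      xs <- ((pj - 1L) * patch_size + 1L):(pj * patch_size)
      out[t_i, ] <- as.vector(crop[ys, xs, ])
    }
  }
  out
}

#' Patch embedding of an image crop
#'
#' Splits a square crop into non-overlapping patches in row-major order and
#' maps each flattened patch through a linear projection, then adds a
#' positional encoding: `tokens = P W + b + pos`.
#'
#' @param crop A side x side x 3 array, side divisible by `patch_size`.
#' @param patch_size Patch side in pixels.
#' @param W Projection matrix, `(patch_size^2 * 3) x d`.
#' @param b Optional length-`d` bias (default 0).
#' @param pos Optional `T x d` positional encoding (default 0).
#' @return A `T x d` token matrix, `T = (side / patch_size)^2`.
#' @export
patch_embed <- function(crop, patch_size, W, b = NULL, pos = NULL) {
  side <- dim(crop)[1]
  if (side %% patch_size != 0L)
    stop("crop side must be divisible by patch_size", call. = FALSE)
  P <- patch_matrix(crop, patch_size)
  tok <- P %*% W
  if (!is.null(b)) tok <- sweep(tok, 2L, as.vector(b), "+")
  if (!is.null(pos)) tok <- tok + pos
  tok
}

# ---- parameters ------------------------------------------------------------

attn_block_params <- function(d, sd) {
  list(Wq = mk_param(d, d, sd), Wk = mk_param(d, d, sd),
       Wv = mk_param(d, d, sd), Wo = mk_param(d, d, sd),
       ln_g = ad_param(matrix(1, 1L, d)), ln_b = ad_param(matrix(0, 1L, d)))
}

lstm_gate_params <- function(hid, d, sd, bias0 = 0) {
  list(W_y = mk_param(hid, d, sd), W_f = mk_param(hid, hid, sd),
       b = ad_param(matrix(bias0, hid, 1L)))
}

init_classifier_params <- function(cfg) {
  d <- cfg$d; hid <- cfg$hidden_width
  pdim <- cfg$patch_size^2 * 3L
  sd_e <- sqrt(1 / pdim); sd_a <- sqrt(1 / d); sd_l <- sqrt(1 / (d + hid))
  ntok <- (cfg$scales %/% cfg$patch_size)^2
  list(
    embed_W = mk_param(pdim, d, sd_e),
    embed_b = ad_param(matrix(0, 1L, d)),
    pos = lapply(ntok, function(tt) mk_param(tt, d, 0.02)),
    scale_attn = lapply(seq_along(cfg$scales), function(i)
      attn_block_params(d, sd_a)),
    fuse_w = ad_param(matrix(0, length(cfg$scales), 1L)),
    fuse_attn = attn_block_params(d, sd_a),
    lstm = list(forget = lstm_gate_params(hid, d, sd_l, bias0 = 1),
                input = lstm_gate_params(hid, d, sd_l),
                output = lstm_gate_params(hid, d, sd_l),
                candidate = lstm_gate_params(hid, d, sd_l)),
    out_W = mk_param(cfg$n_classes, if (cfg$use_lstm) hid else d, 0.01),
    out_b = mk_bias(cfg$n_classes)
  )
}

flatten_params <- function(x) {
  if (is_node(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, flatten_params)))
  list()
}

# ---- forward pieces (ad nodes) ---------------------------------------------

# standard multi-head self-attention block with residual and layer norm;
# returns the output tokens and the head-averaged attention matrix
mha_nodes <- function(X, blk, n_heads) {
  d <- ncol(val(X)); dh <- d %/% n_heads
  Q <- ad_matmul(X, blk$Wq); K <- ad_matmul(X, blk$Wk)
  V <- ad_matmul(X, blk$Wv)
  heads <- vector("list", n_heads)
  attns <- vector("list", n_heads)
  for (hh in seq_len(n_heads)) {
    idx <- ((hh - 1L) * dh + 1L):(hh * dh)
    Qh <- ad_slice_cols(Q, idx); Kh <- ad_slice_cols(K, idx)
    Vh <- ad_slice_cols(V, idx)
    S <- ad_scale(ad_matmul(Qh, ad_transpose(Kh)), 1 / sqrt(dh))
    A <- ad_softmax_rows(S)
    attns[[hh]] <- A
    heads[[hh]] <- ad_matmul(A, Vh)
  }
  O <- ad_matmul(ad_concat_cols(heads), blk$Wo)
  Y <- ad_layernorm_rows(ad_add(X, O), blk$ln_g, blk$ln_b)
  A_avg <- attns[[1]]
  if (n_heads > 1L) {
    for (hh in 2:n_heads) A_avg <- ad_add(A_avg, attns[[hh]])
    A_avg <- ad_scale(A_avg, 1 / n_heads)
  }
  list(tokens = Y, attention = A_avg)
}

# one adaptive LSTM step on column vectors; gates: forget h, input t,
# output k, candidate d~; cell d_s = h (.) d_prev + t (.) d~;
# hidden f_s = k (.) tanh(d_s).  The input-gate pre-activation is shifted
# by logit(significance).
alstm_step_nodes <- function(y, f_prev, c_prev, lstm, sig) {
  pre <- function(g) ad_add_rowbias(
    ad_add(ad_matmul(g$W_y, y), ad_matmul(g$W_f, f_prev)), g$b)
  h_gate <- ad_sigmoid(pre(lstm$forget))
  in_pre <- pre(lstm$input)
  in_pre <- ad_add_scalar_node(in_pre, ad_logit(sig))
  t_gate <- ad_sigmoid(in_pre)
  k_gate <- ad_sigmoid(pre(lstm$output))
  cand <- ad_tanh(pre(lstm$candidate))
  cell <- ad_add(ad_mul(h_gate, c_prev), ad_mul(t_gate, cand))
  hidden <- ad_mul(k_gate, ad_tanh(cell))
  list(hidden = hidden, cell = cell, gates = list(forget = h_gate,
       input = t_gate, output = k_gate, candidate = cand))
}

# fused-gate variant used by the training loop: one stacked matmul per
# step instead of four; numerically identical to alstm_step_nodes
alstm_sequence_nodes <- function(Z, sig, lstm, hid) {
  gates <- c("forget", "input", "output", "candidate")
  Wy <- ad_concat_rows(lapply(gates, function(g) lstm[[g]]$W_y))
  Wf <- ad_concat_rows(lapply(gates, function(g) lstm[[g]]$W_f))
  bb <- ad_concat_rows(lapply(gates, function(g) lstm[[g]]$b))
  f_prev <- ad_const(matrix(0, hid, 1L))
  c_prev <- ad_const(matrix(0, hid, 1L))
  TT <- nrow(val(Z))
  for (t in seq_len(TT)) {
    y <- ad_row_as_col(Z, t)
    pre <- ad_add_rowbias(ad_add(ad_matmul(Wy, y), ad_matmul(Wf, f_prev)), bb)
    h_gate <- ad_sigmoid(ad_slice_rows(pre, 1:hid))
    in_pre <- ad_add_scalar_node(ad_slice_rows(pre, (hid + 1L):(2L * hid)),
                                 ad_logit(ad_row_as_col(sig, t)))
    t_gate <- ad_sigmoid(in_pre)
    k_gate <- ad_sigmoid(ad_slice_rows(pre, (2L * hid + 1L):(3L * hid)))
    cand <- ad_tanh(ad_slice_rows(pre, (3L * hid + 1L):(4L * hid)))
    c_prev <- ad_add(ad_mul(h_gate, c_prev), ad_mul(t_gate, cand))
    f_prev <- ad_mul(k_gate, ad_tanh(c_prev))
  }
  f_prev
}

# full classifier forward; raw_patches is a list (one per scale) of
# T_s x (patch^2*3) matrices
cls_forward_nodes <- function(params, cfg, raw_patches) {
  seqs <- vector("list", length(raw_patches))
  for (i in seq_along(raw_patches)) {
    tok <- ad_add_colbias(ad_matmul(ad_const(raw_patches[[i]]),
                                    params$embed_W), params$embed_b)
    seqs[[i]] <- ad_add(tok, params$pos[[i]])
  }
  ntok <- vapply(raw_patches, nrow, 0L)
  if (cfg$use_attention) {
    att <- lapply(seq_along(seqs), function(i)
      mha_nodes(seqs[[i]], params$scale_attn[[i]], cfg$n_heads))
    wts <- ad_softmax_rows(ad_transpose(params$fuse_w))  # 1 x n_scales
    scaled <- lapply(seq_along(att), function(i)
      ad_scale_node(att[[i]]$tokens, ad_slice_cols(wts, i)))
    Z0 <- ad_concat_rows(scaled)
    fused <- mha_nodes(Z0, params$fuse_attn, cfg$n_heads)
    Z <- fused$tokens
    # significance: mean attention received per token, calibrated so that
    # uniform attention (column mean 1/T) maps to exactly 0.5
    TT <- sum(ntok)
    sig <- if (cfg$adaptive)
      ad_scale(ad_colmeans_as_col(fused$attention), TT / 2) else
      ad_const(matrix(0.5, TT, 1L))
  } else {
    Z <- ad_concat_rows(seqs)
    fused <- NULL
    sig <- ad_const(matrix(0.5, sum(ntok), 1L))
  }
  if (cfg$use_lstm) {
    feat <- alstm_sequence_nodes(Z, sig, params$lstm, cfg$hidden_width)
  } else {
    feat <- ad_colmeans_as_col(Z)  # mean-pooled tokens, d x 1
  }
  logits <- ad_add_rowbias(ad_matmul(params$out_W, feat), params$out_b)
  list(logits = logits, fused = fused, significance = sig)
}

# ---- public structural operations -----------------------------------------

#' Multi-head self-attention over a token sequence
#'
#' Scaled dot-product attention per head, concatenated, output-projected,
#' residual-added and layer-normalized.
#'
#' @param tokens A `T x d` matrix.
#' @param params Block parameters from [attention_params()].
#' @param n_heads Number of heads (`d` divisible by it).
#' @return List with `tokens` (`T x d`) and `attention` (head-averaged
#'   `T x T` matrix whose rows sum to 1).
#' @export
multi_head_attention <- function(tokens, params, n_heads = 2L) {
  if (ncol(tokens) %% n_heads != 0L)
    stop("token dimension must be divisible by n_heads", call. = FALSE)
  tape_off()
  blk <- lapply(params, ad_const)
  out <- mha_nodes(ad_const(tokens), blk, n_heads)
  list(tokens = val(out$tokens), attention = val(out$attention))
}

#' Random initialization of one attention block
#'
#' @param d Token dimension.
#' @param seed Seed.
#' @return List of plain matrices `Wq`, `Wk`, `Wv`, `Wo`, `ln_g`, `ln_b`.
#' @export
attention_params <- function(d, seed = 1L) {
  withr::with_seed(seed, {
    sd <- sqrt(1 / d)
    list(Wq = matrix(stats::rnorm(d * d, 0, sd), d, d),
         Wk = matrix(stats::rnorm(d * d, 0, sd), d, d),
         Wv = matrix(stats::rnorm(d * d, 0, sd), d, d),
         Wo = matrix(stats::rnorm(d * d, 0, sd), d, d),
         ln_g = matrix(1, 1L, d), ln_b = matrix(0, 1L, d))
  })
}

#' Attention-based fusion of per-scale token sequences
#'
#' Each scale passes through its own self-attention block; the sequences
#' are then concatenated along the token axis with softmax-normalized
#' per-scale scalar weights and fed to one cross-scale attention block.
#'
#' @param sequences List of `T_s x d` token matrices (common `d`).
#' @param scale_params List of [attention_params()] blocks, one per scale.
#' @param fuse_params One [attention_params()] block for the cross-scale
#'   pass.
#' @param scale_logits Numeric vector of per-scale weight logits
#'   (softmaxed to the fusion weights).
#' @param n_heads Number of heads.
#' @return List with `tokens` (fused sequence), `attention` (cross-scale
#'   attention matrix), `weights` (softmax-normalized scale weights) and
#'   `significance` (per-token column-mean of the fusion attention).
#' @export
multi_attention_fusion <- function(sequences, scale_params, fuse_params,
                                   scale_logits = rep(0, length(sequences)),
                                   n_heads = 2L) {
  d <- unique(vapply(sequences, ncol, 0L))
  if (length(d) != 1L)
    stop("sequences must share a common dimension d", call. = FALSE)
  tape_off()
  att <- lapply(seq_along(sequences), function(i)
    mha_nodes(ad_const(sequences[[i]]),
              lapply(scale_params[[i]], ad_const), n_heads))
  w <- exp(scale_logits - max(scale_logits))
  w <- w / sum(w)
  scaled <- lapply(seq_along(att), function(i)
    ad_scale(att[[i]]$tokens, w[i]))
  Z0 <- ad_concat_rows(scaled)
  fused <- mha_nodes(Z0, lapply(fuse_params, ad_const), n_heads)
  A <- val(fused$attention)
  list(tokens = val(fused$tokens), attention = A, weights = w,
       significance = colMeans(A) * nrow(A) / 2)
}

#' Plain LSTM parameter initialization
#'
#' One weight pair (input-to-gate, hidden-to-gate) and bias per gate
#' (forget, input, output, candidate).  Zero matrices give the closed-form
#' step used in tests: all gates 0.5, candidate 0.
#'
#' @param input_dim Input dimension.
#' @param hidden_width Hidden units.
#' @param init `"zero"` or `"random"`.
#' @param seed Seed for random init.
#' @export
lstm_params <- function(input_dim, hidden_width, init = c("zero", "random"),
                        seed = 1L) {
  init <- match.arg(init)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else
      matrix(stats::rnorm(nr * nc, 0, sqrt(1 / (input_dim + hidden_width))),
             nr, nc)
  }
  withr::with_seed(seed, {
    gates <- c("forget", "input", "output", "candidate")
    out <- lapply(gates, function(g)
      list(W_y = mk(hidden_width, input_dim),
           W_f = mk(hidden_width, hidden_width),
           b = matrix(0, hidden_width, 1L)))
    names(out) <- gates
    out
  })
}

#' One adaptive LSTM step
#'
#' Forget gate `h = sigmoid(W_y y + W_f f_prev + b)`, candidate
#' `tanh(...)`, input and output gates analogous; the input-gate
#' pre-activation is shifted by `logit(significance)`, so at
#' `significance = 0.5` the step is exactly the textbook LSTM step.  Cell
#' `d_s = h * d_prev + t * candidate` (Hadamard products), hidden
#' `f_s = k * tanh(d_s)`.
#'
#' @param input Numeric input vector (length = input dim).
#' @param state List with `hidden` and `cell` vectors (length =
#'   hidden width).
#' @param params From [lstm_params()].
#' @param significance Real in `[0, 1]`.
#' @return List with `hidden`, `cell` and `gates` (each gate's activation
#'   vector).
#' @export
lstm_step <- function(input, state, params, significance = 0.5) {
  if (!all(is.finite(input)) || !all(is.finite(state$hidden)) ||
      !all(is.finite(state$cell)))
    stop("non-finite inputs to lstm_step", call. = FALSE)
  tape_off()
  blk <- lapply(params, function(g) lapply(g, ad_const))
  st <- alstm_step_nodes(ad_const(matrix(input, ncol = 1L)),
                         ad_const(matrix(state$hidden, ncol = 1L)),
                         ad_const(matrix(state$cell, ncol = 1L)),
                         blk, ad_const(matrix(significance)))
  list(hidden = as.vector(val(st$hidden)), cell = as.vector(val(st$cell)),
       gates = lapply(st$gates, function(n) as.vector(val(n))))
}

# ---- training and inference ------------------------------------------------

crop_patches <- function(crop, cfg) {
  lapply(cfg$scales, function(s) patch_matrix(resize_square(crop, s),
                                              cfg$patch_size))
}

#' Train the pest-crop classifier
#'
#' Cross-entropy loss, Adam at the effective rate `learning_rate x 0.01`,
#' per-crop gradient steps; seed-reproducible.
#'
#' @param crops List of crop arrays (any square size; resized internally).
#' @param labels Integer class labels in `[0, n_classes)`.
#' @param config A [classifier_config()].
#' @return A `mafvit_alstm` model: list with `params`, `config`, `cost`
#'   (per-epoch mean loss tibble) and `trained = TRUE`.
#' @export
train_classifier <- function(crops, labels, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  if (length(crops) != length(labels))
    stop("crops and labels must have equal length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training data must contain at least two classes", call. = FALSE)
  if (any(labels < 0L | labels >= config$n_classes))
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  withr::with_seed(config$seed, {
    params <- init_classifier_params(config)
    plist <- flatten_params(params)
    raw <- lapply(crops, crop_patches, cfg = config)
    lr <- config$learning_rate * 0.01
    cost <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(crops))
      tot <- 0
      for (i in ord) {
        tape_reset()
        zero_grads(plist)
        fwd <- cls_forward_nodes(params, config, raw[[i]])
        loss <- ad_cross_entropy(fwd$logits, labels[i] + 1L)
        if (!is.finite(loss$value))
          stop(sprintf("classifier training diverged at epoch %d", ep),
               call. = FALSE)
        backward(loss)
        adam_step(plist, lr)
        tot <- tot + loss$value
      }
      cost[ep] <- tot / length(crops)
    }
    tape_off()
    structure(list(params = params, config = config,
                   cost = tibble::tibble(epoch = seq_len(config$epochs),
                                         cost = cost),
                   trained = TRUE),
              class = "mafvit_alstm")
  })
}

#' Classify one pest crop
#'
#' @param crop A square crop array (resized internally to the model's
#'   scales).
#' @param model A trained `mafvit_alstm`.
#' @return Named numeric vector of class probabilities (sums to 1).
#' @export
classify <- function(crop, model) {
  if (!isTRUE(model$trained))
    stop("model has not been trained; call train_classifier() first",
         call. = FALSE)
  tape_off()
  fwd <- cls_forward_nodes(model$params, model$config,
                           crop_patches(crop, model$config))
  z <- as.vector(val(fwd$logits))
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  names(p) <- paste0("class_", seq_along(p) - 1L)
  p
}

#' @export
print.mafvit_alstm <- function(x, ...) {
  cat(sprintf(
    "<mafvit_alstm> %d classes, lstm width %d, %d epoch(s), final cost %.4f\n",
    x$config$n_classes, x$config$hidden_width, nrow(x$cost),
    x$cost$cost[nrow(x$cost)]))
  invisible(x)
}
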