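# Minimal reverse-mode automatic differentiation over base-R matrices.
#
# Design: a global "tape" records every intermediate node in creation order;
# creation order reversed is a valid topological order, so backward() is a
# single reverse sweep.  Parameter nodes live OFF the tape (created once,
# reused across steps); their gradients accumulate during the sweep and are
# consumed by the optimizer.  Values are plain numeric matrices; feature maps
# use a channels x (H*W) layout (row-major spatial order), token sequences a
# tokens x dim layout, and state vectors are column matrices.

.tape <- new.env(parent = emptyenv())
.tape$nodes <- vector("list", 1024L)
.tape$n <- 0L
.tape$active <- FALSE

tape_reset <- function() {
  if (.tape$n > 0L) .tape$nodes[seq_len(.tape$n)] <- list(NULL)
  .tape$n <- 0L
  .tape$active <- TRUE
  invisible(NULL)
}

tape_off <- function() {
  .tape$active <- FALSE
  invisible(NULL)
}

new_node <- function(value, parents = list(), backward = NULL, param = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  node$param <- param
  class(node) <- "ad_node"
  if (!param && .tape$active && (length(parents) > 0L || !is.null(backward))) {
    n <- .tape$n + 1L
    if (n > length(.tape$nodes)) {
      .tape$nodes <- c(.tape$nodes, vector("list", length(.tape$nodes)))
    }
    .tape$nodes[[n]] <- node
    .tape$n <- n
  }
  node
}

ad_param <- function(value) new_node(value, param = TRUE)
ad_const <- function(value) new_node(value)

is_node <- function(x) inherits(x, "ad_node")
val <- function(x) if (is_node(x)) x$value else x

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse sweep from `loss` (a scalar node).  Gradients accumulate into
# every reachable node's $grad, including off-tape parameter nodes.
backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  n <- .tape$n
  nodes <- .tape$nodes
  for (i in rev(seq_len(n))) {
    node <- nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      gj <- gs[[j]]
      if (!is.null(gj)) acc_grad(ps[[j]], gj)
    }
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- primitive ops ---------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- val(a); bv <- val(b)
  new_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), crossprod(av, g))
  })
}

ad_add <- function(a, b) {
  new_node(val(a) + val(b), list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  new_node(val(a) - val(b), list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  av <- val(a); bv <- val(b)
  new_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# broadcast a column vector (one entry per row of `a`) across columns
ad_add_rowbias <- function(a, b) {
  av <- val(a); bv <- val(b)
  new_node(av + as.vector(bv), list(a, b), function(g) {
    list(g, matrix(rowSums(g), ncol = 1L))
  })
}

# broadcast a row vector (one entry per column of `a`) across rows
ad_add_colbias <- function(a, b) {
  av <- val(a); bv <- val(b)
  new_node(sweep(av, 2L, as.vector(bv), "+"), list(a, b), function(g) {
    list(g, matrix(colSums(g), nrow = 1L))
  })
}

ad_scale <- function(a, k) {
  new_node(val(a) * k, list(a), function(g) list(g * k))
}

# multiply a matrix node by a scalar node (1x1)
ad_scale_node <- function(a, s) {
  av <- val(a); sv <- as.numeric(val(s))
  new_node(av * sv, list(a, s), function(g) {
    list(g * sv, sum(g * av))
  })
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-val(a)))
  new_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(a) {
  y <- tanh(val(a))
  new_node(y, list(a), function(g) list(g * (1 - y * y)))
}

ad_relu <- function(a) {
  av <- val(a)
  y <- pmax(av, 0)
  m <- av > 0
  new_node(y, list(a), function(g) list(g * m))
}

ad_sum <- function(a) {
  av <- val(a)
  new_node(sum(av), list(a), function(g) {
    list(array(g, dim = dim(av)))
  })
}

ad_mean <- function(a) {
  av <- val(a); n <- length(av)
  new_node(sum(av) / n, list(a), function(g) {
    list(array(g / n, dim = dim(av)))
  })
}

ad_transpose <- function(a) {
  new_node(t(val(a)), list(a), function(g) list(t(g)))
}

# row-wise softmax (rows sum to one)
ad_softmax_rows <- function(a) {
  av <- val(a)
  z <- exp(av - apply(av, 1L, max))
  y <- z / rowSums(z)
  new_node(y, list(a), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

# row-wise layer normalization with per-feature gain/bias (row vectors)
ad_layernorm_rows <- function(a, gain, bias, eps = 1e-5) {
  av <- val(a); gv <- as.vector(val(gain)); bv <- as.vector(val(bias))
  d <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  v <- rowSums(xc * xc) / d
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  new_node(y, list(a, gain, bias), function(g) {
    gg <- matrix(colSums(g * xhat), nrow = 1L)
    gb <- matrix(colSums(g), nrow = 1L)
    gx <- sweep(g, 2L, gv, "*")
    ga <- inv * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat))
    list(ga, gg, gb)
  })
}

ad_concat_rows <- function(nodes) {
  vals <- lapply(nodes, val)
  nr <- vapply(vals, nrow, 0L)
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  new_node(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_concat_cols <- function(nodes) {
  vals <- lapply(nodes, val)
  nc <- vapply(vals, ncol, 0L)
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  new_node(do.call(cbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_slice_rows <- function(a, idx) {
  av <- val(a)
  new_node(av[idx, , drop = FALSE], list(a), function(g) {
    out <- array(0, dim = dim(av))
    out[idx, ] <- g
    list(out)
  })
}

ad_slice_cols <- function(a, idx) {
  av <- val(a)
  new_node(av[, idx, drop = FALSE], list(a), function(g) {
    out <- array(0, dim = dim(av))
    out[, idx] <- g
    list(out)
  })
}

# row i of a (tokens x d) matrix as a d x 1 column vector
ad_row_as_col <- function(a, i) {
  av <- val(a)
  new_node(matrix(av[i, ], ncol = 1L), list(a), function(g) {
    out <- array(0, dim = dim(av))
    out[i, ] <- as.vector(g)
    list(out)
  })
}

# column means of a matrix, returned as a column vector (length = ncol)
ad_colmeans_as_col <- function(a) {
  av <- val(a); nr <- nrow(av)
  new_node(matrix(colMeans(av), ncol = 1L), list(a), function(g) {
    list(matrix(rep(as.vector(g) / nr, each = nr), nrow = nr))
  })
}

ad_rowmeans_as_row <- function(a) {
  av <- val(a); nc <- ncol(av)
  new_node(matrix(rowMeans(av), nrow = 1L), list(a), function(g) {
    list(matrix(rep(as.vector(g) / nc, nc), ncol = nc))
  })
}

# add a scalar node (1x1) to every entry of a matrix node
ad_add_scalar_node <- function(a, s) {
  av <- val(a); sv <- as.numeric(val(s))
  new_node(av + sv, list(a, s), function(g) list(g, sum(g)))
}

# log(p / (1 - p)) with clamping away from {0, 1}
ad_logit <- function(a, eps = 1e-6) {
  av <- pmin(pmax(val(a), eps), 1 - eps)
  inside <- val(a) > eps & val(a) < 1 - eps
  new_node(log(av / (1 - av)), list(a), function(g) {
    list(g * inside / (av * (1 - av)))
  })
}

# ---- spatial ops (channels x H*W layout, row-major spatial order) ----------

# cached index plans for im2col and nearest upsampling
.plan_cache <- new.env(parent = emptyenv())

im2col_plan <- function(h, w, k, stride, pad) {
  key <- paste(h, w, k, stride, pad, sep = "_")
  p <- .plan_cache[[key]]
  if (!is.null(p)) return(p)
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  oy <- rep(seq_len(ho) - 1L, each = wo)
  ox <- rep(seq_len(wo) - 1L, times = ho)
  offsets <- vector("list", k * k)
  o <- 0L
  for (di in seq_len(k) - 1L) {
    for (dj in seq_len(k) - 1L) {
      o <- o + 1L
      sy <- oy * stride + di - pad
      sx <- ox * stride + dj - pad
      ok <- sy >= 0L & sy < h & sx >= 0L & sx < w
      idx <- ifelse(ok, sy * w + sx + 1L, NA_integer_)
      offsets[[o]] <- list(idx = idx, ok = ok)
    }
  }
  p <- list(ho = ho, wo = wo, k = k, offsets = offsets, hw = h * w)
  .plan_cache[[key]] <- p
  p
}

# x: (C x H*W) node -> (k*k*C x Ho*Wo) node of unrolled patches
ad_im2col <- function(x, h, w, k, stride, pad = (k - 1L) %/% 2L) {
  plan <- im2col_plan(h, w, k, stride, pad)
  xv <- val(x)
  cc <- nrow(xv)
  ncols <- plan$ho * plan$wo
  out <- matrix(0, nrow = k * k * cc, ncol = ncols)
  for (o in seq_along(plan$offsets)) {
    off <- plan$offsets[[o]]
    rows <- ((o - 1L) * cc + 1L):(o * cc)
    sel <- off$ok
    out[rows, sel] <- xv[, off$idx[sel], drop = FALSE]
  }
  new_node(out, list(x), function(g) {
    gx <- matrix(0, nrow = cc, ncol = plan$hw)
    for (o in seq_along(plan$offsets)) {
      off <- plan$offsets[[o]]
      rows <- ((o - 1L) * cc + 1L):(o * cc)
      sel <- off$ok
      # per offset the source map is injective for stride >= 1
      gx[, off$idx[sel]] <- gx[, off$idx[sel], drop = FALSE] +
        g[rows, sel, drop = FALSE]
    }
    list(gx)
  })
}

upsample_plan <- function(h, w) {
  key <- paste("up", h, w, sep = "_")
  p <- .plan_cache[[key]]
  if (!is.null(p)) return(p)
  oy <- rep(seq_len(2L * h) - 1L, each = 2L * w)
  ox <- rep(seq_len(2L * w) - 1L, times = 2L * h)
  src <- (oy %/% 2L) * w + (ox %/% 2L) + 1L
  p <- list(src = src, hw = h * w)
  .plan_cache[[key]] <- p
  p
}

# nearest-neighbour x2 upsampling of a (C x H*W) map
ad_upsample2 <- function(x, h, w) {
  plan <- upsample_plan(h, w)
  xv <- val(x)
  new_node(xv[, plan$src, drop = FALSE], list(x), function(g) {
    # rowsum orders groups by sort(unique); groups cover 1..h*w contiguously
    gx <- t(rowsum(t(g), group = plan$src))
    list(gx)
  })
}

# ---- fused losses ----------------------------------------------------------

# weighted binary cross-entropy with logits; z, targets, weights same shape.
# Loss = sum(w * (softplus(z) - t * z)) / sum(w)
ad_bce_logits <- function(z, targets, weights) {
  zv <- val(z); tv <- val(targets); wv <- val(weights)
  sw <- sum(wv)
  p <- 1 / (1 + exp(-zv))
  softplus <- ifelse(zv > 30, zv, log1p(exp(pmin(zv, 30))))
  loss <- sum(wv * (softplus - tv * zv)) / sw
  new_node(loss, list(z), function(g) {
    list(g * wv * (p - tv) / sw)
  })
}

# smooth-L1 (Huber, delta = 1) between pred and target, masked mean
ad_smooth_l1 <- function(pred, target, mask) {
  pv <- val(pred); tv <- val(target); mv <- val(mask)
  n <- max(sum(mv), 1)
  d <- pv - tv
  a <- abs(d)
  l <- ifelse(a < 1, 0.5 * d * d, a - 0.5)
  loss <- sum(mv * l) / n
  new_node(loss, list(pred), function(g) {
    gd <- ifelse(a < 1, d, sign(d))
    list(g * mv * gd / n)
  })
}

# cross-entropy of a single logit column vector (K x 1) against a class index
ad_cross_entropy <- function(logits, label) {
  zv <- as.vector(val(logits))
  z <- zv - max(zv)
  p <- exp(z) / sum(exp(z))
  loss <- -log(max(p[label], 1e-300))
  new_node(loss, list(logits), function(g) {
    gp <- p
    gp[label] <- gp[label] - 1
    list(matrix(g * gp, ncol = 1L))
  })
}

# ---- optimizer -------------------------------------------------------------

# Adam over a flat list of parameter nodes; state kept in each node.
adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) {
      p$m <- array(0, dim = dim(p$value))
      p$v <- array(0, dim = dim(p$value))
      p$t <- 0L
    }
    p$t <- p$t + 1L
    g <- p$grad
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^p$t)
    vhat <- p$v / (1 - beta2^p$t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

# collect all values / gradients into flat numeric vectors (testing aid)
params_flatten <- function(params, what = c("value", "grad")) {
  what <- match.arg(what)
  unlist(lapply(params, function(p) {
    x <- p[[what]]
    if (is.null(x)) rep(0, length(p$value)) else as.vector(x)
  }))
}
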