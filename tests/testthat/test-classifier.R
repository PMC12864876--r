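test_that("patch embedding produces T tokens with linear structure", {
  d <- 8L; p <- 8L
  W <- matrix(rnorm(p * p * 3 * d, 0, 0.1), p * p * 3, d)
  pos <- matrix(rnorm(16 * d), 16, d)
  crop <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  tok <- patch_embed(crop, p, W, pos = pos)
  expect_equal(dim(tok), c(16L, d))
  # zero image: tokens equal the positional encodings
  zero <- array(0, dim = c(32, 32, 3))
  expect_equal(patch_embed(zero, p, W, pos = pos), pos)
  # linear in pixel intensities once encodings are subtracted
  crop2 <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  lhs <- patch_embed(crop + crop2, p, W, pos = pos) - pos
  rhs <- (patch_embed(crop, p, W, pos = pos) - pos) +
    (patch_embed(crop2, p, W, pos = pos) - pos)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(patch_embed(crop, 5L, W), "divisible")
})

test_that("multi-head attention is row-stochastic and symmetric on identical tokens", {
  d <- 8L
  prm <- attention_params(d, seed = 2L)
  single <- matrix(rnorm(d), 1, d)
  out1 <- multi_head_attention(single, prm, n_heads = 2L)
  expect_equal(as.numeric(out1$attention), 1)
  expect_true(all(is.finite(out1$tokens)))

  same <- matrix(rep(rnorm(d), each = 5), 5, d)
  outs <- multi_head_attention(same, prm, n_heads = 2L)
  for (i in 2:5) expect_equal(outs$tokens[i, ], outs$tokens[1, ])

  set.seed(3)
  toks <- matrix(rnorm(6 * d), 6, d)
  a <- multi_head_attention(toks, prm, n_heads = 2L)$attention
  expect_equal(rowSums(a), rep(1, 6), tolerance = 1e-6)
  expect_error(multi_head_attention(toks, prm, n_heads = 3L), "divisible")
})

test_that("fusion reduces to stacked attention for one scale and ignores zero-weight scales", {
  d <- 8L
  p1 <- attention_params(d, seed = 4L)
  pf <- attention_params(d, seed = 5L)
  set.seed(6)
  X <- matrix(rnorm(4 * d), 4, d)
  fused <- multi_attention_fusion(list(X), list(p1), pf)
  expect_equal(fused$weights, 1)
  manual <- multi_head_attention(multi_head_attention(X, p1)$tokens, pf)
  expect_equal(fused$tokens, manual$tokens, tolerance = 1e-10)

  # a scale with (numerically) zero weight cannot influence the other
  # scale's output rows
  Y1 <- matrix(rnorm(3 * d), 3, d)
  Y2 <- matrix(rnorm(3 * d), 3, d)
  p2 <- attention_params(d, seed = 7L)
  f1 <- multi_attention_fusion(list(X, Y1), list(p1, p2), pf,
                               scale_logits = c(0, -1000))
  f2 <- multi_attention_fusion(list(X, Y2), list(p1, p2), pf,
                               scale_logits = c(0, -1000))
  expect_equal(sum(f1$weights), 1)
  expect_equal(f1$tokens[1:4, ], f2$tokens[1:4, ], tolerance = 1e-8)
  expect_equal(length(f1$significance), 7L)
  expect_error(multi_attention_fusion(list(X, matrix(0, 2, 4)),
                                      list(p1, p2), pf), "common dimension")
})

test_that("the zero-parameter LSTM step matches its closed form", {
  prm <- lstm_params(4L, 3L, init = "zero")
  st0 <- list(hidden = rep(0, 3), cell = c(1, -2, 0.5))
  st <- lstm_step(c(1, 2, 3, 4), st0, prm, significance = 0.5)
  expect_equal(st$gates$forget, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(st$gates$input, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(st$gates$output, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(st$gates$candidate, rep(0, 3), tolerance = 1e-12)
  expect_equal(st$cell, 0.5 * st0$cell, tolerance = 1e-12)
  expect_equal(st$hidden, 0.5 * tanh(0.5 * st0$cell), tolerance = 1e-12)
})

test_that("gate saturation preserves the cell and significance shifts the input gate monotonically", {
  prm <- lstm_params(2L, 2L, init = "zero")
  # forget pre-activation -> +inf, input gate -> 0: cell preserved exactly
  prm$forget$b <- matrix(100, 2, 1)
  prm$input$b <- matrix(-100, 2, 1)
  st0 <- list(hidden = c(0.3, -0.4), cell = c(0.7, -1.1))
  st <- lstm_step(c(0.5, -0.5), st0, prm)
  expect_equal(st$cell, st0$cell, tolerance = 1e-12)

  prm2 <- lstm_params(2L, 2L, init = "random", seed = 8L)
  hi <- lstm_step(c(0.5, -0.5), st0, prm2, significance = 0.9)
  lo <- lstm_step(c(0.5, -0.5), st0, prm2, significance = 0.1)
  expect_true(all(hi$gates$input > lo$gates$input))
  expect_error(lstm_step(c(NA, 1), st0, prm2), "non-finite")
})

test_that("gate ranges and the memory bound hold for random parameters", {
  set.seed(9)
  prm <- lstm_params(3L, 4L, init = "random", seed = 9L)
  st <- list(hidden = rep(0, 4), cell = rep(0, 4))
  for (s in 1:10) {
    st2 <- lstm_step(runif(3, -1, 1), st, prm, significance = runif(1))
    expect_true(all(st2$gates$forget > 0 & st2$gates$forget < 1))
    expect_true(all(st2$gates$input > 0 & st2$gates$input < 1))
    expect_true(all(st2$gates$output > 0 & st2$gates$output < 1))
    expect_true(all(st2$gates$candidate > -1 & st2$gates$candidate < 1))
    # |cell_s| <= |cell_0| + s elementwise when inputs are bounded by 1
    expect_true(all(abs(st2$cell) <= s + 1e-9))
    st <- st2
  }
})

test_that("at significance 0.5 the adaptive step equals a textbook LSTM step", {
  prm <- lstm_params(5L, 4L, init = "random", seed = 10L)
  st0 <- list(hidden = rnorm(4), cell = rnorm(4))
  x <- rnorm(5)
  mine <- lstm_step(x, st0, prm, significance = 0.5)
  ref <- reference_lstm_step(x, st0, prm)
  expect_equal(mine$hidden, ref$hidden, tolerance = 1e-10)
  expect_equal(mine$cell, ref$cell, tolerance = 1e-10)
})

test_that("classifier training is reproducible and yields a proper probability vector", {
  tc <- tiny_crops()
  cfg <- classifier_config(hidden_width = 8L, d = 8L, epochs = 2L,
                           seed = 3L)
  m1 <- train_classifier(tc$crops, tc$labels, cfg)
  expect_equal(nrow(m1$cost), 2L)
  m2 <- train_classifier(tc$crops, tc$labels, cfg)
  expect_identical(m1$cost, m2$cost)
  p <- classify(tc$crops[[1]], m1)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_length(p, 3L)
  expect_identical(which.max(p), which.max(classify(tc$crops[[1]], m1)))
  expect_error(train_classifier(tc$crops, rep(0L, length(tc$crops)), cfg),
               "two classes")
})
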