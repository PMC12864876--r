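# the autodiff engine backs every trainable module; each op's backward pass
# is checked against central-difference numeric gradients

tape_check <- function(build_loss, x, tol = 1e-5) {
  fn <- function(xv) {
    pestpyramid:::tape_reset()
    l <- build_loss(pestpyramid:::ad_param(xv))
    l$value
  }
  pestpyramid:::tape_reset()
  p <- pestpyramid:::ad_param(x)
  loss <- build_loss(p)
  pestpyramid:::backward(loss)
  ng <- numeric_grad(fn, x)
  max(abs(p$grad - ng)) / max(1, max(abs(ng)))
}

test_that("core matrix ops have correct gradients", {
  set.seed(42)
  ad <- asNamespace("pestpyramid")
  x <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(20), 4, 5)
  C1 <- matrix(rnorm(12), 3, 4)
  g1 <- matrix(rnorm(4), 1); b1 <- matrix(rnorm(4), 1)
  cases <- list(
    matmul = function(p) ad$ad_sum(ad$ad_matmul(p, ad$ad_const(W))),
    sigmoid = function(p) ad$ad_sum(ad$ad_sigmoid(p)),
    tanh_mul = function(p) ad$ad_sum(ad$ad_mul(ad$ad_tanh(p), p)),
    relu = function(p) ad$ad_sum(ad$ad_relu(p)),
    softmax = function(p) ad$ad_sum(ad$ad_mul(ad$ad_softmax_rows(p),
                                              ad$ad_const(C1))),
    layernorm = function(p) ad$ad_sum(ad$ad_mul(
      ad$ad_layernorm_rows(p, ad$ad_const(g1), ad$ad_const(b1)),
      ad$ad_const(C1))),
    transpose = function(p) ad$ad_sum(ad$ad_mul(ad$ad_transpose(p),
                                                ad$ad_const(t(C1)))),
    slices = function(p) ad$ad_sum(ad$ad_slice_cols(
      ad$ad_concat_cols(list(p, ad$ad_const(x))), 2:6)),
    row_col = function(p) ad$ad_sum(ad$ad_tanh(ad$ad_row_as_col(p, 2))),
    colmeans = function(p) ad$ad_sum(ad$ad_tanh(ad$ad_colmeans_as_col(p)))
  )
  for (nm in names(cases)) {
    expect_lt(tape_check(cases[[nm]], x), 1e-5, label = nm)
  }
})

test_that("spatial ops (im2col convolution, nearest upsampling) have correct gradients", {
  set.seed(7)
  ad <- asNamespace("pestpyramid")
  fm <- matrix(rnorm(3 * 16), 3, 16)  # 3 channels of a 4x4 map
  K1 <- matrix(rnorm(27 * 16), 27, 16)
  K2 <- matrix(rnorm(27 * 4), 27, 4)
  K3 <- matrix(rnorm(3 * 64), 3, 64)
  expect_lt(tape_check(function(p) ad$ad_sum(ad$ad_mul(
    ad$ad_im2col(p, 4, 4, 3, 1), ad$ad_const(K1))), fm), 1e-5)
  expect_lt(tape_check(function(p) ad$ad_sum(ad$ad_mul(
    ad$ad_im2col(p, 4, 4, 3, 2), ad$ad_const(K2))), fm), 1e-5)
  expect_lt(tape_check(function(p) ad$ad_sum(ad$ad_mul(
    ad$ad_upsample2(p, 4, 4), ad$ad_const(K3))), fm), 1e-5)
})

test_that("fused losses have correct gradients", {
  set.seed(9)
  ad <- asNamespace("pestpyramid")
  z <- matrix(rnorm(10), 2, 5)
  tg <- matrix(rbinom(10, 1, 0.5), 2, 5)
  wt <- matrix(runif(10, 0.5, 2), 2, 5)
  T1 <- matrix(rnorm(10), 2, 5)
  M1 <- matrix(rbinom(10, 1, 0.6), 2, 5)
  expect_lt(tape_check(function(p)
    ad$ad_bce_logits(p, ad$ad_const(tg), ad$ad_const(wt)), z), 1e-5)
  expect_lt(tape_check(function(p)
    ad$ad_smooth_l1(p, ad$ad_const(T1), ad$ad_const(M1)), 2 * z), 1e-5)
  expect_lt(tape_check(function(p) ad$ad_cross_entropy(p, 3L),
                       matrix(rnorm(5), ncol = 1)), 1e-5)
})
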