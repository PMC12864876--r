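test_that("the tuning objective follows 1/accuracy + 1/IoU with a penalty cap", {
  expect_equal(objective_jk(1, 1), 2)
  expect_equal(objective_jk(0.5, 0.5), 4)
  expect_equal(objective_jk(0.9672, 0.8), 1 / 0.9672 + 1 / 0.8)
  expect_equal(objective_jk(0, 0.5), 1e6)
  expect_equal(objective_jk(0.5, 1e-12), 1e6)
})

test_that("the fitness-driven random number matches hand arithmetic and its fixed point", {
  expect_equal(compute_h(2, 2, 2, 2), 0.5)
  expect_equal(compute_h(0.37, 0.37, 0.37, 0.37), 0.5)
  expect_equal(compute_h(2, 1, 4, 2.5), 4 / 18.5)
  expect_equal(compute_h(0, 0, 0, 1), 0.5)  # denominator guard
  set.seed(1)
  for (rep in 1:200) {
    f <- sort(runif(4, 0, 10))
    cur <- runif(1, f[1], f[4])
    den <- f[4]^2 + f[1] + cur^2 - mean(f)
    expected <- if (den <= 1e-12) 0.5 else cur^2 / den
    expect_equal(compute_h(cur, f[1], f[4], mean(f)), expected,
                 tolerance = 1e-12)
  }
})

test_that("the exploitation move collapses to the attractor in its degenerate cases", {
  sp <- search_space(rep(-5, 4), rep(5, 4))
  x <- c(1, 2, 3, 4)
  water <- c(0.5, 0.5, 0.5, 0.5)
  expect_equal(gboa_move(x, x, water, h = 0.7, sp), water)
  expect_equal(gboa_move(c(0, 0, 0, 0), c(1, 1, 1, 1), water, h = 0.25, sp),
               water, tolerance = 1e-12)
  expect_equal(gboa_move(c(0, 0, 0, 0), c(1, 1, 1, 1),
                         c(0, 0, 0, 0), h = 0, sp), c(1, 1, 1, 1))
  # clipping keeps every move in bounds
  set.seed(2)
  for (rep in 1:200) {
    p <- gboa_move(runif(4, -5, 5), runif(4, -5, 5), runif(4, -5, 5),
                   runif(1, -1, 1), sp, shrink = runif(1, 0, 2))
    expect_true(all(p >= sp$lower & p <= sp$upper))
  }
})

test_that("exploration resamples uniformly within bounds", {
  sp <- default_search_space()
  set.seed(3)
  draws <- t(replicate(2000, explore_move(rep(0, 4), sp)))
  expect_true(all(t(draws) >= sp$lower & t(draws) <= sp$upper))
  mid <- (sp$lower + sp$upper) / 2
  se <- (sp$upper - sp$lower) / sqrt(12 * nrow(draws))
  expect_true(all(abs(colMeans(draws) - mid) < 3 * se * 1.5))
})

test_that("optimization is elitist, reproducible, and variant-sensitive", {
  sphere <- function(x) sum(x^2)
  sp <- search_space(rep(-5, 4), rep(5, 4))
  o1 <- eigbo_optimize(sphere, sp, population = 8L, iterations = 15L,
                       variant = "eigbo_re", seed = 4L)
  expect_true(all(diff(o1$trace$best) <= 1e-12))
  expect_equal(nrow(o1$trace), 15L)
  o2 <- eigbo_optimize(sphere, sp, population = 8L, iterations = 15L,
                       variant = "eigbo_re", seed = 4L)
  expect_identical(o1$trace, o2$trace)
  o3 <- eigbo_optimize(sphere, sp, population = 8L, iterations = 15L,
                       variant = "gboa", seed = 4L)
  expect_false(identical(o1$trace$best, o3$trace$best))
  expect_true(all(o1$best$position >= sp$lower & o1$best$position <= sp$upper))
})

test_that("failing evaluations receive the penalty and the run continues", {
  flaky <- function(x) if (x[1] > 0) stop("boom") else sum(x^2)
  sp <- search_space(rep(-1, 2), rep(1, 2))
  o <- eigbo_optimize(flaky, sp, population = 6L, iterations = 5L, seed = 5L)
  expect_true(is.finite(o$best$fitness))
  expect_lte(o$best$fitness, 1e6)
})

test_that("integer genes are materialized by half-up rounding at evaluation", {
  sp <- default_search_space()
  seen <- new.env(); seen$vals <- list()
  probe <- function(g) { seen$vals[[length(seen$vals) + 1L]] <- g; sum(g) }
  eigbo_optimize(probe, sp, population = 4L, iterations = 2L, seed = 6L)
  for (v in seen$vals) {
    expect_equal(v[1], round(v[1]))
    expect_equal(v[3], round(v[3]))
    expect_true(v[2] >= 0.01 && v[2] <= 0.99)
  }
})
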