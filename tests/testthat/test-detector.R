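test_that("backbone produces the stride-4..32 shape contract", {
  model <- list(params = pestpyramid:::init_detector_params(8L, 0),
                trained = FALSE)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  maps <- backbone_forward(img, model)
  expect_equal(vapply(maps, function(m) dim(m)[1], 0), c(16, 8, 4, 2))
  expect_equal(vapply(maps, function(m) dim(m)[3], 0), rep(8, 4))
  expect_true(all(vapply(maps, function(m) all(is.finite(m)), TRUE)))
  # doubling hidden_width doubles channel counts
  model2 <- list(params = pestpyramid:::init_detector_params(16L, 0))
  maps2 <- backbone_forward(img, model2)
  expect_equal(dim(maps2[[1]])[3], 16)
  expect_error(backbone_forward(array(0, dim = c(48, 64, 3)), model),
               "divisible by 32")
})

test_that("pyramid merge implements upsample-and-add with its constant-map case", {
  coarse <- array(2, dim = c(1, 1, 1))
  fine <- array(3, dim = c(2, 2, 1))
  merged <- fpn_merge(list(fine, coarse))
  expect_equal(merged[[1]][, , 1], matrix(5, 2, 2))
  expect_equal(as.vector(merged[[2]]), 2)

  # nearest upsampling duplicates entries into 2x2 blocks
  up <- upsample_nearest2(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(up, matrix(c(1, 1, 3, 3, 1, 1, 3, 3,
                            2, 2, 4, 4, 2, 2, 4, 4), 4, 4))

  # with zero laterals on the fine level, the merged fine map is exactly the
  # upsampled chain of the top projection
  set.seed(3)
  c1 <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
  c2 <- array(rnorm(2 * 2 * 2), dim = c(2, 2, 2))
  lat0 <- matrix(0, 2, 2); latI <- diag(2)
  m <- fpn_merge(list(c1, c2), laterals = list(lat0, latI))
  manual <- apply(c2, 3, function(ch) upsample_nearest2(ch))
  expect_equal(as.vector(m[[1]]), as.vector(array(manual, dim = c(4, 4, 2))))
})

test_that("pyramid merge is linear in its inputs under linear laterals", {
  set.seed(5)
  mk <- function() list(array(rnorm(16 * 2), dim = c(4, 4, 2)),
                        array(rnorm(4 * 2), dim = c(2, 2, 2)))
  a <- mk(); b <- mk()
  lats <- list(matrix(rnorm(4), 2, 2), matrix(rnorm(4), 2, 2))
  ab <- lapply(1:2, function(i) a[[i]] + b[[i]])
  ma <- fpn_merge(a, lats); mb <- fpn_merge(b, lats)
  mab <- fpn_merge(ab, lats)
  for (l in 1:2) expect_equal(mab[[l]], ma[[l]] + mb[[l]], tolerance = 1e-12)
})

test_that("adaptive gates scale levels through a sigmoid", {
  pyr <- list(array(1, dim = c(2, 2, 1)), array(2, dim = c(1, 1, 1)))
  g0 <- adaup_fuse(pyr, c(0, 0))
  expect_equal(g0[[1]], pyr[[1]] * 0.5)
  expect_equal(g0[[2]], pyr[[2]] * 0.5)
  gbig <- adaup_fuse(pyr, c(100, 100))
  expect_equal(gbig[[1]], pyr[[1]], tolerance = 1e-12)
  gneg <- adaup_fuse(pyr, c(-10, -10))
  expect_lt(sqrt(sum(gneg[[1]]^2)) / sqrt(sum(pyr[[1]]^2)), 1e-4)
  expect_error(adaup_fuse(pyr, 0), "one gate per")
})

test_that("cell decode inverts encode and zero offsets give a stride-sized box", {
  b0 <- decode_cell(c(0, 0, 0, 0), stride = 8, i = 2, j = 3)
  expect_equal(b0, c(28 - 4, 20 - 4, 28 + 4, 20 + 4))
  set.seed(6)
  for (rep in 1:20) {
    box <- c(x <- runif(1, 0, 40), y <- runif(1, 0, 40),
             x + runif(1, 2, 20), y + runif(1, 2, 20))
    s <- sample(c(4, 8, 16, 32), 1)
    i <- sample(0:5, 1); j <- sample(0:5, 1)
    expect_equal(decode_cell(encode_cell(box, s, i, j), s, i, j), box,
                 tolerance = 1e-10)
  }
})

test_that("detector training decreases cost, is reproducible, and flags untrained models", {
  split <- tiny_split()
  cfg <- detector_config(hidden_width = 8L, epochs = 3L, seed = 2L)
  det <- train_detector(split, cfg)
  expect_equal(nrow(det$cost), 3L)
  expect_lt(det$cost$cost[3], det$cost$cost[1])
  det2 <- train_detector(split, cfg)
  expect_identical(det$cost, det2$cost)

  fake <- det; fake$trained <- FALSE
  expect_error(detect(split$test[[1]]$image, fake), "train_detector")

  d <- detect(split$test[[1]]$image, det, score_threshold = 0.3)
  if (nrow(d) > 1L) expect_true(all(diff(d$score) <= 0))
  expect_true(all(d$x_min >= 0 & d$x_max <= 32))
})

test_that("non-maximum suppression collapses duplicate detections", {
  det <- tibble::tibble(x_min = c(0, 0.5, 20), y_min = c(0, 0.5, 20),
                        x_max = c(10, 10.5, 30), y_max = c(10, 10.5, 30),
                        score = c(0.9, 0.8, 0.7))
  kept <- pestpyramid:::nms_boxes(det, 0.5)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$score, c(0.9, 0.7))
})
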