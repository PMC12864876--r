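test_that("scene generation is deterministic and respects the zero-pest case", {
  cfg <- tiny_scene_cfg(seed = 3L)
  a <- generate_scene(cfg, 5L)
  b <- generate_scene(cfg, 5L)
  expect_identical(a$image, b$image)
  expect_identical(a$annotations, b$annotations)
  other <- generate_scene(cfg, 6L)
  expect_false(identical(a$image, other$image))

  empty_cfg <- scene_config(pests_per_image = c(0L, 0L), seed = 1L)
  sc <- generate_scene(empty_cfg, 0L)
  expect_equal(nrow(sc$annotations), 0L)
})

test_that("generated scenes satisfy image and annotation invariants", {
  cfg <- scene_config(seed = 5L)
  for (i in 0:4) {
    sc <- generate_scene(cfg, i)
    expect_true(all(sc$image >= 0 & sc$image <= 1))
    a <- sc$annotations
    expect_true(all(a$x_min < a$x_max))
    expect_true(all(a$y_min < a$y_max))
    expect_true(all(a$x_min >= 0 & a$x_max <= cfg$image_width))
    expect_true(all(a$y_min >= 0 & a$y_max <= cfg$image_height))
    expect_true(all(a$class_id >= 0 & a$class_id < cfg$n_classes))
  }
})

test_that("pests are placed without mutual overlap when space permits", {
  cfg <- scene_config(image_height = 96L, image_width = 96L,
                      pests_per_image = c(3L, 3L), pest_scale = c(10L, 16L),
                      seed = 2L)
  sc <- generate_scene(cfg, 1L)
  expect_equal(nrow(sc$annotations), 3L)
  a <- sc$annotations
  # brute-force pairwise intersection area
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in (i + 1L):nrow(a)) {
      iw <- max(0, min(a$x_max[i], a$x_max[j]) - max(a$x_min[i], a$x_min[j]))
      ih <- max(0, min(a$y_max[i], a$y_max[j]) - max(a$y_min[i], a$y_min[j]))
      expect_equal(iw * ih, 0)
    }
  }
})

test_that("split arithmetic uses floor(train_fraction * n) and conserves totals", {
  s <- split_indices(2700L, 0.75)
  expect_length(s$train, 2025L)
  expect_length(s$test, 675L)
  s2 <- split_indices(4395L, 0.75)
  expect_length(s2$train, 3296L)
  expect_length(s2$test, 1099L)
  s3 <- split_indices(4L, 0.75)
  expect_length(s3$train, 3L)
  expect_length(s3$test, 1L)
  expect_setequal(c(s3$train, s3$test), 0:3)
  expect_length(intersect(s3$train, s3$test), 0L)
  expect_error(split_indices(10L, 1.2), "train_fraction")
})

test_that("dataset write/read round-trips annotations exactly", {
  dir <- withr::local_tempdir()
  split <- tiny_split()
  man <- write_dataset(split, dir)
  expect_equal(sum(man$summary$n_images), 16L)
  expect_equal(man$summary$n_images[man$summary$split == "train"], 12L)
  back <- read_dataset(dir)
  expect_length(back$train, length(split$train))
  expect_length(back$test, length(split$test))
  for (i in seq_along(split$train)) {
    expect_equal(back$train[[i]]$annotations, split$train[[i]]$annotations)
  }
  # images survive 8-bit PNG quantization to within half a level
  expect_lt(max(abs(back$train[[1]]$image - split$train[[1]]$image)),
            1 / 255)
})

test_that("an empty split writes a valid schema and malformed records are caught", {
  dir <- withr::local_tempdir()
  cfg <- scene_config(pests_per_image = c(0L, 0L), seed = 1L)
  split <- generate_dataset(cfg, 3L, 0.67)
  write_dataset(split, dir)
  js <- jsonlite::read_json(file.path(dir, "train.json"))
  expect_length(js$annotations, 0L)
  expect_length(js$images, 2L)
  back <- read_dataset(dir)
  expect_equal(nrow(back$train[[1]]$annotations), 0L)

  # corrupt one record: bbox with wrong arity must be reported by index
  js2 <- jsonlite::read_json(file.path(dir, "test.json"))
  js2$annotations <- list(list(id = 1, image_id = js2$images[[1]]$id,
                               bbox = list(1, 2, 3), category_id = 0))
  jsonlite::write_json(js2, file.path(dir, "test.json"), auto_unbox = TRUE)
  expect_error(read_dataset(dir), "malformed annotation record 1")
})

test_that("classes are separable by a pixel-mean nearest-centroid rule", {
  cfg <- scene_config(pests_per_image = c(1L, 1L), seed = 9L)
  crops <- list(); labels <- integer(0)
  for (i in 0:59) {
    sc <- generate_scene(cfg, i)
    a <- sc$annotations
    if (nrow(a) == 0L) next
    crops[[length(crops) + 1L]] <- crop_detection(
      sc$image, c(a$x_min[1], a$y_min[1], a$x_max[1], a$y_max[1]))
    labels <- c(labels, a$class_id[1])
  }
  feats <- t(vapply(crops, function(cr) apply(cr, 3, mean), numeric(3)))
  train <- seq_len(40)
  cents <- t(vapply(0:2, function(k)
    colMeans(feats[train, , drop = FALSE][labels[train] == k, , drop = FALSE]),
    numeric(3)))
  test <- setdiff(seq_along(labels), train)
  pred <- vapply(test, function(i)
    which.min(colSums((t(cents) - feats[i, ])^2)) - 1L, 0L)
  expect_gt(mean(pred == labels[test]), 1 / 3)
})
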