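# Synthetic pest-scene generation and annotation I/O.
#
# Scenes emulate field images collected by IoT camera nodes: a low-frequency
# green/brown vegetation background with optional clutter, containing a
# variable number of pest-like textured blobs at variable scale.  Class
# identity is encoded by hue and texture family (stripes / spots / rings) so
# that classes are statistically separable and learnable by small models.
# Boxes are 0-based, half-open pixel rectangles [x_min, x_max) x [y_min, y_max).

#' Configuration for the synthetic pest-scene generator
#'
#' The defaults define the package's standard desk-scale study condition:
#' 64 x 64 RGB scenes with 3 pest classes, 1-3 pests per scene at 10-24 px
#' diameter, moderate background clutter and light sensor noise.
#'
#' @param image_height,image_width Scene size in pixels.
#' @param n_classes Number of pest classes (>= 1).
#' @param pests_per_image Inclusive integer range `c(min, max)` of pests
#'   placed per scene.
#' @param pest_scale Inclusive pixel range `c(min, max)` of pest diameter;
#'   minimum 4 px, maximum at most half the shorter image side.
#' @param background_complexity Real in `[0, 1]` controlling texture clutter.
#' @param noise_sigma Standard deviation of additive Gaussian sensor noise on
#'   the `[0, 1]` intensity scale.
#' @param seed Non-negative integer; together with the scene index this fully
#'   determines every generated scene.
#' @return A validated `scene_config` object (a list).
#' @export
#' @examples
#' cfg <- scene_config(n_classes = 3, seed = 7)
#' sc <- generate_scene(cfg, index = 0)
#' dim(sc$image)
scene_config <- function(image_height = 64L, image_width = 64L,
                         n_classes = 3L, pests_per_image = c(1L, 3L),
                         pest_scale = c(10L, 24L),
                         background_complexity = 0.5,
                         noise_sigma = 0.02, seed = 1L) {
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_classes = as.integer(n_classes),
    pests_per_image = as.integer(pests_per_image),
    pest_scale = as.integer(pest_scale),
    background_complexity = as.numeric(background_complexity),
    noise_sigma = as.numeric(noise_sigma),
    seed = as.integer(seed)
  )
  if (cfg$image_height < 8L || cfg$image_width < 8L)
    stop("image dimensions must be at least 8 px", call. = FALSE)
  if (cfg$n_classes < 1L) stop("n_classes must be >= 1", call. = FALSE)
  if (length(cfg$pests_per_image) != 2L || cfg$pests_per_image[1] < 0L ||
      cfg$pests_per_image[1] > cfg$pests_per_image[2])
    stop("pests_per_image must be an ordered range c(min, max), min >= 0",
         call. = FALSE)
  if (length(cfg$pest_scale) != 2L || cfg$pest_scale[1] < 4L ||
      cfg$pest_scale[1] > cfg$pest_scale[2])
    stop("pest_scale must be an ordered range with min >= 4 px", call. = FALSE)
  if (cfg$pest_scale[2] > min(cfg$image_height, cfg$image_width) / 2)
    stop("pest_scale max must be <= half the shorter image side", call. = FALSE)
  if (cfg$background_complexity < 0 || cfg$background_complexity > 1)
    stop("background_complexity must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (cfg$seed < 0L) stop("seed must be non-negative", call. = FALSE)
  structure(cfg, class = "scene_config")
}

# deterministic per-scene seed; injective for seed < 2^15, index < 2^16
scene_seed <- function(seed, index) {
  (seed %% 32768L) * 65536L + (index %% 65536L)
}

# bilinear upsampling of a coarse grid to h x w
bilinear_grid <- function(m, h, w) {
  gh <- nrow(m); gw <- ncol(m)
  ys <- seq(1, gh, length.out = h)
  xs <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ys), gh - 1L); fy <- ys - y0
  x0 <- pmin(floor(xs), gw - 1L); fx <- xs - x0
  a <- m[cbind(rep(y0, times = w), rep(x0, each = h))]
  b <- m[cbind(rep(y0, times = w), rep(x0 + 1L, each = h))]
  cc <- m[cbind(rep(y0 + 1L, times = w), rep(x0, each = h))]
  d <- m[cbind(rep(y0 + 1L, times = w), rep(x0 + 1L, each = h))]
  fyv <- rep(fy, times = w); fxv <- rep(fx, each = h)
  matrix(a * (1 - fyv) * (1 - fxv) + b * (1 - fyv) * fxv +
           cc * fyv * (1 - fxv) + d * fyv * fxv, nrow = h)
}

# class appearance: hue avoids the green background band; texture family
# cycles through stripes / spots / rings
class_style <- function(class_id, n_classes) {
  hue <- (0.55 + 0.8 * class_id / n_classes) %% 1
  list(hue = hue, family = class_id %% 3L)
}

render_pest <- function(image, x0, y0, d, class_id, n_classes, phase) {
  sty <- class_style(class_id, n_classes)
  u <- matrix(rep(seq(-1, 1, length.out = d), each = d), nrow = d)  # x coord
  v <- matrix(rep(seq(-1, 1, length.out = d), times = d), nrow = d) # y coord
  r <- sqrt(u^2 + v^2)
  modul <- switch(as.character(sty$family),
    "0" = 0.5 + 0.45 * sin(2 * pi * 2.5 * u + phase),
    "1" = ifelse(sin(pi * 3 * u + phase) * sin(pi * 3 * v) > 0.25, 0.95, 0.25),
    "2" = 0.5 + 0.45 * cos(2 * pi * 2.5 * r + phase))
  vval <- 0.35 + 0.6 * pmin(pmax(modul, 0), 1)
  vval[r > 0.78 & r <= 0.95] <- 0.08  # dark outline: a strong edge cue
  cols <- grDevices::col2rgb(grDevices::hsv(sty$hue, 0.85, as.vector(vval))) / 255
  alpha <- pmin(pmax((0.97 - r) / 0.08, 0), 1)  # soft elliptical mask
  ys <- (y0 + 1L):(y0 + d); xs <- (x0 + 1L):(x0 + d)
  for (ch in 1:3) {
    patch <- matrix(cols[ch, ], nrow = d)
    image[ys, xs, ch] <- (1 - alpha) * image[ys, xs, ch] + alpha * patch
  }
  image
}

#' Generate one synthetic pest scene
#'
#' Fully determined by `(config$seed, index)`: the same pair always yields a
#' bit-identical image and annotation table.  Pests are placed by rejection
#' sampling without mutual box overlap; if the canvas cannot host another
#' pest after a bounded number of attempts the scene degrades gracefully to
#' fewer pests.
#'
#' @param config A [scene_config()].
#' @param index Non-negative scene index.
#' @return A `pest_scene`: list with `image` (height x width x 3 array of
#'   reals in `[0, 1]`), `annotations` (tibble with `x_min`, `y_min`,
#'   `x_max`, `y_max`, `class_id`; 0-based half-open boxes), `index`.
#' @export
generate_scene <- function(config, index) {
  stopifnot(inherits(config, "scene_config"))
  if (index < 0) stop("index must be >= 0", call. = FALSE)
  h <- config$image_height; w <- config$image_width
  withr::with_seed(scene_seed(config$seed, index), {
    # vegetation background: smooth green/brown field plus fine clutter
    cx <- config$background_complexity
    coarse <- matrix(stats::runif(49), 7, 7)
    field <- bilinear_grid(coarse, h, w)
    green <- c(0.28, 0.42, 0.20); brown <- c(0.43, 0.35, 0.22)
    image <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      image[, , ch] <- green[ch] * (1 - cx * field) + brown[ch] * cx * field
    }
    if (cx > 0) {
      clutter <- matrix(stats::runif(h * w, -1, 1), h, w) * 0.06 * cx
      smallg <- bilinear_grid(matrix(stats::runif(14 * 14), 14, 14), h, w)
      for (ch in 1:3) {
        image[, , ch] <- image[, , ch] + clutter + 0.08 * cx * (smallg - 0.5)
      }
    }
    # pests
    kmin <- config$pests_per_image[1]; kmax <- config$pests_per_image[2]
    k <- kmin + sample.int(kmax - kmin + 1L, 1L) - 1L
    boxes <- matrix(integer(0), ncol = 4L)
    classes <- integer(0)
    placed <- 0L
    if (k > 0L) {
      for (p in seq_len(k)) {
        d <- config$pest_scale[1] +
          sample.int(config$pest_scale[2] - config$pest_scale[1] + 1L, 1L) - 1L
        cls <- sample.int(config$n_classes, 1L) - 1L
        phase <- stats::runif(1, 0, 2 * pi)
        ok <- FALSE
        for (attempt in 1:60) {
          x0 <- sample.int(w - d + 1L, 1L) - 1L
          y0 <- sample.int(h - d + 1L, 1L) - 1L
          cand <- c(x0, y0, x0 + d, y0 + d)
          if (nrow(boxes) == 0L ||
              all(apply(boxes, 1L, function(b) {
                max(0, min(b[3], cand[3]) - max(b[1], cand[1])) *
                  max(0, min(b[4], cand[4]) - max(b[2], cand[2])) == 0
              }))) {
            ok <- TRUE
            break
          }
        }
        if (!ok) next  # degrade to fewer pests
        image <- render_pest(image, x0, y0, d, cls, config$n_classes, phase)
        boxes <- rbind(boxes, cand)
        classes <- c(classes, cls)
        placed <- placed + 1L
      }
    }
    if (config$noise_sigma > 0) {
      image <- image + array(stats::rnorm(h * w * 3, 0, config$noise_sigma),
                             dim = c(h, w, 3))
    }
    image <- pmin(pmax(image, 0), 1)
    ann <- tibble::tibble(
      x_min = as.integer(if (placed) boxes[, 1] else integer(0)),
      y_min = as.integer(if (placed) boxes[, 2] else integer(0)),
      x_max = as.integer(if (placed) boxes[, 3] else integer(0)),
      y_max = as.integer(if (placed) boxes[, 4] else integer(0)),
      class_id = classes
    )
    structure(list(image = image, annotations = ann, index = as.integer(index)),
              class = "pest_scene")
  })
}

#' Deterministic train/test index assignment
#'
#' The train split receives `floor(train_fraction * n_total)` scenes; the
#' remainder is the test split.  Assignment is sequential by scene index
#' unless `shuffle = TRUE`, in which case a seed-controlled permutation is
#' applied first.
#'
#' @param n_total Total number of scenes (>= 2).
#' @param train_fraction Real in `(0, 1)`.
#' @param shuffle Permute indices before splitting?
#' @param seed Seed for the optional shuffle.
#' @return List with integer vectors `train` and `test` of 0-based indices.
#' @export
#' @examples
#' lengths(split_indices(2700, 0.75))  # 2025 train, 675 test
split_indices <- function(n_total, train_fraction = 0.75, shuffle = FALSE,
                          seed = 1L) {
  if (n_total < 2L) stop("n_total must be >= 2", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly inside (0, 1)", call. = FALSE)
  idx <- seq_len(n_total) - 1L
  if (shuffle) idx <- withr::with_seed(seed, sample(idx))
  n_train <- floor(train_fraction * n_total)
  list(train = idx[seq_len(n_train)], test = idx[-seq_len(n_train)])
}

#' Generate a full train/test dataset of synthetic scenes
#'
#' @inheritParams split_indices
#' @param config A [scene_config()].
#' @return A `scene_split`: list with `train` and `test` lists of
#'   `pest_scene` objects, plus the index assignment in `indices`.
#' @export
generate_dataset <- function(config, n_total, train_fraction = 0.75,
                             shuffle = FALSE) {
  stopifnot(inherits(config, "scene_config"))
  idx <- split_indices(n_total, train_fraction, shuffle, config$seed)
  structure(list(
    train = lapply(idx$train, function(i) generate_scene(config, i)),
    test = lapply(idx$test, function(i) generate_scene(config, i)),
    indices = idx
  ), class = "scene_split")
}

scene_file_name <- function(index) sprintf("scene_%05d.png", index)

coco_json <- function(scenes, n_classes) {
  images <- lapply(scenes, function(sc) list(
    id = sc$index,
    file_name = scene_file_name(sc$index),
    height = dim(sc$image)[1],
    width = dim(sc$image)[2]
  ))
  anns <- list()
  aid <- 0L
  for (sc in scenes) {
    a <- sc$annotations
    for (r in seq_len(nrow(a))) {
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = sc$index,
        bbox = c(a$x_min[r], a$y_min[r],
                 a$x_max[r] - a$x_min[r], a$y_max[r] - a$y_min[r]),
        category_id = a$class_id[r]
      )
    }
  }
  cats <- lapply(seq_len(n_classes) - 1L,
                 function(k) list(id = k, name = paste0("pest_", k)))
  list(images = images, annotations = anns, categories = cats)
}

annotations_csv <- function(scenes) {
  rows <- lapply(scenes, function(sc) {
    a <- sc$annotations
    if (nrow(a) == 0L) return(NULL)
    dplyr::mutate(a, image = scene_file_name(sc$index), .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(image = character(0), x_min = integer(0),
                          y_min = integer(0), x_max = integer(0),
                          y_max = integer(0), class_id = integer(0))
  }
  out
}

#' Write a scene split to disk (PNG + COCO JSON + CSV mirror)
#'
#' Images are written as PNG under `images/<split>/`; annotations as one
#' COCO-style JSON per split (boxes stored as `x, y, width, height`) and a
#' flat CSV mirror with box corners.
#'
#' @param split A `scene_split` from [generate_dataset()].
#' @param directory Output directory (created if needed).
#' @return A manifest: list of tibbles `summary` (per-split image and
#'   annotation counts) and `classes` (per-split, per-class counts).
#' @export
write_dataset <- function(split, directory) {
  stopifnot(inherits(split, "scene_split"))
  n_classes <- max(c(0L, unlist(lapply(c(split$train, split$test),
                                       function(s) s$annotations$class_id)))) + 1L
  for (part in c("train", "test")) {
    img_dir <- file.path(directory, "images", part)
    if (!dir.create(img_dir, recursive = TRUE, showWarnings = FALSE) &&
        !dir.exists(img_dir))
      stop("cannot create directory: ", img_dir, call. = FALSE)
    for (sc in split[[part]]) {
      png::writePNG(sc$image, file.path(img_dir, scene_file_name(sc$index)))
    }
    jsonlite::write_json(coco_json(split[[part]], n_classes),
                         file.path(directory, paste0(part, ".json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(annotations_csv(split[[part]]),
                     file.path(directory, paste0("annotations_", part, ".csv")),
                     row.names = FALSE)
  }
  manifest(split)
}

manifest <- function(split) {
  per <- function(part) {
    scenes <- split[[part]]
    anns <- dplyr::bind_rows(lapply(scenes, function(s) s$annotations))
    list(
      summary = tibble::tibble(split = part, n_images = length(scenes),
                               n_annotations = nrow(anns)),
      classes = if (nrow(anns)) dplyr::count(anns, .data$class_id) |>
        dplyr::mutate(split = part, .before = 1L)
      else tibble::tibble(split = character(0), class_id = integer(0),
                          n = integer(0))
    )
  }
  tr <- per("train"); te <- per("test")
  list(summary = dplyr::bind_rows(tr$summary, te$summary),
       classes = dplyr::bind_rows(tr$classes, te$classes))
}

read_coco_part <- function(directory, part) {
  path <- file.path(directory, paste0(part, ".json"))
  if (!file.exists(path)) stop("missing annotation file: ", path, call. = FALSE)
  js <- jsonlite::read_json(path)
  scenes <- list()
  ann_by_img <- list()
  for (i in seq_along(js$annotations)) {
    a <- js$annotations[[i]]
    if (is.null(a$image_id) || is.null(a$bbox) || length(a$bbox) != 4L ||
        is.null(a$category_id))
      stop(sprintf("malformed annotation record %d in %s", i, path),
           call. = FALSE)
    key <- as.character(a$image_id)
    bb <- as.numeric(unlist(a$bbox))
    if (bb[3] <= 0 || bb[4] <= 0)
      stop(sprintf("malformed annotation record %d in %s: non-positive box",
                   i, path), call. = FALSE)
    ann_by_img[[key]] <- rbind(ann_by_img[[key]],
                               c(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4],
                                 as.numeric(a$category_id)))
  }
  for (im in js$images) {
    if (is.null(im$id) || is.null(im$file_name))
      stop("malformed image record in ", path, call. = FALSE)
    img_path <- file.path(directory, "images", part, im$file_name)
    if (!file.exists(img_path)) stop("missing image file: ", img_path,
                                     call. = FALSE)
    img <- png::readPNG(img_path)
    m <- ann_by_img[[as.character(im$id)]]
    ann <- if (is.null(m)) {
      tibble::tibble(x_min = integer(0), y_min = integer(0),
                     x_max = integer(0), y_max = integer(0),
                     class_id = integer(0))
    } else {
      tibble::tibble(x_min = as.integer(m[, 1]), y_min = as.integer(m[, 2]),
                     x_max = as.integer(m[, 3]), y_max = as.integer(m[, 4]),
                     class_id = as.integer(m[, 5]))
    }
    scenes[[length(scenes) + 1L]] <-
      structure(list(image = img, annotations = ann,
                     index = as.integer(im$id)), class = "pest_scene")
  }
  scenes
}

#' Read a dataset written by [write_dataset()]
#'
#' Inverse of [write_dataset()] on its own output; also accepts any external
#' image folder laid out in the same COCO-style schema.
#'
#' @param directory Dataset directory.
#' @return A `scene_split`.
#' @export
read_dataset <- function(directory) {
  tr <- read_coco_part(directory, "train")
  te <- read_coco_part(directory, "test")
  structure(list(train = tr, test = te,
                 indices = list(train = vapply(tr, `[[`, 0L, "index"),
                                test = vapply(te, `[[`, 0L, "index"))),
            class = "scene_split")
}

#' @export
print.pest_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<pest_scene #%d> %dx%d px, %d annotation(s)\n",
              x$index, d[2], d[1], nrow(x$annotations)))
  invisible(x)
}

#' @export
print.scene_split <- function(x, ...) {
  cat(sprintf("<scene_split> %d train / %d test scenes\n",
              length(x$train), length(x$test)))
  invisible(x)
}
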