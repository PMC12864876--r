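# Population-based hyperparameter optimization: the gooseneck-barnacle
# exploitation move (an inter-member distance times cos(2*pi*h) pulled
# toward the best region found so far), either with the classical uniform
# random number h on (-1, 1) ("gboa") or with h replaced by the
# fitness-ratio expression Currentfit^2 / (Worstfit^2 + Bestfit +
# Currentfit^2 - Meanfit) ("eigbo_re").  Minimizes 1/accuracy + 1/IoU over
# the 4-gene space (FPN width, FPN rate, LSTM width, LSTM rate).

#' Default 4-gene search space
#'
#' Hidden widths are integers in `[5, 255]`; learning-rate genes reals in
#' `[0.01, 0.99]`.
#'
#' @return Tibble with columns `name`, `kind`, `lower`, `upper`.
#' @export
default_search_space <- function() {
  tibble::tibble(
    name = c("fpn_hidden", "fpn_lr", "lstm_hidden", "lstm_lr"),
    kind = c("integer", "real", "integer", "real"),
    lower = c(5, 0.01, 5, 0.01),
    upper = c(255, 0.99, 255, 0.99)
  )
}

#' Generic box search space
#'
#' @param lower,upper Numeric bound vectors.
#' @param kind Character vector, `"real"` or `"integer"` per gene.
#' @param name Optional gene names.
#' @export
search_space <- function(lower, upper, kind = rep("real", length(lower)),
                         name = paste0("g", seq_along(lower))) {
  if (any(lower >= upper)) stop("need lower < upper per gene", call. = FALSE)
  tibble::tibble(name = name, kind = kind, lower = as.numeric(lower),
                 upper = as.numeric(upper))
}

#' Tuning objective: 1/accuracy + 1/IoU
#'
#' Minimized over the gene space; degenerate inputs (either term at or
#' below `1e-9`) return the penalty cap `1e6`.
#'
#' @param accuracy,iou Reals in `[0, 1]`.
#' @export
#' @examples
#' objective_jk(0.5, 0.5)  # 4
objective_jk <- function(accuracy, iou) {
  if (!is.finite(accuracy) || !is.finite(iou) || accuracy <= 1e-9 ||
      iou <= 1e-9) return(1e6)
  1 / accuracy + 1 / iou
}

#' Fitness-driven random number
#'
#' `h = current^2 / (worst^2 + best + current^2 - mean)`.  When every
#' fitness in the population is equal this reduces exactly to 0.5, which is
#' also the fallback when the denominator underflows (at or below `1e-12`).
#'
#' @param current,best,worst,mean Finite non-negative fitness values.
#' @export
#' @examples
#' compute_h(2, 2, 2, 2)          # 0.5
#' compute_h(2, 1, 4, 2.5)        # 4 / 18.5
compute_h <- function(current, best, worst, mean) {
  # the all-equal algebraic fixed point is returned exactly, avoiding the
  # catastrophic cancellation of worst^2 + best - mean for extreme scales
  if (current == best && best == worst && worst == mean && current > 0)
    return(0.5)
  den <- worst^2 + best + current^2 - mean
  if (!is.finite(den) || den <= 1e-12) return(0.5)
  current^2 / den
}

clip_to_space <- function(x, space) {
  pmin(pmax(x, space$lower), space$upper)
}

# integer genes are materialized by half-up rounding at evaluation only
materialize <- function(x, space) {
  ifelse(space$kind == "integer", floor(x + 0.5), x)
}

#' Barnacle exploitation move
#'
#' `new = s * shrink * cos(2 pi h) + water` componentwise, where
#' `s = x_j - x_i` is the signed inter-parent difference, `water` the best
#' region found so far and `shrink` an annealing coefficient (the optimizer
#' passes `shrink_base^iteration`, tightening the search around the
#' attractor as the run progresses); the result is clipped to the bounds.
#' The signed difference keeps candidate placement symmetric around the
#' attractor, which the absolute distance would bias to one side.
#'
#' @param x_i,x_j Parent positions.
#' @param water Attractor position (global best).
#' @param h Random number (uniform on `(-1, 1)` for the classical variant,
#'   [compute_h()] for the fitness-driven one).
#' @param space Search space tibble.
#' @param shrink Scale coefficient (default 1 = no annealing).
#' @export
gboa_move <- function(x_i, x_j, water, h, space, shrink = 1) {
  s <- x_j - x_i
  clip_to_space(s * shrink * cos(2 * pi * h) + water, space)
}

#' Uniform exploration move
#'
#' Resamples every gene uniformly within its bounds (uses the current RNG
#' stream).
#'
#' @param x Current position (ignored apart from its length).
#' @param space Search space tibble.
#' @export
explore_move <- function(x, space) {
  stats::runif(nrow(space), space$lower, space$upper)
}

#' Population metaheuristic over a box search space
#'
#' Per iteration: all members are evaluated, the population fitness summary
#' (current/best/worst/mean) is formed, and each member either explores
#' (uniform resample, probability decaying linearly over iterations) or
#' performs the exploitation move [gboa_move()] paired with a random
#' distinct member and attracted to the global best.  The `eigbo_re`
#' variant draws `h` from [compute_h()] using the member's own fitness as
#' the current fitness; the `gboa` variant draws `h ~ U(-1, 1)`.  Elitism
#' preserves the best candidate verbatim, so the best-fitness trace is
#' non-increasing.  Fully seed-deterministic; an evaluation error assigns
#' the penalty `1e6` and the run continues.
#'
#' @param eval_fn Function position-vector -> fitness (minimized); integer
#'   genes arrive rounded.
#' @param space Search space tibble ([default_search_space()] by default).
#' @param population Population size (>= 2); the reference protocol uses 10.
#' @param iterations Update iterations; the reference protocol uses 50.
#' @param variant `"eigbo_re"` or `"gboa"`.
#' @param explore_prob Length-2 vector: exploration probability at the
#'   first and last iteration (linear decay between).
#' @param shrink_base Base of the geometric annealing of the exploitation
#'   move's scale (`shrink = shrink_base^iteration`).
#' @param init Optional matrix of starting positions (one row per member,
#'   recycled/truncated to `population`); remaining members are drawn
#'   uniformly.  Lets a caller seed the population with known-good genes.
#' @param seed Seed for the full run.
#' @return A `pp_optim`: list with `best` (list `position`, `genes`
#'   (materialized), `fitness`), `trace` (tibble per iteration with best /
#'   mean fitness and the best position) and `variant`.
#' @export
eigbo_optimize <- function(eval_fn, space = default_search_space(),
                           population = 10L, iterations = 50L,
                           variant = c("eigbo_re", "gboa"),
                           explore_prob = c(0.25, 0.05), shrink_base = 0.9,
                           init = NULL, seed = 1L) {
  variant <- match.arg(variant)
  if (population < 2L) stop("population must be >= 2", call. = FALSE)
  ngene <- nrow(space)
  safe_eval <- function(x) {
    f <- tryCatch(eval_fn(materialize(x, space)), error = function(e) 1e6)
    if (!is.finite(f)) 1e6 else f
  }
  withr::with_seed(seed, {
    pos <- t(vapply(seq_len(population), function(i)
      stats::runif(ngene, space$lower, space$upper), numeric(ngene)))
    if (!is.null(init)) {
      init <- matrix(init, ncol = ngene)
      k <- min(nrow(init), population)
      pos[seq_len(k), ] <- clip_to_space(init[seq_len(k), , drop = FALSE],
                                         space)
    }
    fit <- apply(pos, 1L, safe_eval)
    trace <- vector("list", iterations)
    for (it in seq_len(iterations)) {
      best_i <- which.min(fit)
      water <- pos[best_i, ]
      summ <- list(best = min(fit), worst = max(fit), mean = mean(fit))
      p_explore <- explore_prob[1] +
        (explore_prob[2] - explore_prob[1]) * (it - 1) /
        max(1L, iterations - 1L)
      shrink <- shrink_base^it
      new_pos <- pos
      for (m in seq_len(population)) {
        if (m == best_i) next  # elitism: keep the best member verbatim
        if (stats::runif(1) < p_explore) {
          new_pos[m, ] <- explore_move(pos[m, ], space)
        } else {
          others <- setdiff(seq_len(population), m)
          j <- others[sample.int(length(others), 1L)]
          h <- if (variant == "eigbo_re")
            compute_h(fit[m], summ$best, summ$worst, summ$mean)
          else stats::runif(1, -1, 1)
          new_pos[m, ] <- gboa_move(pos[m, ], pos[j, ], water, h, space,
                                    shrink)
        }
      }
      new_fit <- fit
      for (m in seq_len(population)) {
        if (m == best_i) next
        new_fit[m] <- safe_eval(new_pos[m, ])
      }
      pos <- new_pos; fit <- new_fit
      bi <- which.min(fit)
      trace[[it]] <- tibble::tibble(
        iteration = it, best = fit[bi], mean = mean(fit),
        !!!stats::setNames(as.list(pos[bi, ]), space$name))
    }
    best_i <- which.min(fit)
    structure(list(
      best = list(position = pos[best_i, ],
                  genes = stats::setNames(materialize(pos[best_i, ], space),
                                          space$name),
                  fitness = fit[best_i]),
      trace = dplyr::bind_rows(trace),
      variant = variant,
      population = population, iterations = iterations, seed = seed
    ), class = "pp_optim")
  })
}

#' @export
print.pp_optim <- function(x, ...) {
  cat(sprintf("<pp_optim %s> best fitness %.6g after %d iterations\n",
              x$variant, x$best$fitness, x$iterations))
  print(x$best$genes)
  invisible(x)
}

#' Tune detector and classifier genes on a dataset
#'
#' The evaluation of one candidate trains a scaled-down detector and
#' classifier with the candidate's four genes on (a subsample of) the
#' train split, then measures classification accuracy and count-based
#' detection IoU on a held-out validation slice and returns
#' [objective_jk()].  Budget fields control the problem size so a full
#' tuning run stays desk-scale.
#'
#' @param split A `scene_split`.
#' @param budget List: `population`, `iterations`, `n_train` (scenes used
#'   per evaluation), `n_val`, `epochs_det`, `epochs_cls`, `variant`,
#'   `explore_prob`.
#' @param seed Seed.
#' @return A `pp_optim` whose `best$genes` are the tuned
#'   `fpn_hidden`, `fpn_lr`, `lstm_hidden`, `lstm_lr`.
#' @export
tune_pipeline <- function(split, budget = list(), seed = 1L) {
  b <- utils::modifyList(list(population = 5L, iterations = 4L,
                              n_train = 24L, n_val = 8L, epochs_det = 2L,
                              epochs_cls = 2L, variant = "eigbo_re",
                              explore_prob = c(0.25, 0.05)), budget)
  n_tr <- min(b$n_train, length(split$train) - 1L)
  tr_scenes <- split$train[seq_len(n_tr)]
  val_scenes <- split$train[(n_tr + 1L):min(length(split$train),
                                            n_tr + b$n_val)]
  eval_fn <- function(genes) {
    fitness_of_genes(genes, tr_scenes, val_scenes,
                     epochs_det = b$epochs_det, epochs_cls = b$epochs_cls,
                     seed = seed)
  }
  space <- default_search_space()
  # seed the population with the midpoint genes so tuning never starts blind
  midpoint <- (space$lower + space$upper) / 2
  eigbo_optimize(eval_fn, space, population = b$population,
                 iterations = b$iterations, variant = b$variant,
                 explore_prob = b$explore_prob, init = midpoint, seed = seed)
}

# train a candidate's scaled-down pipeline and score objective_jk on the
# validation scenes
fitness_of_genes <- function(genes, tr_scenes, val_scenes, epochs_det,
                             epochs_cls, seed) {
  n_classes <- max(unlist(lapply(c(tr_scenes, val_scenes),
                                 function(s) s$annotations$class_id))) + 1L
  det <- train_detector(
    list(train = tr_scenes),
    detector_config(hidden_width = genes[1], learning_rate = genes[2],
                    epochs = epochs_det, seed = seed))
  crops <- list(); labels <- integer(0)
  for (sc in tr_scenes) {
    a <- sc$annotations
    for (r in seq_len(nrow(a))) {
      crops[[length(crops) + 1L]] <- crop_detection(
        sc$image, c(a$x_min[r], a$y_min[r], a$x_max[r], a$y_max[r]))
      labels <- c(labels, a$class_id[r])
    }
  }
  if (length(unique(labels)) < 2L) return(1e6)
  cls <- train_classifier(
    crops, labels,
    classifier_config(hidden_width = genes[3], learning_rate = genes[4],
                      epochs = epochs_cls, n_classes = n_classes,
                      seed = seed))
  evaluate_genes(det, cls, val_scenes)$objective
}

# accuracy (classification on matched detections), count-IoU (detection
# matches) and the resulting objective on a set of scenes
evaluate_genes <- function(det, cls, val_scenes) {
  tp <- 0L; fp <- 0L; fn <- 0L
  correct <- 0L; total <- 0L
  for (sc in val_scenes) {
    d <- detect(sc$image, det)
    m <- match_detections(d, sc$annotations)
    tp <- tp + m$counts$tp; fp <- fp + m$counts$fp; fn <- fn + m$counts$fn
    for (r in seq_len(nrow(m$matches))) {
      gt_r <- m$matches$gt_index[r]; pr_r <- m$matches$pred_index[r]
      crop <- crop_detection(sc$image,
                             as.numeric(d[pr_r, c("x_min", "y_min",
                                                  "x_max", "y_max")]))
      pred <- which.max(classify(crop, cls)) - 1L
      total <- total + 1L
      if (pred == sc$annotations$class_id[gt_r]) correct <- correct + 1L
    }
  }
  acc <- if (total > 0L) correct / total else 0
  iou <- if (tp + fp + fn > 0L) tp / (tp + fp + fn) else 0
  list(accuracy = acc, iou = iou, objective = objective_jk(acc, iou))
}
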