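# Synthetic-world generation: items on a rectangle with a sinusoidal
# decision boundary, annotator populations with condition-specific
# drift/diffusion parameters, and label + reaction-time matrices obtained by
# explicit Euler-Maruyama simulation of each decision.

#' Experiment configuration
#'
#' Bundles the knobs of a synthetic crowdsourcing experiment: the number of
#' items and annotators, the uniform supports the four annotator parameters
#' are drawn from, the Euler time step, the sampling rectangle and the root
#' seed.
#'
#' @param n_items Number of items (default 200).
#' @param n_annotators Number of annotators (default 10).
#' @param mu0_support,sigma0_support Closed intervals (length-2 numeric) for
#'   the condition-0 drift and diffusion parameters.
#' @param mu1_support,sigma1_support Same for condition 1.
#' @param dt Euler time step in seconds (default 0.01, the value used for
#'   label generation; smaller values such as 0.001 are useful for path
#'   plotting and oracle checks).
#' @param seed Integer root seed.
#' @param grid Rectangle `c(x1_min, x1_max, x2_min, x2_max)`; default
#'   `[0, 2*pi] x [-1, 1]`.
#' @return An object of class `experiment_config` (a validated list).
#' @seealso [experiment_preset()] for the two built-in presets.
#' @export
experiment_config <- function(n_items = 200L, n_annotators = 10L,
                              mu0_support = c(0.1, 0.5),
                              sigma0_support = c(0.5, 0.9),
                              mu1_support = c(0.1, 0.5),
                              sigma1_support = c(0.5, 0.9),
                              dt = 0.01, seed = 1L,
                              grid = c(0, 2 * pi, -1, 1)) {
  n_items <- as.integer(n_items)
  n_annotators <- as.integer(n_annotators)
  if (is.na(n_items) || n_items < 1L) {
    stop("`n_items` must be a positive integer", call. = FALSE)
  }
  if (is.na(n_annotators) || n_annotators < 1L) {
    stop("`n_annotators` must be a positive integer", call. = FALSE)
  }
  check_support <- function(s, name, positive = FALSE) {
    if (!is.numeric(s) || length(s) != 2L || any(!is.finite(s)) || s[1] > s[2]) {
      stop("`", name, "` must be a numeric interval c(lower, upper)",
           call. = FALSE)
    }
    if (positive && s[1] <= 0) {
      stop("`", name, "` must be strictly positive", call. = FALSE)
    }
    s
  }
  check_support(mu0_support, "mu0_support")
  check_support(mu1_support, "mu1_support")
  check_support(sigma0_support, "sigma0_support", positive = TRUE)
  check_support(sigma1_support, "sigma1_support", positive = TRUE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a positive number", call. = FALSE)
  }
  check_grid(grid)
  structure(list(n_items = n_items, n_annotators = n_annotators,
                 mu0_support = mu0_support, sigma0_support = sigma0_support,
                 mu1_support = mu1_support, sigma1_support = sigma1_support,
                 dt = dt, seed = as.integer(seed), grid = grid),
            class = "experiment_config")
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) != 4L || any(!is.finite(grid)) ||
      grid[2] <= grid[1] || grid[4] <= grid[3]) {
    stop("`grid` must be c(x1_min, x1_max, x2_min, x2_max) with positive area",
         call. = FALSE)
  }
  invisible(grid)
}

#' Built-in experiment presets
#'
#' Two standard annotator populations on the sinusoidal-boundary task, each
#' with 200 items and 10 annotators labeled at `dt = 0.01`:
#' * `"exp1"`: both conditions draw drift from U(0.1, 0.5) and diffusion
#'   from U(0.5, 0.9);
#' * `"exp2"`: condition 0 draws drift from U(0.1, 0.4) and diffusion from
#'   U(0.5, 0.7); condition 1 draws drift from U(0.2, 0.5) and diffusion
#'   from U(0.5, 0.9).
#'
#' @param name `"exp1"` or `"exp2"`.
#' @param ... Overrides passed on to [experiment_config()] (e.g. `seed`).
#' @return An `experiment_config`.
#' @export
#' @examples
#' cfg <- experiment_preset("exp1", seed = 7)
#' cfg$mu0_support
experiment_preset <- function(name = c("exp1", "exp2"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    exp1 = list(mu0_support = c(0.1, 0.5), sigma0_support = c(0.5, 0.9),
                mu1_support = c(0.1, 0.5), sigma1_support = c(0.5, 0.9)),
    exp2 = list(mu0_support = c(0.1, 0.4), sigma0_support = c(0.5, 0.7),
                mu1_support = c(0.2, 0.5), sigma1_support = c(0.5, 0.9))
  )
  args <- modifyList(base, list(...))
  cfg <- do.call(experiment_config, args)
  cfg$preset <- name
  cfg
}

#' Sample items on the rectangle and assign sinusoidal ground truth
#'
#' Items are drawn uniformly on the rectangle and labeled by the sinusoidal
#' rule: `z = 0` if `sin(x1) < x2` (the point lies above the sine curve),
#' `z = 1` otherwise. On the default rectangle the two classes each cover
#' exactly half of the area.
#'
#' @param n Number of items (>= 1).
#' @param grid Rectangle `c(x1_min, x1_max, x2_min, x2_max)`.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return Data frame with columns `item_id`, `x1`, `x2`, `z`.
#' @export
#' @examples
#' items <- generate_items(5, seed = 1)
#' items$z == as.integer(sin(items$x1) >= items$x2)
generate_items <- function(n, grid = c(0, 2 * pi, -1, 1), seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be a positive integer", call. = FALSE)
  check_grid(grid)
  if (!is.null(seed)) set.seed(seed)
  x1 <- runif(n, grid[1], grid[2])
  x2 <- runif(n, grid[3], grid[4])
  z <- ifelse(sin(x1) < x2, 0L, 1L)
  data.frame(item_id = seq_len(n), x1 = x1, x2 = x2, z = z)
}

#' Draw an annotator population from an experiment configuration
#'
#' Each of the four condition-specific parameters of each annotator is an
#' independent uniform draw from its configured support.
#'
#' @param cfg An [experiment_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return Data frame with columns `annotator_id`, `mu0`, `sigma0`, `mu1`,
#'   `sigma1`.
#' @export
sample_annotators <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  set.seed(seed)
  k <- cfg$n_annotators
  data.frame(
    annotator_id = seq_len(k),
    mu0    = runif(k, cfg$mu0_support[1], cfg$mu0_support[2]),
    sigma0 = runif(k, cfg$sigma0_support[1], cfg$sigma0_support[2]),
    mu1    = runif(k, cfg$mu1_support[1], cfg$mu1_support[2]),
    sigma1 = runif(k, cfg$sigma1_support[1], cfg$sigma1_support[2])
  )
}

# Vectorized Euler-Maruyama first-passage simulation. Paths start at 0 and
# step by mu*dt + sigma*sqrt(dt)*N(0,1) until |X| >= boundary; the label is
# decided by the sign at the absorbing step (overshoot is not corrected) and
# the reaction time is steps * dt. `drift`/`diffusion` are scalars or
# length-n vectors. Uses the current RNG state.
#
# `boundary` defaults to the literal absorbing boundary 1. Discrete-time
# crossing detection overestimates continuous first-passage functionals by
# O(sqrt(dt)); setting boundary = 1 - 0.5826 * sigma * sqrt(dt)
# (Broadie-Glasserman-Kou continuity correction) removes the leading-order
# term, which is what the Monte-Carlo oracles for the closed forms use.
simulate_paths <- function(drift, diffusion, n = max(length(drift), length(diffusion)),
                           dt = 0.01, max_steps = 1e7, boundary = 1) {
  stopifnot(dt > 0, n >= 1, all(boundary > 0))
  drift <- rep_len(drift, n)
  diffusion <- rep_len(diffusion, n)
  check_diffusion(diffusion)
  mu_dt <- drift * dt
  sd_step <- diffusion * sqrt(dt)
  boundary <- rep_len(boundary, n)
  x <- numeric(n)
  idx <- seq_len(n)               # original index of still-active paths
  hit_upper <- logical(n)
  steps <- integer(n)
  k <- 0L
  while (length(idx) > 0L) {
    k <- k + 1L
    if (k > max_steps) {
      stop("first-passage simulation exceeded ", max_steps,
           " steps for ", length(idx), " path(s); check drift/diffusion/dt",
           call. = FALSE)
    }
    x <- x + mu_dt + sd_step * rnorm(length(idx))
    done <- abs(x) >= boundary
    if (any(done)) {
      fin <- idx[done]
      steps[fin] <- k
      hit_upper[fin] <- x[done] >= boundary[done]
      keep <- !done
      x <- x[keep]; idx <- idx[keep]
      mu_dt <- mu_dt[keep]; sd_step <- sd_step[keep]
      boundary <- boundary[keep]
    }
  }
  list(hit_upper = hit_upper, rt = steps * dt)
}

#' Simulate a single annotator decision
#'
#' Runs one Euler-Maruyama evidence path for an annotator conditioned on the
#' ground truth `z`, using the `(mu0, sigma0)` pair when `z = 0` and
#' `(mu1, sigma1)` when `z = 1`. The path starts at 0 and terminates at the
#' first step where `|X| >= 1`; the label equals `z` if and only if the
#' absorbing step has `X >= 1`, and the reaction time is the number of steps
#' times `dt`.
#'
#' @param annotator A one-row data frame (or list) with `mu0`, `sigma0`,
#'   `mu1`, `sigma1`.
#' @param z Ground-truth condition, 0 or 1.
#' @param dt Euler time step in seconds.
#' @param max_steps Safety cap on the number of steps (termination is almost
#'   sure; hitting the cap raises a diagnostic error).
#' @return List with elements `y` (integer label) and `rt` (seconds, a
#'   positive multiple of `dt`).
#' @export
#' @examples
#' set.seed(1)
#' ann <- data.frame(mu0 = 0.3, sigma0 = 0.7, mu1 = 0.3, sigma1 = 0.7)
#' simulate_decision(ann, z = 1)
simulate_decision <- function(annotator, z, dt = 0.01, max_steps = 1e7) {
  annotator <- as_annotator_frame(annotator)
  stopifnot(nrow(annotator) == 1L, z %in% c(0L, 1L))
  mu <- if (z == 0L) annotator$mu0 else annotator$mu1
  sg <- if (z == 0L) annotator$sigma0 else annotator$sigma1
  sim <- simulate_paths(mu, sg, n = 1L, dt = dt, max_steps = max_steps)
  y <- if (sim$hit_upper[1]) as.integer(z) else 1L - as.integer(z)
  list(y = y, rt = sim$rt[1])
}

#' Annotate a set of items with a pool of drift-diffusion annotators
#'
#' Runs one independent decision simulation per (item, annotator) pair,
#' conditioning each annotator's parameters on the item's ground truth.
#' Labels are conditionally independent of the item features given the
#' ground truth. Each annotator consumes its own random substream derived
#' from `seed`, so adding annotators to a pool never changes the labels of
#' the existing ones.
#'
#' @param items Data frame from [generate_items()] (columns `item_id`, `x1`,
#'   `x2`, `z`).
#' @param annotators Data frame from [sample_annotators()].
#' @param dt Euler time step in seconds.
#' @param seed Integer root seed for the label streams.
#' @param max_steps Safety cap per decision.
#' @return A `crowd_dataset`: list with `items`, `annotators`, integer label
#'   matrix `y` (items x annotators), reaction-time matrix `rt`, `dt`,
#'   `seed`.
#' @export
annotate_dataset <- function(items, annotators, dt = 0.01, seed = 1L,
                             max_steps = 1e7) {
  stopifnot(is.data.frame(items),
            all(c("item_id", "x1", "x2", "z") %in% names(items)))
  annotators <- as_annotator_frame(annotators)
  n <- nrow(items); k <- nrow(annotators)
  y <- matrix(NA_integer_, n, k)
  rt <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    set.seed(derive_seed(seed, j))
    mu <- ifelse(items$z == 0L, annotators$mu0[j], annotators$mu1[j])
    sg <- ifelse(items$z == 0L, annotators$sigma0[j], annotators$sigma1[j])
    sim <- simulate_paths(mu, sg, n = n, dt = dt, max_steps = max_steps)
    y[, j] <- ifelse(sim$hit_upper, items$z, 1L - items$z)
    rt[, j] <- sim$rt
  }
  colnames(y) <- colnames(rt) <- paste0("a", seq_len(k))
  crowd_dataset(items, annotators, y, rt, dt = dt, seed = seed)
}

#' Construct a crowd dataset container
#'
#' @param items Item data frame (`item_id`, `x1`, `x2`, `z`); `z` may be NA
#'   for real data with unknown truth.
#' @param annotators True annotator parameter table, or `NULL` when unknown.
#' @param y Integer label matrix (items x annotators) with entries 0/1.
#' @param rt Reaction-time matrix (seconds, > 0), or `NULL` when unavailable.
#' @param dt Time step used to generate `rt` (informational).
#' @param seed Root seed used to generate the labels (informational).
#' @return An object of class `crowd_dataset`.
#' @export
crowd_dataset <- function(items, annotators, y, rt = NULL, dt = NA_real_,
                          seed = NA_integer_) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (!all(y %in% c(0L, 1L))) {
    stop("label matrix `y` must contain only 0/1", call. = FALSE)
  }
  if (nrow(y) != nrow(items)) {
    stop("`y` must have one row per item", call. = FALSE)
  }
  if (!is.null(rt)) {
    rt <- as.matrix(rt)
    if (!all(dim(rt) == dim(y))) {
      stop("`rt` must have the same shape as `y`", call. = FALSE)
    }
    if (any(!is.finite(rt)) || any(rt <= 0)) {
      stop("reaction times must be strictly positive", call. = FALSE)
    }
  }
  structure(list(items = items, annotators = annotators, y = y, rt = rt,
                 dt = dt, seed = seed),
            class = "crowd_dataset")
}

#' Simulate a complete synthetic crowdsourcing experiment
#'
#' Convenience wrapper chaining [generate_items()], [sample_annotators()]
#' and [annotate_dataset()] with sub-seeds derived from one root seed.
#'
#' @param cfg An [experiment_config()].
#' @param seed Root seed (defaults to `cfg$seed`).
#' @return A `crowd_dataset` containing the hidden truth and the generating
#'   annotator parameters.
#' @export
#' @examples
#' cfg <- experiment_preset("exp1", n_items = 20, n_annotators = 3)
#' ds <- simulate_experiment(cfg, seed = 1)
#' dim(ds$y)
simulate_experiment <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "experiment_config"))
  items <- generate_items(cfg$n_items, cfg$grid, seed = derive_seed(seed, 1001))
  ann <- sample_annotators(cfg, seed = derive_seed(seed, 1002))
  annotate_dataset(items, ann, dt = cfg$dt, seed = derive_seed(seed, 1003))
}

#' @export
print.crowd_dataset <- function(x, ...) {
  cat("crowd_dataset:", nrow(x$y), "items x", ncol(x$y), "annotators\n")
  if (!is.null(x$items$z) && !anyNA(x$items$z)) {
    cat("  class balance (z = 1):", round(mean(x$items$z), 3), "\n")
  }
  cat("  reaction times:", if (is.null(x$rt)) "absent" else "present",
      "; dt =", x$dt, "\n")
  invisible(x)
}
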