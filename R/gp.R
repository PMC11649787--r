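# Gaussian-process regression from item features to inferred latent values,
# thresholded through the logistic link to classify arbitrary new points.
# Zero-mean GP with an RBF kernel (amplitude * exp(-||x - x'||^2 / (2 l^2)))
# summed with a white-noise kernel; hyperparameters are selected by
# maximizing the log marginal likelihood (Cholesky form) under box bounds,
# with seeded random restarts.

rbf_cross_kernel <- function(x1, x2, amplitude, lengthscale) {
  # squared Euclidean cross-distances
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  d2[d2 < 0] <- 0
  amplitude * exp(-d2 / (2 * lengthscale^2))
}

gp_neg_logml <- function(theta, d2, f, n) {
  amplitude <- exp(theta[1]); lengthscale <- exp(theta[2])
  noise <- exp(theta[3])
  K <- amplitude * exp(-d2 / (2 * lengthscale^2))
  diag(K) <- diag(K) + noise
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), f))
  0.5 * sum(f * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
}

#' Fit a Gaussian-process regressor to inferred latent values
#'
#' Zero-mean GP regression of latent values on item features with an RBF
#' plus white kernel. The amplitude, length scale and noise variance are
#' chosen by maximizing the log marginal likelihood with L-BFGS-B in log
#' space within box bounds; several seeded restarts guard against local
#' optima.
#'
#' @param x Numeric matrix (n x m) of item features, n >= 2.
#' @param f Numeric vector of latent targets (length n).
#' @param lengthscale_bounds Box bounds for the RBF length scale
#'   (default `c(0.001, 1000)`).
#' @param noise_bounds Box bounds for the white-noise variance
#'   (default `c(0.001, 10)`).
#' @param amplitude_bounds Box bounds for the RBF amplitude (signal
#'   variance; default `c(0.001, 1000)`).
#' @param n_restarts Number of optimizer starts (default 5: one default
#'   start plus seeded log-uniform draws within the bounds).
#' @param seed Integer seed for the restart draws.
#' @return Object of class `ddm_gp` holding the training inputs/targets,
#'   fitted hyperparameters, the weight vector used for prediction and the
#'   maximized log marginal likelihood.
#' @export
#' @examples
#' x <- cbind(seq(0, 1, length.out = 20), 0)
#' fit <- fit_gp(x, sin(2 * pi * x[, 1]), seed = 1)
#' predict(fit, x[1:3, , drop = FALSE])
fit_gp <- function(x, f, lengthscale_bounds = c(0.001, 1000),
                   noise_bounds = c(0.001, 10),
                   amplitude_bounds = c(0.001, 1000),
                   n_restarts = 5L, seed = NULL) {
  x <- as.matrix(x)
  f <- as.numeric(f)
  n <- nrow(x)
  if (n < 2L) stop("at least two training points are required", call. = FALSE)
  if (length(f) != n) stop("`x` and `f` must have matching length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(f))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (nrow(unique(x)) < 2L) {
    stop("all training inputs are identical: the kernel matrix is singular ",
         "up to the noise term and the length scale is unidentifiable",
         call. = FALSE)
  }
  bounds <- rbind(amplitude = amplitude_bounds,
                  lengthscale = lengthscale_bounds,
                  noise = noise_bounds)
  if (any(bounds[, 1] <= 0) || any(bounds[, 1] >= bounds[, 2])) {
    stop("hyperparameter bounds must be positive with lower < upper",
         call. = FALSE)
  }
  lower <- log(bounds[, 1]); upper <- log(bounds[, 2])
  d2 <- as.matrix(dist(x))^2
  start_default <- pmin(pmax(log(c(1, 1, 0.1)), lower), upper)
  starts <- list(start_default)
  if (n_restarts > 1L) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(n_restarts - 1L)) {
      starts[[r + 1L]] <- runif(3, lower, upper)
    }
  }
  obj <- function(theta) gp_neg_logml(theta, d2, f, n)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("marginal-likelihood optimization failed", call. = FALSE)
  amplitude <- exp(best$par[1]); lengthscale <- exp(best$par[2])
  noise <- exp(best$par[3])
  K <- amplitude * exp(-d2 / (2 * lengthscale^2))
  diag(K) <- diag(K) + noise
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), f))
  structure(list(x = x, f = f, amplitude = amplitude,
                 lengthscale = lengthscale, noise = noise,
                 alpha = alpha, logml = -best$value,
                 bounds = bounds),
            class = "ddm_gp")
}

#' Predict latent values at new points
#'
#' Posterior mean of the zero-mean GP at the new inputs (the white-noise
#' component contributes to the training covariance only).
#'
#' @param object A fitted `ddm_gp`.
#' @param newdata Numeric matrix (or data frame) of new inputs with the same
#'   number of columns as the training inputs.
#' @param ... Unused.
#' @return Numeric vector of predicted latent values.
#' @export
predict.ddm_gp <- function(object, newdata, ...) {
  xs <- as.matrix(newdata)
  if (ncol(xs) != ncol(object$x)) {
    stop("`newdata` must have ", ncol(object$x), " columns", call. = FALSE)
  }
  ks <- rbf_cross_kernel(xs, object$x, object$amplitude, object$lengthscale)
  as.numeric(ks %*% object$alpha)
}

#' Classify new points with a fitted latent-value GP
#'
#' Computes the predicted latent value `f*`, the logistic class probability
#' and the hard label for each new point. Under the default convention
#' (`positive_branch = 1`, the logistic link `P(z = 1 | f) = S(f)`) the
#' label is `z* = 1` iff `f* > 0`; with `positive_branch = 0` (the pairing
#' used by the default inference convention, where the latent carries the
#' probability of condition 0) the mapping flips to `z* = 1` iff `f* < 0`.
#' In both cases `p_star` is reported on the `P(z = 1)` scale and an exact
#' tie `f* = 0` resolves to `z* = 0`.
#'
#' @param model A fitted `ddm_gp`.
#' @param newdata New inputs (matrix or data frame).
#' @param positive_branch Which condition the latent's logistic weight
#'   refers to (1, the default, or 0).
#' @return Data frame with columns `f_star`, `p_star`, `z_star`.
#' @export
predict_label <- function(model, newdata, positive_branch = 1L) {
  if (!inherits(model, "ddm_gp")) {
    stop("`model` must be a fitted ddm_gp", call. = FALSE)
  }
  positive_branch <- check_branch(positive_branch)
  fs <- predict(model, newdata)
  if (positive_branch == 1L) {
    p <- stats::plogis(fs)
    z <- ifelse(fs > 0, 1L, 0L)
  } else {
    p <- stats::plogis(-fs)
    z <- ifelse(fs < 0, 1L, 0L)
  }
  data.frame(f_star = fs, p_star = p, z_star = z)
}

#' @export
print.ddm_gp <- function(x, ...) {
  cat("ddm_gp:", nrow(x$x), "training points,", ncol(x$x), "features\n")
  cat(sprintf("  amplitude %.4g, length scale %.4g, noise variance %.4g\n",
              x$amplitude, x$lengthscale, x$noise))
  cat(sprintf("  log marginal likelihood %.4f\n", x$logml))
  invisible(x)
}
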