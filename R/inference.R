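# Mean-field variational inference for the drift-diffusion crowdsourcing
# model. The optimized objective is the evidence lower bound
#
#   g(q, F, mu0, mu1, sigma0, sigma1) =
#     sum_i ln[ sum_j w_i P(y_ij | z = A) + (1 - w_i) P(y_ij | z = 1 - A) ]
#     + sum_i [ q_i ln S(f_i) + (1 - q_i) ln(1 - S(f_i)) ]
#     - sum_i [ q_i ln q_i + (1 - q_i) ln(1 - q_i) ]
#
# with w_i = S(f_i) and annotator response probabilities
# P(y | z = c) built from S(2 mu_c / sigma_c^2). The default likelihood form
# is the mixture with the product over annotators inside the logarithm
# ("product"), the likelihood implied by conditional independence of the
# annotators given the truth; the variant with the sum over annotators
# inside the logarithm is available as likelihood_form = "printed" (it
# aggregates annotators as a linear vote and is kept for comparison; see
# the methods vignette). A, the branch whose
# probability the weights w_i and q_i carry, is condition 0 by default
# (`positive_branch = 0`); flipping it relabels everything consistently.
#
# All annotator parameters and q are softly constrained to (0, 1) through
# the penalty c(v) = -exp(beta (max(v) - 1)) - exp(-beta min(v)) added per
# parameter block. Optimization is full-batch gradient ascent with a fixed
# learning rate; reaction-time information enters either as a squared-error
# regularizer on expected decision times (method "1") or as a post-hoc
# accuracy-preserving rescaling of the recovered parameters (method "2").

#' Constraint penalty keeping a parameter block inside (0, 1)
#'
#' `c(v) = -base^(beta * (max(v) - 1)) - exp(-beta * min(v))`: approximately
#' zero while all entries are well inside the unit interval and steeply
#' negative as the extreme entries approach or cross 0 or 1. The default
#' base is `e`, matching the second term.
#'
#' @param v Non-empty numeric vector.
#' @param beta Penalty sharpness (default 30).
#' @param base Base of the upper-boundary term (default `exp(1)`).
#' @return A scalar penalty value (<= 0).
#' @export
#' @examples
#' constraint_penalty(c(0.2, 0.5, 0.8))   # ~ -2.5e-4
#' constraint_penalty(0)                  # ~ -1
constraint_penalty <- function(v, beta = 30, base = exp(1)) {
  if (length(v) == 0L || any(!is.finite(v))) {
    stop("`v` must be a non-empty finite numeric vector", call. = FALSE)
  }
  stopifnot(beta > 0, base > 1)
  -base^(beta * (max(v) - 1)) - exp(-beta * min(v))
}

# gradient of constraint_penalty; nonzero only at the extreme entries
constraint_penalty_grad <- function(v, beta = 30, base = exp(1)) {
  g <- numeric(length(v))
  imax <- which.max(v); imin <- which.min(v)
  g[imax] <- g[imax] - log(base) * beta * base^(beta * (v[imax] - 1))
  g[imin] <- g[imin] + beta * exp(-beta * v[imin])
  g
}

# Annotator response probability matrices.
# P0[i, j] = P(y_ij | z_i = 0), P1[i, j] = P(y_ij | z_i = 1).
response_prob_matrices <- function(y, s0, s1) {
  n <- nrow(y); k <- ncol(y)
  S0 <- matrix(s0, n, k, byrow = TRUE)
  S1 <- matrix(s1, n, k, byrow = TRUE)
  list(P0 = (1 - y) * S0 + y * (1 - S0),
       P1 = y * S1 + (1 - y) * (1 - S1))
}

# Shared likelihood core. `w` is the per-item probability weight on the
# branch selected by `positive_branch`. Returns the log-likelihood value
# and, if grad = TRUE, gradients with respect to w and to the response
# probabilities s0 = S(2 mu0 / sigma0^2), s1 = S(2 mu1 / sigma1^2).
crowd_loglik_core <- function(y, w, s0, s1,
                              likelihood_form = c("product", "printed"),
                              positive_branch = 0L, eps = 1e-9,
                              grad = FALSE) {
  likelihood_form <- match.arg(likelihood_form)
  pm <- response_prob_matrices(y, s0, s1)
  if (positive_branch == 0L) { A <- pm$P0; B <- pm$P1 } else { A <- pm$P1; B <- pm$P0 }
  if (likelihood_form == "printed") {
    ra <- rowSums(A); rb <- rowSums(B)
    D <- w * ra + (1 - w) * rb
    value <- sum(log(D))
    if (!grad) return(list(value = value))
    gw <- (ra - rb) / D
    # weight multiplying the condition-0 response matrix
    w0 <- if (positive_branch == 0L) w else 1 - w
    gs0 <- colSums((w0 / D) * (1 - 2 * y))
    gs1 <- colSums(((1 - w0) / D) * (2 * y - 1))
  } else {
    lA <- rowSums(log(pmax(A, eps)))
    lB <- rowSums(log(pmax(B, eps)))
    M <- pmax(lA, lB)
    ea <- exp(lA - M); eb <- exp(lB - M)
    den <- w * ea + (1 - w) * eb
    value <- sum(M + log(den))
    if (!grad) return(list(value = value))
    gw <- (ea - eb) / den
    rA <- w * ea / den                       # responsibility of branch A
    r0 <- if (positive_branch == 0L) rA else 1 - rA
    gs0 <- colSums(r0 * (1 - 2 * y) / pmax(pm$P0, eps))
    gs1 <- colSums((1 - r0) * (2 * y - 1) / pmax(pm$P1, eps))
  }
  list(value = value, gw = gw, gs0 = gs0, gs1 = gs1)
}

#' Log-likelihood of a crowd label matrix
#'
#' Evaluates the data log-likelihood of the 0/1 label matrix given per-item
#' branch probabilities and annotator drift/diffusion parameters. The
#' default `"product"` form is the mixture
#' `sum_i ln[p_i prod_j P(y_ij | z=A) + (1 - p_i) prod_j P(y_ij | z=1-A)]`
#' implied by conditional independence of the annotators given the truth;
#' `likelihood_form = "printed"` instead keeps a sum over annotators inside
#' the logarithm, which aggregates annotators as a linear vote (the two
#' coincide for a single annotator).
#'
#' @param y Integer matrix (items x annotators) with entries 0/1.
#' @param p Per-item probability of the branch selected by
#'   `positive_branch` (default: probability that `z = 0`).
#' @param annotators Data frame with columns `mu0`, `sigma0`, `mu1`,
#'   `sigma1`.
#' @param likelihood_form `"product"` (the default) or `"printed"` (sum
#'   over annotators inside the logarithm).
#' @param positive_branch Which condition the probabilities `p` refer to
#'   (0, the default, or 1).
#' @param eps Clipping floor used inside logarithms.
#' @return Scalar log-likelihood (finite).
#' @export
data_log_likelihood <- function(y, p, annotators,
                                likelihood_form = c("product", "printed"),
                                positive_branch = 0L, eps = 1e-9) {
  y <- check_label_matrix(y)
  annotators <- as_annotator_frame(annotators)
  stopifnot(length(p) == nrow(y), all(p >= 0), all(p <= 1))
  positive_branch <- check_branch(positive_branch)
  s0 <- correct_probability(annotators$mu0, annotators$sigma0)
  s1 <- correct_probability(annotators$mu1, annotators$sigma1)
  crowd_loglik_core(y, p, s0, s1, likelihood_form, positive_branch, eps)$value
}

check_label_matrix <- function(y) {
  y <- as.matrix(y)
  if (length(y) == 0L) stop("label matrix `y` is empty", call. = FALSE)
  if (!all(y %in% c(0, 1))) {
    stop("label matrix `y` must contain only 0/1", call. = FALSE)
  }
  storage.mode(y) <- "double"
  y
}

check_branch <- function(positive_branch) {
  if (!(length(positive_branch) == 1L && positive_branch %in% c(0, 1))) {
    stop("`positive_branch` must be 0 or 1", call. = FALSE)
  }
  as.integer(positive_branch)
}

#' Evidence lower bound of the variational crowdsourcing model
#'
#' The data log-likelihood evaluated with per-item weights `S(f_i)`, plus
#' the cross-entropy coupling `sum_i q_i ln S(f_i) + (1 - q_i) ln(1 - S(f_i))`
#' and the entropy of the mean-field label posterior. Constraint penalties
#' are not included; they are added per block by the optimizer (see
#' [constraint_penalty()]).
#'
#' @inheritParams data_log_likelihood
#' @param q Per-item posterior probabilities of the `positive_branch`
#'   condition, strictly inside (0, 1).
#' @param f Per-item latent values (the means of the Gaussian variational
#'   factors), unconstrained.
#' @return Scalar objective value.
#' @export
elbo_objective <- function(y, q, f, annotators,
                           likelihood_form = c("product", "printed"),
                           positive_branch = 0L, eps = 1e-9) {
  y <- check_label_matrix(y)
  annotators <- as_annotator_frame(annotators)
  stopifnot(length(q) == nrow(y), length(f) == nrow(y),
            all(q > 0), all(q < 1), all(is.finite(f)))
  positive_branch <- check_branch(positive_branch)
  s0 <- correct_probability(annotators$mu0, annotators$sigma0)
  s1 <- correct_probability(annotators$mu1, annotators$sigma1)
  ll <- crowd_loglik_core(y, stats::plogis(f), s0, s1, likelihood_form,
                          positive_branch, eps)$value
  qc <- clip_unit(q, eps)
  ce <- sum(q * stats::plogis(f, log.p = TRUE) +
              (1 - q) * stats::plogis(-f, log.p = TRUE))
  ent <- -sum(qc * log(qc) + (1 - qc) * log1p(-qc))
  ll + ce + ent
}

#' Reaction-time summary by annotator and estimated condition
#'
#' Mean observed reaction time and item count for every annotator under
#' each estimated condition. Conditions are typically obtained by
#' thresholding the inferred posterior probabilities (see
#' [predicted_labels()]).
#'
#' @param rt Reaction-time matrix (items x annotators), seconds.
#' @param condition Integer vector of estimated conditions (0/1), one per
#'   item.
#' @return Data frame of class `rt_summary` with columns `annotator`,
#'   `condition`, `mean_rt`, `n_items`. Conditions with no items get
#'   `mean_rt = NA` and `n_items = 0`.
#' @export
rt_summary <- function(rt, condition) {
  rt <- as.matrix(rt)
  stopifnot(length(condition) == nrow(rt), all(condition %in% c(0L, 1L)))
  if (any(!is.finite(rt)) || any(rt <= 0)) {
    stop("reaction times must be strictly positive", call. = FALSE)
  }
  k <- ncol(rt)
  out <- expand.grid(annotator = seq_len(k), condition = c(0L, 1L),
                     KEEP.OUT.ATTRS = FALSE)
  out$mean_rt <- NA_real_
  out$n_items <- 0L
  for (cond in c(0L, 1L)) {
    sel <- condition == cond
    rows <- out$condition == cond
    out$n_items[rows] <- sum(sel)
    if (any(sel)) {
      out$mean_rt[rows] <- colMeans(rt[sel, , drop = FALSE])
    }
  }
  class(out) <- c("rt_summary", "data.frame")
  out
}

# k x 2 matrices (mean, n) from an rt_summary
rt_summary_matrices <- function(rtsum, k) {
  mean_rt <- matrix(NA_real_, k, 2)
  n_items <- matrix(0L, k, 2)
  mean_rt[cbind(rtsum$annotator, rtsum$condition + 1L)] <- rtsum$mean_rt
  n_items[cbind(rtsum$annotator, rtsum$condition + 1L)] <- rtsum$n_items
  list(mean_rt = mean_rt, n_items = n_items)
}

#' Reaction-time regularizer on expected decision times
#'
#' Penalizes squared deviations between the model-implied expected decision
#' time of each annotator under each condition (via the optional-stopping
#' identity, see [expected_decision_time()]) and the observed mean reaction
#' time: `-lambda * sum_(j, c) (E[tau](mu_c^j, sigma_c^j) - mean_rt_jc)^2`.
#' Conditions with no assigned items are skipped. The value is 0 exactly
#' when every model-implied mean matches the observed mean.
#'
#' @param annotators Data frame with columns `mu0`, `sigma0`, `mu1`,
#'   `sigma1` (current parameter estimates).
#' @param rtsum An [rt_summary()].
#' @param lambda Non-negative regularizer weight.
#' @return Scalar value (<= 0).
#' @export
rt_regularizer <- function(annotators, rtsum, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a non-negative number", call. = FALSE)
  }
  annotators <- as_annotator_frame(annotators)
  k <- nrow(annotators)
  m <- rt_summary_matrices(rtsum, k)
  if (any(m$mean_rt[m$n_items > 0] <= 0, na.rm = TRUE)) {
    stop("observed mean reaction times must be positive", call. = FALSE)
  }
  tt <- cbind(expected_decision_time(annotators$mu0, annotators$sigma0),
              expected_decision_time(annotators$mu1, annotators$sigma1))
  dev <- tt - m$mean_rt
  -lambda * sum(dev[m$n_items > 0]^2, na.rm = TRUE)
}

# partial derivatives of expected_decision_time wrt mu and sigma
decision_time_grad <- function(mu, sigma) {
  t <- 2 * mu / sigma^2
  p <- stats::plogis(t)
  sp <- p * (1 - p)
  dmu <- ifelse(abs(mu) < 1e-6, 0,
                4 * sp / (sigma^2 * mu) - (2 * p - 1) / mu^2)
  dsigma <- -8 * sp / sigma^3
  list(dmu = dmu, dsigma = dsigma)
}

# gradient of rt_regularizer wrt (mu0, sigma0, mu1, sigma1); returns list
rt_regularizer_grad <- function(mu0, sigma0, mu1, sigma1, rtsum, lambda) {
  k <- length(mu0)
  m <- rt_summary_matrices(rtsum, k)
  g <- list(mu0 = numeric(k), sigma0 = numeric(k),
            mu1 = numeric(k), sigma1 = numeric(k))
  for (cond in 1:2) {
    use <- m$n_items[, cond] > 0
    if (!any(use)) next
    mu <- if (cond == 1) mu0 else mu1
    sg <- if (cond == 1) sigma0 else sigma1
    tt <- expected_decision_time(mu, sg)
    dg <- decision_time_grad(mu, sg)
    coef <- ifelse(use, -2 * lambda * (tt - m$mean_rt[, cond]), 0)
    if (cond == 1) {
      g$mu0 <- g$mu0 + coef * dg$dmu
      g$sigma0 <- g$sigma0 + coef * dg$dsigma
    } else {
      g$mu1 <- g$mu1 + coef * dg$dmu
      g$sigma1 <- g$sigma1 + coef * dg$dsigma
    }
  }
  g
}

#' Optimization settings for the variational fit
#'
#' Defaults reproduce the reference schedule: learning rate 0.01, all
#' parameters initialized at 0.5, penalty sharpness `beta = 30`, and the
#' stop rule "the later of `min_iter` iterations or an ELBO change below
#' `elbo_tol`", with a hard cap preventing non-termination.
#'
#' @param learn_rate Gradient-ascent learning rate.
#' @param min_iter Minimum number of iterations (default 300).
#' @param elbo_tol Absolute ELBO-change threshold (default 0.1).
#' @param max_iter Hard iteration cap (default 5000).
#' @param beta Constraint-penalty sharpness (default 30).
#' @param penalty_base Base of the upper-boundary penalty term (default `e`).
#' @param lambda Reaction-time regularizer weight for method "1".
#' @param grad_clip Component-wise bound applied to every gradient block
#'   before the update (default 1, so no coordinate moves by more than
#'   `learn_rate * grad_clip` per iteration; `Inf` disables). The mixture
#'   log-likelihood is cliff-shaped near saturated response probabilities
#'   and a fixed learning rate overshoots without this safeguard; the
#'   reported gradients themselves (see the finite-difference tests) are
#'   exact.
#' @param likelihood_form `"product"` (the mixture implied by conditional
#'   independence of annotators given the truth, the default) or
#'   `"printed"`; see [data_log_likelihood()].
#' @param positive_branch Condition carried by `q` and `S(f)` (0 or 1).
#' @param constrain_f Apply the constraint penalty to the latent block `f`
#'   as well (default `FALSE`; `f` must span both signs to encode labels).
#' @param init Initial value for every parameter (default 0.5).
#' @param eps Clipping floor used inside logarithms.
#' @return A list of class `vb_control`.
#' @export
vb_control <- function(learn_rate = 0.01, min_iter = 300L, elbo_tol = 0.1,
                       max_iter = 5000L, beta = 30, penalty_base = exp(1),
                       lambda = 1, grad_clip = 1,
                       likelihood_form = c("product", "printed"),
                       positive_branch = 0L, constrain_f = FALSE,
                       init = 0.5, eps = 1e-9) {
  likelihood_form <- match.arg(likelihood_form)
  stopifnot(learn_rate > 0, min_iter >= 1, elbo_tol > 0,
            max_iter >= min_iter, beta > 0, lambda >= 0, grad_clip > 0,
            init > 0, init < 1, eps > 0)
  structure(list(learn_rate = learn_rate, min_iter = as.integer(min_iter),
                 elbo_tol = elbo_tol, max_iter = as.integer(max_iter),
                 beta = beta, penalty_base = penalty_base, lambda = lambda,
                 grad_clip = grad_clip,
                 likelihood_form = likelihood_form,
                 positive_branch = check_branch(positive_branch),
                 constrain_f = isTRUE(constrain_f), init = init, eps = eps),
            class = "vb_control")
}

# objective actually ascended: ELBO + per-block penalties (+ RT regularizer)
vb_objective_full <- function(y, par, control, rtsum = NULL) {
  ann <- data.frame(mu0 = par$mu0, sigma0 = par$sigma0,
                    mu1 = par$mu1, sigma1 = par$sigma1)
  value <- elbo_objective(y, par$q, par$f, ann,
                          likelihood_form = control$likelihood_form,
                          positive_branch = control$positive_branch,
                          eps = control$eps)
  blocks <- list(par$q, par$mu0, par$mu1, par$sigma0, par$sigma1)
  if (control$constrain_f) blocks <- c(blocks, list(par$f))
  for (v in blocks) {
    value <- value + constraint_penalty(v, control$beta, control$penalty_base)
  }
  if (!is.null(rtsum) && control$lambda > 0) {
    value <- value + rt_regularizer(ann, rtsum, control$lambda)
  }
  value
}

vb_gradient_full <- function(y, par, control, rtsum = NULL) {
  s0 <- stats::plogis(2 * par$mu0 / par$sigma0^2)
  s1 <- stats::plogis(2 * par$mu1 / par$sigma1^2)
  w <- stats::plogis(par$f)
  core <- crowd_loglik_core(y, w, s0, s1, control$likelihood_form,
                            control$positive_branch, control$eps, grad = TRUE)
  qc <- clip_unit(par$q, control$eps)
  g <- list()
  g$q <- par$f - logit(qc) +
    constraint_penalty_grad(par$q, control$beta, control$penalty_base)
  g$f <- dlogis_dx(par$f) * core$gw + (par$q - w)
  if (control$constrain_f) {
    g$f <- g$f + constraint_penalty_grad(par$f, control$beta,
                                         control$penalty_base)
  }
  # chain rule from response probabilities to drift/diffusion
  d0 <- s0 * (1 - s0); d1 <- s1 * (1 - s1)
  g$mu0 <- core$gs0 * d0 * 2 / par$sigma0^2
  g$sigma0 <- core$gs0 * d0 * (-4 * par$mu0 / par$sigma0^3)
  g$mu1 <- core$gs1 * d1 * 2 / par$sigma1^2
  g$sigma1 <- core$gs1 * d1 * (-4 * par$mu1 / par$sigma1^3)
  for (blk in c("mu0", "mu1", "sigma0", "sigma1")) {
    g[[blk]] <- g[[blk]] +
      constraint_penalty_grad(par[[blk]], control$beta, control$penalty_base)
  }
  if (!is.null(rtsum) && control$lambda > 0) {
    rg <- rt_regularizer_grad(par$mu0, par$sigma0, par$mu1, par$sigma1,
                              rtsum, control$lambda)
    for (blk in names(rg)) g[[blk]] <- g[[blk]] + rg[[blk]]
  }
  g
}

#' Fit the variational crowdsourcing model
#'
#' Full-batch gradient ascent on the evidence lower bound with constraint
#' penalties on every (0, 1)-bounded block. Three variants:
#' * `method = "plain"`: labels only;
#' * `method = "1"`: adds the reaction-time regularizer
#'   ([rt_regularizer()]) to the objective, with per-condition observed
#'   mean reaction times recomputed each iteration from the current
#'   thresholded posteriors (and treated as constants in the gradient);
#' * `method = "2"`: plain ascent followed by [rescale_by_rt()].
#'
#' Iteration stops at the later of `control$min_iter` iterations and an
#' absolute ELBO change below `control$elbo_tol` (hard cap
#' `control$max_iter`).
#'
#' @param y Integer label matrix (items x annotators), entries 0/1.
#' @param rt Reaction-time matrix matching `y` (required for methods "1"
#'   and "2").
#' @param method `"plain"`, `"1"` or `"2"`.
#' @param control A [vb_control()].
#' @return Object of class `ddm_vb_fit`: posterior probabilities `q` (of
#'   the `positive_branch` condition), latent values `f`, annotator
#'   parameter estimates (with analytic sensitivity/specificity), the
#'   ELBO trace, convergence information and the settings used.
#' @export
#' @examples
#' cfg <- experiment_preset("exp1", n_items = 30, n_annotators = 3)
#' ds <- simulate_experiment(cfg, seed = 1)
#' fit <- fit_variational(ds$y, ds$rt, method = "2",
#'                        control = vb_control(min_iter = 50))
#' head(predicted_labels(fit))
fit_variational <- function(y, rt = NULL, method = c("plain", "1", "2"),
                            control = vb_control()) {
  method <- match.arg(as.character(method), c("plain", "1", "2"))
  stopifnot(inherits(control, "vb_control"))
  y <- check_label_matrix(y)
  n <- nrow(y); k <- ncol(y)
  if (method %in% c("1", "2")) {
    if (is.null(rt)) {
      stop("method ", method, " requires reaction times", call. = FALSE)
    }
    rt <- as.matrix(rt)
    stopifnot(all(dim(rt) == dim(y)))
    if (any(!is.finite(rt)) || any(rt <= 0)) {
      stop("reaction times must be strictly positive", call. = FALSE)
    }
  }
  par <- list(q = rep(control$init, n), f = rep(control$init, n),
              mu0 = rep(control$init, k), sigma0 = rep(control$init, k),
              mu1 = rep(control$init, k), sigma1 = rep(control$init, k))
  trace <- numeric(control$max_iter + 1L)
  rtsum <- NULL
  if (method == "1") {
    rtsum <- rt_summary(rt, assign_condition(par$q, control$positive_branch))
  }
  trace[1] <- vb_objective_full(y, par, control, rtsum)
  it <- 0L
  converged <- FALSE
  while (it < control$max_iter) {
    it <- it + 1L
    if (method == "1") {
      rtsum <- rt_summary(rt, assign_condition(par$q, control$positive_branch))
    }
    g <- vb_gradient_full(y, par, control, rtsum)
    for (blk in names(g)) {
      if (any(!is.finite(g[[blk]]))) {
        stop("non-finite gradient in block '", blk, "' at iteration ", it,
             call. = FALSE)
      }
    }
    for (blk in names(par)) {
      step <- pmin(pmax(g[[blk]], -control$grad_clip), control$grad_clip)
      par[[blk]] <- par[[blk]] + control$learn_rate * step
    }
    par$q <- clip_unit(par$q, control$eps)
    trace[it + 1L] <- vb_objective_full(y, par, control, rtsum)
    if (it >= control$min_iter &&
        abs(trace[it + 1L] - trace[it]) < control$elbo_tol) {
      converged <- TRUE
      break
    }
  }
  annotators <- data.frame(annotator_id = seq_len(k),
                           mu0 = par$mu0, sigma0 = par$sigma0,
                           mu1 = par$mu1, sigma1 = par$sigma1)
  annotators <- cbind(annotators,
                      annotator_sensitivity_specificity(annotators))
  fit <- structure(list(q = par$q, f = par$f, annotators = annotators,
                        elbo_trace = trace[seq_len(it + 1L)],
                        iterations = it, converged = converged,
                        method = method, control = control,
                        rescaled = FALSE),
                   class = "ddm_vb_fit")
  if (method == "2") fit <- rescale_by_rt(fit, rt)
  fit
}

# map posterior probabilities of the positive branch to 0/1 condition
# estimates; exact ties at 0.5 go to class 0
assign_condition <- function(q, positive_branch) {
  if (positive_branch == 0L) ifelse(q >= 0.5, 0L, 1L) else ifelse(q > 0.5, 1L, 0L)
}

#' Predicted item labels from a variational fit
#'
#' Thresholds the posterior probabilities at 0.5; exact ties resolve to
#' class 0.
#'
#' @param fit A `ddm_vb_fit`.
#' @return Integer vector of 0/1 labels.
#' @export
predicted_labels <- function(fit) {
  stopifnot(inherits(fit, "ddm_vb_fit"))
  assign_condition(fit$q, fit$control$positive_branch)
}

#' Rescale recovered parameters to match observed reaction times
#'
#' Labels identify annotator accuracy only through `mu / sigma^2`; reaction
#' times pin the remaining scale. For each annotator and condition this
#' applies the accuracy-preserving map `(mu, sigma) -> (c mu, sqrt(c) sigma)`
#' with `c` chosen so that the model-implied expected decision time equals
#' the observed mean reaction time of the items assigned to that condition
#' (under this map the expected time scales exactly by `1 / c`, so
#' `c = E[tau](mu, sigma) / mean_rt`). Sensitivities and specificities are
#' unchanged to machine precision. Conditions with no assigned items are
#' left untouched.
#'
#' @param fit A `ddm_vb_fit`.
#' @param rt Reaction-time matrix (items x annotators).
#' @return The fit with rescaled annotator parameters (`rescaled = TRUE`).
#' @export
rescale_by_rt <- function(fit, rt) {
  stopifnot(inherits(fit, "ddm_vb_fit"))
  rt <- as.matrix(rt)
  stopifnot(nrow(rt) == length(fit$q), ncol(rt) == nrow(fit$annotators))
  cond <- assign_condition(fit$q, fit$control$positive_branch)
  rtsum <- rt_summary(rt, cond)
  k <- nrow(fit$annotators)
  m <- rt_summary_matrices(rtsum, k)
  if (any(m$mean_rt[m$n_items > 0] <= 0, na.rm = TRUE)) {
    stop("observed mean reaction times must be positive", call. = FALSE)
  }
  ann <- fit$annotators
  for (condn in 1:2) {
    use <- m$n_items[, condn] > 0
    if (!any(use)) next
    mu_col <- if (condn == 1) "mu0" else "mu1"
    sg_col <- if (condn == 1) "sigma0" else "sigma1"
    tt <- expected_decision_time(ann[[mu_col]], ann[[sg_col]])
    cc <- ifelse(use, tt / m$mean_rt[, condn], 1)
    ann[[mu_col]] <- cc * ann[[mu_col]]
    ann[[sg_col]] <- sqrt(cc) * ann[[sg_col]]
  }
  ann$sensitivity <- correct_probability(ann$mu1, ann$sigma1)
  ann$specificity <- correct_probability(ann$mu0, ann$sigma0)
  fit$annotators <- ann
  fit$rescaled <- TRUE
  fit
}

#' Estimate uniform prior supports from recovered annotator parameters
#'
#' The support of each parameter's uniform prior is estimated by the
#' minimum and maximum of the corresponding recovered per-annotator values.
#'
#' @param fit A `ddm_vb_fit`, or a data frame with columns `mu0`, `sigma0`,
#'   `mu1`, `sigma1`.
#' @return Data frame with columns `parameter`, `lower`, `upper`.
#' @export
estimate_supports <- function(fit) {
  ann <- if (inherits(fit, "ddm_vb_fit")) fit$annotators else fit
  ann <- as_annotator_frame(ann)
  params <- c("mu0", "mu1", "sigma0", "sigma1")
  data.frame(parameter = params,
             lower = vapply(params, function(p) min(ann[[p]]), numeric(1)),
             upper = vapply(params, function(p) max(ann[[p]]), numeric(1)),
             row.names = NULL)
}

#' @export
print.ddm_vb_fit <- function(x, ...) {
  cat("ddm_vb_fit (method ", x$method, "): ", length(x$q), " items, ",
      nrow(x$annotators), " annotators\n", sep = "")
  cat("  iterations:", x$iterations,
      if (x$converged) "(ELBO change below tolerance)" else "(hard cap)", "\n")
  cat("  final ELBO objective:", format(x$elbo_trace[length(x$elbo_trace)]),
      "\n")
  if (x$rescaled) cat("  parameters rescaled to observed reaction times\n")
  invisible(x)
}
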