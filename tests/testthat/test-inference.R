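# Variational inference: likelihood forms, ELBO, penalty, gradients,
# gradient ascent, reaction-time integration, support estimation.

test_that("constraint penalty: direct values, containment shape, validation", {
  # direct evaluation of -e^(beta (max - 1)) - e^(-beta min)
  expect_equal(constraint_penalty(0.5, beta = 30),
               -exp(30 * (0.5 - 1)) - exp(-30 * 0.5), tolerance = 1e-15)
  expect_equal(constraint_penalty(0.5, beta = 30), -2 * exp(-15),
               tolerance = 1e-12)
  expect_equal(constraint_penalty(0, beta = 30), -exp(-30) - 1,
               tolerance = 1e-15)
  # near zero well inside the unit interval, blowing up outside
  expect_gt(constraint_penalty(c(0.3, 0.5, 0.7)), -1e-3)
  expect_lt(constraint_penalty(c(0.3, 1.4)), -1e4)
  # monotone non-increasing as the maximum crosses 1
  v <- seq(0.9, 1.5, by = 0.1)
  pen <- vapply(v, function(m) constraint_penalty(c(0.5, m)), numeric(1))
  expect_true(all(diff(pen) < 0))
  # configurable base
  expect_equal(constraint_penalty(0.5, beta = 30, base = 2),
               -2^(-15) - exp(-15), tolerance = 1e-15)
  expect_error(constraint_penalty(numeric(0)), "non-empty")
})

test_that("log-likelihood matches scalar hand computation in both forms", {
  set.seed(41)
  n <- 2; k <- 2
  y <- matrix(c(1L, 0L, 0L, 1L), n, k)
  ann <- data.frame(mu0 = c(0.31, 0.18), sigma0 = c(0.62, 0.81),
                    mu1 = c(0.44, 0.27), sigma1 = c(0.55, 0.73))
  p <- c(0.3, 0.8)
  s0 <- plogis(2 * ann$mu0 / ann$sigma0^2)
  s1 <- plogis(2 * ann$mu1 / ann$sigma1^2)
  ll_printed <- ll_product <- 0
  for (i in 1:n) {
    acc <- 0; l0 <- 1; l1 <- 1
    for (j in 1:k) {
      b0 <- (1 - s0[j])^y[i, j] * s0[j]^(1 - y[i, j])     # P(y | z = 0)
      b1 <- s1[j]^y[i, j] * (1 - s1[j])^(1 - y[i, j])     # P(y | z = 1)
      acc <- acc + p[i] * b0 + (1 - p[i]) * b1
      l0 <- l0 * b0; l1 <- l1 * b1
    }
    ll_printed <- ll_printed + log(acc)
    ll_product <- ll_product + log(p[i] * l0 + (1 - p[i]) * l1)
  }
  expect_equal(data_log_likelihood(y, p, ann, likelihood_form = "printed"),
               ll_printed, tolerance = 1e-12)
  expect_equal(data_log_likelihood(y, p, ann, likelihood_form = "product"),
               ll_product, tolerance = 1e-12)

  # single annotator, perfect specificity: P(y = 0 | z = 0) -> 1
  y1 <- matrix(0L, 1, 1)
  ann1 <- data.frame(mu0 = 40, sigma0 = 0.5, mu1 = 0.3, sigma1 = 0.7)
  for (form in c("printed", "product")) {
    expect_equal(data_log_likelihood(y1, 1, ann1, likelihood_form = form),
                 0, tolerance = 1e-10)
  }
  # uninformative annotator: every response probability is 0.5
  ann0 <- data.frame(mu0 = 0, sigma0 = 0.7, mu1 = 0, sigma1 = 0.7)
  expect_equal(data_log_likelihood(matrix(1L, 1, 1), 0.5, ann0), log(0.5),
               tolerance = 1e-12)
  expect_error(data_log_likelihood(matrix(numeric(0), 0, 0), numeric(0), ann0),
               "empty")
})

test_that("label-swap symmetry holds for both likelihood forms", {
  set.seed(42)
  n <- 7; k <- 3
  y <- matrix(rbinom(n * k, 1, 0.5), n, k)
  ann <- data.frame(mu0 = runif(k, 0.1, 0.5), sigma0 = runif(k, 0.5, 0.9),
                    mu1 = runif(k, 0.1, 0.5), sigma1 = runif(k, 0.5, 0.9))
  ann_swap <- data.frame(mu0 = ann$mu1, sigma0 = ann$sigma1,
                         mu1 = ann$mu0, sigma1 = ann$sigma0)
  p <- runif(n, 0.05, 0.95)
  for (form in c("printed", "product")) {
    expect_equal(
      data_log_likelihood(y, p, ann, likelihood_form = form),
      data_log_likelihood(1L - y, 1 - p, ann_swap, likelihood_form = form),
      tolerance = 1e-12)
  }
  # the positive_branch flag only changes which condition the weights
  # refer to: complementing the weights leaves the likelihood unchanged
  expect_equal(
    data_log_likelihood(y, p, ann, positive_branch = 0L),
    data_log_likelihood(y, 1 - p, ann, positive_branch = 1L),
    tolerance = 1e-12)
})

test_that("ELBO reduces to the likelihood at q = S(f) and q is coordinatewise optimal there", {
  set.seed(43)
  n <- 8; k <- 3
  y <- matrix(rbinom(n * k, 1, 0.4), n, k)
  ann <- data.frame(mu0 = runif(k, 0.2, 0.5), sigma0 = runif(k, 0.5, 0.9),
                    mu1 = runif(k, 0.2, 0.5), sigma1 = runif(k, 0.5, 0.9))
  f <- runif(n, -2, 2)
  # cross-entropy and entropy cancel exactly when q = S(f)
  expect_equal(elbo_objective(y, plogis(f), f, ann),
               data_log_likelihood(y, plogis(f), ann), tolerance = 1e-10)

  # coordinate-wise maximizer of the objective matches a dense grid
  i <- 3L
  q <- rep(0.5, n)
  qgrid <- seq(1e-5, 1 - 1e-5, length.out = 100001)
  vals <- vapply(qgrid, function(qq) {
    q2 <- q; q2[i] <- qq
    elbo_objective(y, q2, f, ann)
  }, numeric(1))
  expect_lt(abs(qgrid[which.max(vals)] - plogis(f[i])), 1e-4)
})

test_that("analytic gradients match central finite differences", {
  set.seed(44)
  n <- 6; k <- 3
  y <- matrix(rbinom(n * k, 1, 0.5), n, k)
  for (form in c("product", "printed")) {
    for (with_rt in c(FALSE, TRUE)) {
      ctl <- vb_control(likelihood_form = form, lambda = 1)
      par <- random_vb_state(n, k, seed = 100 + with_rt)
      rtsum <- NULL
      if (with_rt) {
        rtsum <- rt_summary(matrix(runif(n * k, 0.5, 3), n, k),
                            rbinom(n, 1, 0.5))
      }
      ga <- ddmcrowd:::vb_gradient_full(y, par, ctl, rtsum)
      gn <- fd_gradient(y, par, ctl, rtsum)
      for (blk in names(ga)) {
        rel <- abs(ga[[blk]] - gn[[blk]]) /
          pmax(1e-8, abs(ga[[blk]]), abs(gn[[blk]]))
        expect_lt(max(rel), 1e-4)
      }
    }
  }
})

test_that("gradient ascent increases the objective and keeps parameters interior", {
  ds <- tiny_dataset(seed = 5, n_items = 60, n_annotators = 4)
  for (m in c("plain", "1")) {
    fit <- fit_variational(ds$y, ds$rt, method = m)
    tr <- fit$elbo_trace
    expect_gte(tr[length(tr)], tr[1] - 1e-6)
    ann <- fit$annotators
    expect_true(all(ann$mu0 > 0 & ann$mu0 < 1))
    expect_true(all(ann$mu1 > 0 & ann$mu1 < 1))
    expect_true(all(ann$sigma0 > 0 & ann$sigma0 < 1))
    expect_true(all(ann$sigma1 > 0 & ann$sigma1 < 1))
    expect_true(all(fit$q > 0 & fit$q < 1))
    expect_gte(fit$iterations, 300L)
  }
  # deterministic rerun: the optimizer uses no randomness
  f1 <- fit_variational(ds$y, ds$rt, method = "2")
  f2 <- fit_variational(ds$y, ds$rt, method = "2")
  expect_identical(f1, f2)
})

test_that("a highly reliable annotator pool lets q recover the truth exactly", {
  cfg <- experiment_config(n_items = 50, n_annotators = 1,
                           mu0_support = c(5, 5), sigma0_support = c(0.5, 0.5),
                           mu1_support = c(5, 5), sigma1_support = c(0.5, 0.5))
  ds <- simulate_experiment(cfg, seed = 6)
  expect_identical(as.integer(ds$y[, 1]), ds$items$z)  # labels are perfect
  fit <- fit_variational(ds$y, ds$rt, method = "plain")
  expect_identical(predicted_labels(fit), ds$items$z)
})

test_that("reaction-time regularizer: zero at match, inert at lambda 0, validation", {
  ann <- data.frame(mu0 = c(0.3, 0.2), sigma0 = c(0.7, 0.6),
                    mu1 = c(0.4, 0.25), sigma1 = c(0.8, 0.55))
  rtsum <- data.frame(
    annotator = rep(1:2, 2), condition = rep(0:1, each = 2),
    mean_rt = c(expected_decision_time(ann$mu0, ann$sigma0),
                expected_decision_time(ann$mu1, ann$sigma1)),
    n_items = 10L)
  class(rtsum) <- c("rt_summary", "data.frame")
  expect_equal(rt_regularizer(ann, rtsum, lambda = 1), 0, tolerance = 1e-12)
  # nonzero deviation, scaled by lambda
  rtsum2 <- rtsum; rtsum2$mean_rt <- rtsum2$mean_rt + 0.5
  expect_equal(rt_regularizer(ann, rtsum2, lambda = 2),
               2 * rt_regularizer(ann, rtsum2, lambda = 1), tolerance = 1e-12)
  expect_lt(rt_regularizer(ann, rtsum2, lambda = 1), 0)
  expect_error(rt_regularizer(ann, rtsum, lambda = -1), "non-negative")

  # lambda = 0 makes method 1 coincide with plain ascent
  ds <- tiny_dataset(seed = 7, n_items = 40, n_annotators = 3)
  f0 <- fit_variational(ds$y, ds$rt, method = "1",
                        control = vb_control(lambda = 0))
  fp <- fit_variational(ds$y, ds$rt, method = "plain",
                        control = vb_control(lambda = 0))
  expect_equal(f0$q, fp$q, tolerance = 1e-12)
  expect_equal(f0$annotators$mu0, fp$annotators$mu0, tolerance = 1e-12)
})

test_that("reaction-time information pulls drift estimates toward the truth", {
  # single annotator with known parameters; labels alone identify only
  # mu / sigma^2, reaction times pin the scale
  err_plain <- err_m1 <- numeric(20)
  for (s in 1:20) {
    items <- generate_items(150, seed = derive_seed(s, 1))
    ann <- data.frame(annotator_id = 1L, mu0 = 0.3, sigma0 = 0.7,
                      mu1 = 0.3, sigma1 = 0.7)
    ds <- annotate_dataset(items, ann, dt = 0.01, seed = derive_seed(s, 2))
    fp <- fit_variational(ds$y, ds$rt, "plain")
    f1 <- fit_variational(ds$y, ds$rt, "1")
    err_plain[s] <- mean(abs(c(fp$annotators$mu0, fp$annotators$mu1) - 0.3))
    err_m1[s] <- mean(abs(c(f1$annotators$mu0, f1$annotators$mu1) - 0.3))
  }
  expect_lt(mean(err_m1), mean(err_plain))
  expect_gte(sum(err_m1 < err_plain), 13L)
})

test_that("rescaling to reaction times preserves accuracy and matches mean RTs exactly", {
  ds <- tiny_dataset(seed = 8, n_items = 80, n_annotators = 4)
  fit <- fit_variational(ds$y, ds$rt, method = "plain")
  before <- fit$annotators
  fit2 <- rescale_by_rt(fit, ds$rt)
  after <- fit2$annotators
  # sensitivities/specificities invariant to machine precision
  expect_equal(after$sensitivity, before$sensitivity, tolerance = 1e-12)
  expect_equal(after$specificity, before$specificity, tolerance = 1e-12)
  # model-implied expected decision times now equal the observed means
  cond <- ddmcrowd:::assign_condition(fit$q, fit$control$positive_branch)
  rtsum <- rt_summary(ds$rt, cond)
  m <- ddmcrowd:::rt_summary_matrices(rtsum, 4)
  for (j in 1:4) {
    if (m$n_items[j, 1] > 0) {
      expect_equal(expected_decision_time(after$mu0[j], after$sigma0[j]),
                   m$mean_rt[j, 1], tolerance = 1e-10)
    }
    if (m$n_items[j, 2] > 0) {
      expect_equal(expected_decision_time(after$mu1[j], after$sigma1[j]),
                   m$mean_rt[j, 2], tolerance = 1e-10)
    }
  }
  # an already matched fit is left unchanged
  fit3 <- rescale_by_rt(fit2, ds$rt)
  expect_equal(fit3$annotators$mu0, after$mu0, tolerance = 1e-10)

  # a deliberately mis-scaled estimate on the accuracy ridge is pulled back
  # to the generating parameters (200 items, truth (0.3, 0.7))
  items <- generate_items(200, seed = 9)
  ann <- data.frame(annotator_id = 1L, mu0 = 0.3, sigma0 = 0.7,
                    mu1 = 0.3, sigma1 = 0.7)
  dsm <- annotate_dataset(items, ann, dt = 0.01, seed = 10)
  mis <- fit_variational(dsm$y, dsm$rt, method = "plain")
  mis$q <- ifelse(items$z == 0L, 1 - 1e-6, 1e-6)  # perfect assignment
  # (0.6, 0.99) sits on the same accuracy ridge as (0.3, 0.7): c = 2
  mis$annotators$mu0 <- 0.6; mis$annotators$sigma0 <- 0.99
  mis$annotators$mu1 <- 0.6; mis$annotators$sigma1 <- 0.99
  res <- rescale_by_rt(mis, dsm$rt)
  # tolerance: 3 SE of the mean-reaction-time-driven scale (computed from
  # the observed spread) plus the O(sqrt(dt)) bias of observed Euler RTs
  tol_scale <- function(rt_cond) {
    3 * sd(rt_cond) / (sqrt(length(rt_cond)) * mean(rt_cond)) +
      2 * 0.5826 * 0.7 * sqrt(0.01)
  }
  rt0 <- dsm$rt[items$z == 0L, 1]; rt1 <- dsm$rt[items$z == 1L, 1]
  expect_lt(abs(res$annotators$mu0 - 0.3), 0.3 * tol_scale(rt0))
  expect_lt(abs(res$annotators$mu1 - 0.3), 0.3 * tol_scale(rt1))
  expect_lt(abs(res$annotators$sigma0 - 0.7), 0.5 * 0.7 * tol_scale(rt0))
})

test_that("support estimation takes per-parameter extremes of the recovered pool", {
  ann <- data.frame(mu0 = c(0.2, 0.4, 0.3), sigma0 = c(0.5, 0.6, 0.55),
                    mu1 = c(0.15, 0.35, 0.25), sigma1 = c(0.7, 0.8, 0.75))
  sup <- estimate_supports(ann)
  expect_identical(sup$lower[sup$parameter == "mu0"], 0.2)
  expect_identical(sup$upper[sup$parameter == "mu0"], 0.4)
  expect_true(all(sup$lower <= sup$upper))
  one <- estimate_supports(ann[1, ])
  expect_identical(one$lower, one$upper)

  # recovered supports overlap the generating boxes on a replicate
  cfg <- experiment_preset("exp1")
  ds <- simulate_experiment(cfg, seed = 11)
  fit <- fit_variational(ds$y, ds$rt, method = "2")
  sup <- estimate_supports(fit)
  overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  expect_true(overlaps(unlist(sup[sup$parameter == "mu0", c("lower", "upper")]),
                       c(0.1, 0.5)))
  expect_true(overlaps(unlist(sup[sup$parameter == "sigma0", c("lower", "upper")]),
                       c(0.5, 0.9)))
})

test_that("input validation: missing reaction times and malformed labels", {
  ds <- tiny_dataset(seed = 12, n_items = 20, n_annotators = 2)
  expect_error(fit_variational(ds$y, NULL, method = "1"),
               "requires reaction times")
  expect_error(fit_variational(ds$y, NULL, method = "2"),
               "requires reaction times")
  expect_error(fit_variational(matrix(2L, 3, 2), method = "plain"), "0/1")
  expect_error(fit_variational(ds$y, abs(ds$rt) * -1, method = "1"),
               "positive")
})
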