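# Metric grid and experiment orchestration: parameter-recovery MSEs,
# annotator sensitivity/specificity MSEs, crowdsourced-label metrics and
# held-out Gaussian-process classification metrics, plus a majority-vote
# baseline.

#' Mean-squared error between true and estimated parameter vectors
#'
#' @param true,est Numeric vectors of equal length.
#' @return Mean of squared differences (>= 0).
#' @export
#' @examples
#' parameter_mse(c(0.1, 0.3), c(0.2, 0.3))  # 0.005
parameter_mse <- function(true, est) {
  if (length(true) != length(est)) {
    stop("`true` and `est` must have equal length", call. = FALSE)
  }
  stopifnot(is.numeric(true), is.numeric(est))
  mean((true - est)^2)
}

#' Accuracy, sensitivity and specificity of binary predictions
#'
#' Sensitivity is computed on the `truth == 1` class and specificity on the
#' `truth == 0` class. When a class is absent from `truth` the corresponding
#' rate is undefined and reported as `NA` (never as 0).
#'
#' @param pred,truth Integer 0/1 vectors of equal length.
#' @return Named numeric vector `c(accuracy, sensitivity, specificity)` in
#'   percent.
#' @export
#' @examples
#' classification_metrics(c(1, 0, 1), c(1, 0, 0))
classification_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  stopifnot(all(pred %in% c(0, 1)), all(truth %in% c(0, 1)))
  acc <- 100 * mean(pred == truth)
  sens <- if (any(truth == 1)) 100 * mean(pred[truth == 1] == 1) else NA_real_
  spec <- if (any(truth == 0)) 100 * mean(pred[truth == 0] == 0) else NA_real_
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' Majority-vote label aggregation
#'
#' Assigns each item the most frequent annotator label; exact ties resolve
#' to class 0.
#'
#' @param y Integer label matrix (items x annotators), entries 0/1.
#' @return Integer vector of aggregated labels.
#' @export
majority_vote <- function(y) {
  y <- check_label_matrix(y)
  ifelse(rowMeans(y) > 0.5, 1L, 0L)
}

#' Run one full synthetic crowdsourcing experiment
#'
#' Generates items, draws an annotator pool, simulates labels and reaction
#' times, aggregates the labels (variational method "1" or "2", or the
#' majority-vote baseline), trains the Gaussian-process classifier, and
#' evaluates on a fresh uniform test sample. The dataset and the test
#' sample depend only on `cfg` and `seed`, not on `method`, so methods can
#' be compared on identical data within a seed.
#'
#' For the baseline, the GP is trained on the majority labels encoded as
#' +1/-1 latent targets; parameter-recovery MSEs are undefined (`NA`).
#'
#' @param cfg An [experiment_config()].
#' @param method `"1"`, `"2"` or `"baseline"`.
#' @param n_test Size of the held-out uniform test sample (default 10000).
#' @param seed Root seed for the replicate.
#' @param control A [vb_control()] for the variational methods.
#' @return Object of class `ddm_eval_report`: parameter MSEs (`mse`, per
#'   condition), `mse_sensitivity`, `mse_specificity`, crowdsourced-label
#'   metrics (`crowd`), Gaussian-process classifier metrics (`gp`), and the
#'   generating/estimated annotator tables.
#' @export
run_experiment <- function(cfg, method = c("1", "2", "baseline"),
                           n_test = 10000L, seed = 1L,
                           control = vb_control()) {
  stopifnot(inherits(cfg, "experiment_config"))
  method <- match.arg(as.character(method), c("1", "2", "baseline"))
  items <- generate_items(cfg$n_items, cfg$grid, seed = derive_seed(seed, 1001))
  ann_true <- sample_annotators(cfg, seed = derive_seed(seed, 1002))
  ds <- annotate_dataset(items, ann_true, dt = cfg$dt,
                         seed = derive_seed(seed, 1003))
  test <- generate_items(n_test, cfg$grid, seed = derive_seed(seed, 1004))
  gp_seed <- derive_seed(seed, 1005)

  true_rates <- annotator_sensitivity_specificity(ann_true)
  if (method == "baseline") {
    zhat <- majority_vote(ds$y)
    gp <- fit_gp(as.matrix(items[, c("x1", "x2")]), ifelse(zhat == 1L, 1, -1),
                 seed = gp_seed)
    gp_pred <- predict_label(gp, as.matrix(test[, c("x1", "x2")]),
                             positive_branch = 1L)
    mse <- c(mu0 = NA_real_, mu1 = NA_real_,
             sigma0 = NA_real_, sigma1 = NA_real_)
    mse_sens <- NA_real_
    mse_spec <- NA_real_
    ann_est <- NULL
    fit <- NULL
  } else {
    fit <- fit_variational(ds$y, ds$rt, method = method, control = control)
    zhat <- predicted_labels(fit)
    gp <- fit_gp(as.matrix(items[, c("x1", "x2")]), fit$f, seed = gp_seed)
    gp_pred <- predict_label(gp, as.matrix(test[, c("x1", "x2")]),
                             positive_branch = control$positive_branch)
    ann_est <- fit$annotators
    mse <- c(mu0 = parameter_mse(ann_true$mu0, ann_est$mu0),
             mu1 = parameter_mse(ann_true$mu1, ann_est$mu1),
             sigma0 = parameter_mse(ann_true$sigma0, ann_est$sigma0),
             sigma1 = parameter_mse(ann_true$sigma1, ann_est$sigma1))
    mse_sens <- parameter_mse(true_rates$sensitivity, ann_est$sensitivity)
    mse_spec <- parameter_mse(true_rates$specificity, ann_est$specificity)
  }
  structure(list(
    method = method, seed = seed, n_test = as.integer(n_test),
    mse = mse, mse_sensitivity = mse_sens, mse_specificity = mse_spec,
    crowd = classification_metrics(zhat, items$z),
    gp = classification_metrics(gp_pred$z_star, test$z),
    annotators_true = ann_true, annotators_est = ann_est,
    fit = fit, config = cfg
  ), class = "ddm_eval_report")
}

#' Run replicated experiments over several seeds
#'
#' @param cfg An [experiment_config()].
#' @param method `"1"`, `"2"` or `"baseline"`.
#' @param seeds Integer vector of replicate seeds.
#' @param n_test Held-out test-sample size per replicate.
#' @param control A [vb_control()].
#' @return List of class `ddm_eval_replicates` with the individual reports
#'   and a `summary` data frame of per-metric means and standard deviations
#'   across seeds.
#' @export
run_replicates <- function(cfg, method, seeds, n_test = 10000L,
                           control = vb_control()) {
  reports <- lapply(seeds, function(s) {
    run_experiment(cfg, method = method, n_test = n_test, seed = s,
                   control = control)
  })
  structure(list(reports = reports, summary = aggregate_reports(reports),
                 method = method, seeds = seeds),
            class = "ddm_eval_replicates")
}

# flatten one report into a named metric vector
report_metrics <- function(report) {
  c(stats::setNames(report$mse, paste0("mse_", names(report$mse))),
    mse_sensitivity = report$mse_sensitivity,
    mse_specificity = report$mse_specificity,
    stats::setNames(report$crowd, paste0("crowd_", names(report$crowd))),
    stats::setNames(report$gp, paste0("gp_", names(report$gp))))
}

#' Aggregate replicate reports into a metric summary table
#'
#' @param reports List of `ddm_eval_report` objects.
#' @return Data frame with columns `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_reports <- function(reports) {
  mat <- do.call(rbind, lapply(reports, report_metrics))
  data.frame(metric = colnames(mat),
             mean = colMeans(mat),
             sd = apply(mat, 2, sd),
             n = nrow(mat), row.names = NULL)
}

#' @export
print.ddm_eval_report <- function(x, ...) {
  cat("ddm_eval_report (method ", x$method, ", seed ", x$seed, ")\n", sep = "")
  if (!all(is.na(x$mse))) {
    cat("  parameter MSE:",
        paste(sprintf("%s=%.4f", names(x$mse), x$mse), collapse = ", "), "\n")
    cat(sprintf("  MSE sensitivity %.4f, specificity %.4f\n",
                x$mse_sensitivity, x$mse_specificity))
  }
  cat(sprintf("  crowdsourced labels: acc %.1f%%, sens %.1f%%, spec %.1f%%\n",
              x$crowd[1], x$crowd[2], x$crowd[3]))
  cat(sprintf("  GP classifier (%d pts): acc %.1f%%, sens %.1f%%, spec %.1f%%\n",
              x$n_test, x$gp[1], x$gp[2], x$gp[3]))
  invisible(x)
}

#' @export
print.ddm_eval_replicates <- function(x, ...) {
  cat("ddm_eval_replicates: method", x$method, "over", length(x$seeds),
      "seeds\n")
  print(x$summary, digits = 4)
  invisible(x)
}
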