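# Closed-form quantities for the symmetric-boundary drift-diffusion model.
#
# The evidence process is dX = mu dt + sigma dW, started at X(0) = 0, with
# absorbing boundaries fixed at +1 and -1 and no offset. Under this
# parameterization the probability of absorption at +1 and the expected
# absorption time have closed forms (logistic hit probability, and the
# optional-stopping identity E[X(tau)] = mu E[tau]).

check_diffusion <- function(diffusion) {
  if (!is.numeric(diffusion) || length(diffusion) == 0L ||
      any(!is.finite(diffusion)) || any(diffusion <= 0)) {
    stop("`diffusion` must be strictly positive and finite", call. = FALSE)
  }
  invisible(diffusion)
}

check_drift <- function(drift) {
  if (!is.numeric(drift) || length(drift) == 0L || any(!is.finite(drift))) {
    stop("`drift` must be numeric and finite", call. = FALSE)
  }
  invisible(drift)
}

#' Probability that a drift-diffusion decision is correct
#'
#' For an evidence process `dX = mu dt + sigma dW` started at 0 with
#' absorbing boundaries at +1 (correct) and -1 (incorrect), the probability
#' of absorption at the upper boundary is `S(2 mu / sigma^2)`, where `S` is
#' the logistic function. Applied to an annotator's condition-specific
#' parameters this is the annotator's sensitivity (condition `z = 1`) or
#' specificity (condition `z = 0`).
#'
#' The value depends on `(mu, sigma)` only through `mu / sigma^2`: the map
#' `(mu, sigma) -> (c mu, sqrt(c) sigma)` leaves it unchanged while scaling
#' expected decision times by `1 / c`, which is what makes accuracy and
#' reaction time separately controllable.
#'
#' @param drift Drift rate(s) `mu` (evidence units per second; any sign).
#' @param diffusion Diffusion rate(s) `sigma` (> 0, evidence units per
#'   square-root second). Recycled against `drift`.
#' @return Probability in (0, 1), vectorized over the inputs.
#' @seealso [expected_decision_time()], [annotator_sensitivity_specificity()]
#' @export
#' @examples
#' correct_probability(0, 1)        # symmetric random walk: 0.5
#' correct_probability(0.3, 0.7)    # ~ 0.773
correct_probability <- function(drift, diffusion) {
  check_drift(drift)
  check_diffusion(diffusion)
  stats::plogis(2 * drift / diffusion^2)
}

#' Expected decision time of a drift-diffusion decision
#'
#' Expected first-passage time of the evidence process to either boundary.
#' For `mu != 0` the optional stopping theorem gives
#' `E[tau] = E[X(tau)] / mu = (2 p - 1) / mu` with
#' `p = correct_probability(mu, sigma)`. For `mu = 0` the driftless
#' absorption formula `boundary^2 / sigma^2 = 1 / sigma^2` is used; it is the
#' continuous limit of the drifted expression, and the implementation
#' switches to it for `|mu| < 1e-8` so the function is continuous in `mu`.
#'
#' @inheritParams correct_probability
#' @return Expected decision time in seconds (strictly positive), vectorized.
#' @export
#' @examples
#' expected_decision_time(0, 1)      # 1 second
#' expected_decision_time(0.3, 0.7)  # ~ 1.82 seconds
expected_decision_time <- function(drift, diffusion) {
  check_drift(drift)
  check_diffusion(diffusion)
  p <- correct_probability(drift, diffusion)
  # recycle explicitly so ifelse() keeps full length
  rec <- drift + 0 * diffusion
  sig <- diffusion + 0 * drift
  ifelse(abs(rec) < 1e-8, 1 / sig^2, (2 * p - 1) / rec)
}

#' Analytic sensitivity and specificity of drift-diffusion annotators
#'
#' Sensitivity is the correct-response probability under condition `z = 1`,
#' `S(2 mu1 / sigma1^2)`; specificity the one under `z = 0`,
#' `S(2 mu0 / sigma0^2)`.
#'
#' @param annotators Data frame with numeric columns `mu0`, `sigma0`, `mu1`,
#'   `sigma1` (one row per annotator), as returned by [sample_annotators()]
#'   or stored in a fitted [fit_variational()] object.
#' @return Data frame with columns `sensitivity` and `specificity` in (0, 1).
#' @export
#' @examples
#' ann <- data.frame(mu0 = 0.3, sigma0 = 0.7, mu1 = 0.3, sigma1 = 0.7)
#' annotator_sensitivity_specificity(ann)
annotator_sensitivity_specificity <- function(annotators) {
  annotators <- as_annotator_frame(annotators)
  data.frame(
    sensitivity = correct_probability(annotators$mu1, annotators$sigma1),
    specificity = correct_probability(annotators$mu0, annotators$sigma0)
  )
}

# validate/coerce an annotator parameter table
as_annotator_frame <- function(annotators) {
  need <- c("mu0", "sigma0", "mu1", "sigma1")
  if (!is.data.frame(annotators) && is.list(annotators)) {
    annotators <- as.data.frame(annotators[intersect(names(annotators),
                                                     c("annotator_id", need))])
  }
  if (!is.data.frame(annotators) || !all(need %in% names(annotators))) {
    stop("`annotators` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  check_drift(annotators$mu0); check_drift(annotators$mu1)
  check_diffusion(annotators$sigma0); check_diffusion(annotators$sigma1)
  annotators
}
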