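# Internal helpers shared across modules.

logit <- function(p) log(p) - log1p(-p)

# derivative of the logistic function, numerically safe for large |x|
dlogis_dx <- function(x) {
  s <- stats::plogis(x)
  s * (1 - s)
}

clip_unit <- function(x, eps = 1e-9) pmin(pmax(x, eps), 1 - eps)

#' Derive a reproducible child seed from a root seed
#'
#' Deterministically maps a root seed and an integer stream id to a new seed
#' so that independent parts of a pipeline (item sampling, each annotator's
#' label stream, the held-out test grid, hyperparameter restarts, ...)
#' consume separate random streams. Derived seeds for streams `1..j` do not
#' change when further streams are added, so e.g. enlarging an annotator
#' pool leaves the labels of existing annotators untouched.
#'
#' @param seed Integer root seed.
#' @param id Integer stream identifier (non-negative).
#' @return A single integer seed in `[1, 2^31 - 2]`, usable with `set.seed()`.
#' @export
#' @examples
#' derive_seed(1, 1)
#' derive_seed(1, 2)
derive_seed <- function(seed, id) {
  stopifnot(length(seed) == 1L, length(id) == 1L,
            is.finite(seed), is.finite(id))
  m <- 2147483647 # 2^31 - 1; all products below stay exact in doubles
  s <- (abs(as.double(seed)) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + (abs(as.double(id)) %% m) * 7919) %% m
  as.integer((s %% (m - 2)) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
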