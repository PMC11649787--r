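# File-format contracts: datasets as a pair of CSV files (items.csv,
# labels.csv) plus a provenance JSON, inference results and evaluation
# reports as versioned JSON, GP models as JSON + CSV. CSV dialect: comma,
# UTF-8, header row, '.' decimal; floats serialized with 17 significant
# digits so that values round-trip exactly.

RESULT_SCHEMA_VERSION <- "1.0"

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_csv17 <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

#' Write a crowd dataset to a directory
#'
#' Writes `items.csv` (`item_id`, `x1`, `x2`, `z`), `labels.csv`
#' (`item_id`, `annotator_id`, `y`, `rt_seconds`, long format),
#' `provenance.json` (time step, root seed, shapes) and, when the
#' generating annotator parameters are known, `annotators.csv`. Rewriting
#' the same dataset produces identical files.
#'
#' @param ds A `crowd_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "crowd_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_csv17(ds$items, file.path(dir, "items.csv"))
  n <- nrow(ds$y); k <- ncol(ds$y)
  labels <- data.frame(
    item_id = rep(ds$items$item_id, times = k),
    annotator_id = rep(seq_len(k), each = n),
    y = as.integer(ds$y),
    rt_seconds = if (is.null(ds$rt)) rep(NA_real_, n * k) else as.double(ds$rt)
  )
  write_csv17(labels, file.path(dir, "labels.csv"))
  if (!is.null(ds$annotators)) {
    write_csv17(ds$annotators, file.path(dir, "annotators.csv"))
  }
  prov <- list(format = "ddmcrowd-dataset", version = RESULT_SCHEMA_VERSION,
               dt = ds$dt, seed = ds$seed,
               n_items = n, n_annotators = k,
               has_annotator_parameters = !is.null(ds$annotators))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a crowd dataset from a directory
#'
#' Validates the schema of `items.csv` and `labels.csv` written by
#' [write_dataset()]: labels must be 0/1, reaction times (when present)
#' strictly positive, and every (item, annotator) pair present exactly
#' once. Violations raise errors naming the offending column and row.
#'
#' @param dir Directory containing the dataset files.
#' @return A `crowd_dataset`.
#' @export
read_dataset <- function(dir) {
  items_path <- file.path(dir, "items.csv")
  labels_path <- file.path(dir, "labels.csv")
  if (!file.exists(items_path) || !file.exists(labels_path)) {
    stop("`", dir, "` does not contain items.csv and labels.csv",
         call. = FALSE)
  }
  items <- read.csv(items_path)
  need <- c("item_id", "x1", "x2", "z")
  if (!all(need %in% names(items))) {
    stop("items.csv must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  labels <- read.csv(labels_path)
  needl <- c("item_id", "annotator_id", "y")
  if (!all(needl %in% names(labels))) {
    stop("labels.csv must have columns ", paste(needl, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(labels$y %in% c(0L, 1L)))
  if (length(bad) > 0L) {
    stop("labels.csv column `y` must be 0/1; first violation at row ",
         bad[1], call. = FALSE)
  }
  has_rt <- "rt_seconds" %in% names(labels) && !all(is.na(labels$rt_seconds))
  if (has_rt) {
    bad <- which(!is.finite(labels$rt_seconds) | labels$rt_seconds <= 0)
    if (length(bad) > 0L) {
      stop("labels.csv column `rt_seconds` must be positive; ",
           "first violation at row ", bad[1], call. = FALSE)
    }
  }
  n <- nrow(items)
  ann_ids <- sort(unique(labels$annotator_id))
  k <- length(ann_ids)
  if (nrow(labels) != n * k) {
    stop("labels.csv must contain one row per (item, annotator) pair",
         call. = FALSE)
  }
  ii <- match(labels$item_id, items$item_id)
  jj <- match(labels$annotator_id, ann_ids)
  if (anyNA(ii)) {
    stop("labels.csv references item_id values missing from items.csv",
         call. = FALSE)
  }
  y <- matrix(NA_integer_, n, k)
  y[cbind(ii, jj)] <- as.integer(labels$y)
  rt <- NULL
  if (has_rt) {
    rt <- matrix(NA_real_, n, k)
    rt[cbind(ii, jj)] <- labels$rt_seconds
  }
  colnames(y) <- paste0("a", seq_len(k))
  if (!is.null(rt)) colnames(rt) <- colnames(y)
  annotators <- NULL
  dt <- NA_real_; seed <- NA_integer_
  prov_path <- file.path(dir, "provenance.json")
  if (file.exists(prov_path)) {
    prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE)
    dt <- prov$dt %||% NA_real_
    seed <- prov$seed %||% NA_integer_
  }
  ann_path <- file.path(dir, "annotators.csv")
  if (file.exists(ann_path)) {
    annotators <- read.csv(ann_path)
  }
  crowd_dataset(items, annotators, y, rt, dt = dt, seed = seed)
}

#' Serialize a variational fit to JSON
#'
#' Versioned schema: per-annotator parameter estimates with analytic
#' sensitivity/specificity, per-item posterior probabilities and latent
#' values, the ELBO trace, and the settings used.
#'
#' @param fit A `ddm_vb_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_result <- function(fit, path) {
  stopifnot(inherits(fit, "ddm_vb_fit"))
  out <- list(
    format = "ddmcrowd-result", version = RESULT_SCHEMA_VERSION,
    method = fit$method,
    positive_branch = fit$control$positive_branch,
    likelihood_form = fit$control$likelihood_form,
    rescaled = fit$rescaled,
    iterations = fit$iterations,
    converged = fit$converged,
    annotators = fit$annotators,
    items = data.frame(q = fit$q, f = fit$f),
    elbo_trace = fit$elbo_trace
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized variational fit
#'
#' @param path JSON path written by [write_result()].
#' @return A `ddm_vb_fit` (optimization settings restored from the file;
#'   fields not serialized keep their defaults).
#' @export
read_result <- function(path) {
  res <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(res$format) || res$format != "ddmcrowd-result") {
    stop("`", path, "` is not a ddmcrowd result file", call. = FALSE)
  }
  need <- c("annotators", "items", "elbo_trace", "method")
  missing <- setdiff(need, names(res))
  if (length(missing) > 0L) {
    stop("result file is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  control <- vb_control(
    likelihood_form = res$likelihood_form %||% "printed",
    positive_branch = res$positive_branch %||% 0L
  )
  structure(list(q = res$items$q, f = res$items$f,
                 annotators = as.data.frame(res$annotators),
                 elbo_trace = res$elbo_trace,
                 iterations = res$iterations %||% NA_integer_,
                 converged = isTRUE(res$converged),
                 method = res$method, control = control,
                 rescaled = isTRUE(res$rescaled)),
            class = "ddm_vb_fit")
}

#' Persist a fitted GP model
#'
#' Hyperparameters go to `<prefix>.json`; training inputs and latent
#' targets to `<prefix>_training.csv`.
#'
#' @param model A `ddm_gp`.
#' @param prefix Path prefix for the two files.
#' @return `prefix`, invisibly.
#' @export
write_gp <- function(model, prefix) {
  stopifnot(inherits(model, "ddm_gp"))
  meta <- list(format = "ddmcrowd-gp", version = RESULT_SCHEMA_VERSION,
               amplitude = model$amplitude, lengthscale = model$lengthscale,
               noise = model$noise, logml = model$logml)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  train <- as.data.frame(model$x)
  names(train) <- paste0("x", seq_len(ncol(model$x)))
  train$f <- model$f
  write_csv17(train, paste0(prefix, "_training.csv"))
  invisible(prefix)
}

#' Load a persisted GP model
#'
#' @param prefix Path prefix used with [write_gp()].
#' @return A `ddm_gp` ready for prediction.
#' @export
read_gp <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (is.null(meta$format) || meta$format != "ddmcrowd-gp") {
    stop("`", prefix, ".json` is not a ddmcrowd GP file", call. = FALSE)
  }
  train <- read.csv(paste0(prefix, "_training.csv"))
  f <- train$f
  x <- as.matrix(train[, setdiff(names(train), "f"), drop = FALSE])
  d2 <- as.matrix(dist(x))^2
  K <- meta$amplitude * exp(-d2 / (2 * meta$lengthscale^2))
  diag(K) <- diag(K) + meta$noise
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), f))
  structure(list(x = x, f = f, amplitude = meta$amplitude,
                 lengthscale = meta$lengthscale, noise = meta$noise,
                 alpha = alpha, logml = meta$logml, bounds = NULL),
            class = "ddm_gp")
}
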