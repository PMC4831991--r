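#' Generalised logarithm
#'
#' `glog(y, lambda) = ln(y + sqrt(y^2 + lambda))`. With `lambda = 1` this is
#' the inverse hyperbolic sine; as `lambda -> 0` it approaches
#' `ln(2y)` for positive `y`. Monotone increasing in `y` for every
#' `lambda >= 0`.
#'
#' @param y numeric values (any real).
#' @param lambda non-negative offset parameter (intensity-squared units).
#' @return Transformed values.
#' @export
glog <- function(y, lambda) {
  stopifnot(lambda >= 0)
  log(y + sqrt(y^2 + lambda))
}

#' Estimate the glog offset from technical replicates
#'
#' Chooses the `lambda` that minimises the technical (replicate) variation
#' of the glog-transformed QC samples. The naive sum of transformed
#' variances is degenerate (it tends to 0 as `lambda` grows, flattening
#' everything), so the objective is Jacobian-normalised, as in maximum
#' likelihood for transform-both-sides models:
#' `J(lambda) = SSE(lambda) / GM(lambda)^2`, where `SSE` is the pooled
#' within-feature sum of squared deviations of transformed QC values from
#' their feature means and `GM` is the geometric mean over QC cells of the
#' transform derivative `1 / sqrt(y^2 + lambda)`. Minimised by bounded
#' golden-section search on `log10(lambda)`; deterministic.
#'
#' @param table a `peak_table` containing QC samples (at least 3). Features
#'   with any missing QC cell are dropped from the objective.
#' @param lower,upper optional search bounds for `lambda`; defaults span
#'   `min(y)^2 * 1e-4` to `max(y)^2 * 1e4` over the QC cells used.
#' @return A list of class `glog_params` with elements `lambda`,
#'   `objective`, `trace` (tibble of evaluated points), `n_features_used`.
#' @export
optimize_lambda <- function(table, lower = NULL, upper = NULL) {
  qc <- which(table$samples$is_qc)
  if (length(qc) < 3) stop("need at least 3 QC samples", call. = FALSE)
  Q <- table$intensities[qc, , drop = FALSE]
  keep <- colSums(is.na(Q)) == 0
  if (!any(keep)) stop("no feature has complete QC values", call. = FALSE)
  Q <- Q[, keep, drop = FALSE]

  if (is.null(lower)) lower <- max(min(Q)^2 * 1e-4, 1e-12)
  if (is.null(upper)) upper <- max(Q)^2 * 1e4

  if (all(apply(Q, 2, stats::sd) == 0)) {
    warning("QC replicates have zero variance; lambda is unidentified, ",
            "returning the lower search bound", call. = FALSE)
    return(structure(list(lambda = lower, objective = 0,
                          trace = tibble::tibble(), n_features_used = ncol(Q)),
                     class = "glog_params"))
  }

  trace <- new.env(); trace$pts <- list()
  objective <- function(log10_lambda) {
    lam <- 10^log10_lambda
    Z <- glog(Q, lam)
    sse <- sum(sweep(Z, 2, colMeans(Z))^2)
    mean_log_deriv <- -mean(0.5 * log(Q^2 + lam))
    val <- log(sse) - 2 * mean_log_deriv   # log J(lambda), monotone in J
    trace$pts[[length(trace$pts) + 1L]] <- c(lambda = lam, objective = val)
    val
  }
  opt <- stats::optimize(objective, interval = log10(c(lower, upper)),
                         tol = 1e-6)
  structure(list(
    lambda = 10^opt$minimum,
    objective = opt$objective,
    trace = tibble::as_tibble(do.call(rbind, trace$pts)),
    n_features_used = ncol(Q)
  ), class = "glog_params")
}

#' @export
print.glog_params <- function(x, ...) {
  cat(sprintf("<glog_params> lambda = %.4g (objective %.4g, %d features)\n",
              x$lambda, x$objective, x$n_features_used))
  invisible(x)
}

#' Transform a peak table element-wise
#'
#' Applies one of the closed transformation vocabulary to every observed
#' cell; missing cells stay missing. `glog` requires a `lambda` (a
#' `glog_params` object or a number); `nlog` is the natural logarithm and
#' errors on non-positive values; `IHS` is the inverse hyperbolic sine
#' (identical to glog with `lambda = 1`).
#'
#' @param table a `peak_table`.
#' @param method `"none"`, `"glog"`, `"nlog"` or `"IHS"`.
#' @param lambda glog offset (a number or [optimize_lambda()] result);
#'   required for `method = "glog"`.
#' @return The transformed `peak_table` (values may be any real).
#' @export
transform_table <- function(table, method, lambda = NULL) {
  method <- check_stage(method, "transformation")
  mat <- table$intensities
  out <- switch(method,
    none = return(table),
    glog = {
      if (inherits(lambda, "glog_params")) lambda <- lambda$lambda
      if (is.null(lambda)) stop("glog requires lambda", call. = FALSE)
      glog(mat, lambda)
    },
    nlog = {
      if (any(mat[!is.na(mat)] <= 0)) {
        stop("nlog of non-positive value", call. = FALSE)
      }
      log(mat)
    },
    IHS = glog(mat, 1)
  )
  set_intensities(table, out)
}

#' Scale a peak table feature-wise
#'
#' Centres and scales each feature (column) over its observed cells using
#' the sample standard deviation (n - 1): `auto` divides by the standard
#' deviation, `pareto` by its square root, `range` by max - min, and `vast`
#' is autoscaling additionally multiplied by mean/sd (division by the
#' coefficient of variation, down-weighting noisy features). Features with
#' zero spread are set to all-zero with a warning; `vast` errors when a
#' feature mean is zero.
#'
#' @param table a `peak_table`; every feature needs at least 2 observed
#'   values.
#' @param method `"none"`, `"auto"`, `"pareto"`, `"range"` or `"vast"`.
#' @return The scaled `peak_table`.
#' @export
scale_table <- function(table, method) {
  method <- check_stage(method, "scaling")
  if (method == "none") return(table)
  mat <- table$intensities
  if (any(colSums(!is.na(mat)) < 2)) {
    stop("every feature needs at least 2 observed values to scale",
         call. = FALSE)
  }
  m <- colMeans(mat, na.rm = TRUE)
  s <- apply(mat, 2, stats::sd, na.rm = TRUE)
  spread <- switch(method,
    auto = s,
    pareto = sqrt(s),
    range = apply(mat, 2, function(x) diff(range(x, na.rm = TRUE))),
    vast = s
  )
  if (method == "vast" && any(m == 0)) {
    stop("vast scaling undefined for zero-mean feature", call. = FALSE)
  }
  zero <- spread == 0
  if (any(zero)) {
    warning(sum(zero), " zero-spread feature(s) set to all-zero",
            call. = FALSE)
    spread[zero] <- 1
  }
  out <- sweep(sweep(mat, 2, m), 2, spread, "/")
  if (method == "vast") out <- sweep(out, 2, m / s, "*")
  out[, zero] <- 0
  out[is.na(mat)] <- NA_real_
  set_intensities(table, out)
}
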