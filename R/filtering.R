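#' Fill features absent in a single class
#'
#' For every feature that has no observed value in one class but is observed
#' in at least one other class, the missing cells of the fully-missing class
#' are replaced by half the minimum observed intensity of the whole matrix.
#' A feature absent from a whole class is most plausibly below the limit of
#' detection there, so a small-value fill is used rather than leaving the
#' cells to a generic imputer. Other missing cells are untouched; the
#' operation is idempotent.
#'
#' @param table a `peak_table` with class labels on the non-QC samples.
#' @return The filled `peak_table`.
#' @export
fill_class_absent <- function(table) {
  mat <- table$intensities
  if (all(is.na(mat))) stop("no observed values in table", call. = FALSE)
  half_min <- 0.5 * min(mat, na.rm = TRUE)
  labs <- class_labels(table)
  if (length(labs) < 2) return(table)
  rows_by_class <- lapply(labs, function(l) class_rows(table, l))
  for (j in seq_len(ncol(mat))) {
    n_obs <- vapply(rows_by_class, function(r) sum(!is.na(mat[r, j])),
                    integer(1))
    if (any(n_obs == 0L) && any(n_obs > 0L)) {
      for (k in which(n_obs == 0L)) {
        mat[rows_by_class[[k]], j] <- half_min
      }
    }
  }
  set_intensities(table, mat)
}

#' Filter features and samples by missingness
#'
#' Drops features whose missing fraction exceeds `threshold` (strictly
#' greater than; boundary cases are retained), then drops samples whose
#' missing fraction, computed on the surviving features, exceeds the same
#' threshold. The removal report is attached as attribute `"removed"`.
#'
#' @param table a `peak_table`.
#' @param threshold maximum tolerated missing fraction, in `(0, 1]`
#'   (default 0.20).
#' @param include_qc include QC samples when computing feature missing
#'   fractions (default `TRUE`).
#' @return The filtered `peak_table`; `attr(, "removed")` is a tibble with
#'   columns `id`, `kind`, `missing_fraction`.
#' @export
filter_by_missing <- function(table, threshold = 0.20, include_qc = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  rows <- if (include_qc) seq_len(n_samples(table)) else
    which(!table$samples$is_qc)
  feat_frac <- colMeans(is.na(table$intensities[rows, , drop = FALSE]))
  keep_f <- feat_frac <= threshold
  if (!any(keep_f)) stop("all features removed by missingness filter",
                         call. = FALSE)
  sub <- table$intensities[, keep_f, drop = FALSE]
  samp_frac <- rowMeans(is.na(sub))
  keep_s <- samp_frac <= threshold
  removed <- dplyr::bind_rows(
    tibble::tibble(id = table$features$feature_id[!keep_f], kind = "feature",
                   missing_fraction = unname(feat_frac[!keep_f])),
    tibble::tibble(id = table$samples$sample_id[!keep_s], kind = "sample",
                   missing_fraction = unname(samp_frac[!keep_s]))
  )
  out <- table[keep_s, keep_f]
  attr(out, "removed") <- removed
  out
}

#' Diagnose the structure of missingness
#'
#' Computes, over features, the Pearson correlations of the per-feature
#' missing-value count with m/z, retention time and mean observed response.
#' Correlations near zero support treating the missingness as completely at
#' random. Undefined correlations (e.g. no missing values anywhere, so the
#' count has zero variance) are returned as `NA` with a warning.
#'
#' @param table a `peak_table` with at least 3 features.
#' @return A tibble with one row per predictor (`mz`, `rt`,
#'   `mean_response`) and columns `variable`, `pearson_r`, plus attributes
#'   `"per_feature"` (the per-feature counts tibble) and
#'   `"percent_missing"`.
#' @export
diagnose_missingness <- function(table) {
  if (n_features(table) < 3) stop("need at least 3 features", call. = FALSE)
  miss <- colSums(is.na(table$intensities))
  per_feature <- tibble::tibble(
    feature_id = table$features$feature_id,
    mz = table$features$mz,
    rt = table$features$rt,
    mean_response = colMeans(table$intensities, na.rm = TRUE),
    n_missing = miss
  )
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0 || anyNA(x) || anyNA(y)) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  out <- tibble::tibble(
    variable = c("mz", "rt", "mean_response"),
    pearson_r = c(
      safe_cor(per_feature$mz, miss),
      safe_cor(per_feature$rt, miss),
      safe_cor(per_feature$mean_response, miss)
    )
  )
  if (anyNA(out$pearson_r)) {
    warning("undefined Pearson correlation (zero variance) for: ",
            paste(out$variable[is.na(out$pearson_r)], collapse = ", "),
            call. = FALSE)
  }
  attr(out, "per_feature") <- per_feature
  attr(out, "percent_missing") <- 100 * mean(is.na(table$intensities))
  out
}
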