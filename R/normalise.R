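#' Normalise each sample to a constant sum
#'
#' Divides every observed value in a row (sample) by the row total over
#' observed values and multiplies by 100, so each sample's observed values
#' sum to 100 (unit: percent of total ion signal). Missing cells stay
#' missing and are excluded from the row total by default.
#'
#' @param table a `peak_table`.
#' @param missing_as_zero if `TRUE`, missing cells contribute 0 to the row
#'   total (observed rows then sum to less than 100); default `FALSE`.
#' @return The normalised `peak_table`; `attr(, "factors")` is a tibble of
#'   per-sample factors (`sample_id`, `factor` = row total / 100).
#' @export
normalise_sum <- function(table, missing_as_zero = FALSE) {
  mat <- table$intensities
  totals <- rowSums(mat, na.rm = TRUE)
  if (any(totals <= 0)) {
    stop("sample with no positive observed values cannot be sum-normalised",
         call. = FALSE)
  }
  out <- sweep(mat, 1, totals / 100, "/")
  res <- set_intensities(table, out)
  attr(res, "factors") <- tibble::tibble(
    sample_id = table$samples$sample_id, factor = totals / 100
  )
  res
}

#' Probabilistic quotient normalisation
#'
#' Normalises each sample by the median of its feature-wise quotients
#' against a reference profile. The reference is the per-feature mean over
#' QC samples (observed cells); with no QC samples a per-feature median over
#' all samples is used when `fallback_median = TRUE`. Quotients use only
#' features observed in both the sample and the reference; every observed
#' cell of the sample (QC samples included) is divided by the sample's
#' median quotient.
#'
#' @param table a `peak_table`.
#' @param reference optional explicit reference profile (length
#'   `n_features`).
#' @param fallback_median with no QC samples and no explicit reference, use
#'   the per-feature median across all samples as reference (default
#'   `TRUE`, with a message).
#' @param min_joint minimum number of jointly observed features required per
#'   sample (default 3).
#' @return The normalised `peak_table`; `attr(, "factors")` holds the
#'   per-sample median quotients.
#' @export
normalise_pqn <- function(table, reference = NULL, fallback_median = TRUE,
                          min_joint = 3) {
  mat <- table$intensities
  if (is.null(reference)) {
    qc <- which(table$samples$is_qc)
    if (length(qc) > 0) {
      reference <- colMeans(mat[qc, , drop = FALSE], na.rm = TRUE)
    } else if (fallback_median) {
      message("no QC samples: using per-feature median across all samples ",
              "as PQN reference")
      reference <- apply(mat, 2, stats::median, na.rm = TRUE)
    } else {
      stop("no QC samples and no reference supplied", call. = FALSE)
    }
  }
  if (length(reference) != ncol(mat)) {
    stop("reference length must equal the number of features", call. = FALSE)
  }
  coef <- vapply(seq_len(nrow(mat)), function(i) {
    joint <- which(!is.na(mat[i, ]) & !is.na(reference) & reference > 0)
    if (length(joint) < min_joint) {
      stop("sample ", table$samples$sample_id[i], " shares fewer than ",
           min_joint, " observed features with the reference", call. = FALSE)
    }
    stats::median(mat[i, joint] / reference[joint])
  }, numeric(1))
  if (any(coef <= 0)) {
    stop("non-positive quotient median encountered", call. = FALSE)
  }
  res <- set_intensities(table, sweep(mat, 1, coef, "/"))
  attr(res, "factors") <- tibble::tibble(
    sample_id = table$samples$sample_id, factor = coef
  )
  res
}
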