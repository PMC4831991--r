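#' Construct a peak table
#'
#' A `peak_table` holds a samples-by-features intensity matrix together with
#' feature metadata (m/z, retention time) and sample metadata (class label,
#' QC flag). Missing intensities are stored as `NA`. Before transformation
#' all observed intensities must be finite and non-negative; transformed or
#' scaled tables may hold any real value (see `nonneg`).
#'
#' @param intensities numeric matrix, samples in rows, features in columns.
#'   `NA` marks a missing (undetected) cell.
#' @param features data frame with columns `feature_id`, `mz`, `rt`; one row
#'   per matrix column, in column order.
#' @param samples data frame with columns `sample_id`, `class`, `is_qc`; one
#'   row per matrix row, in row order. `class` may be `NA` for QC samples.
#' @param nonneg if `TRUE` (the default for raw intensity data) observed
#'   values must be >= 0.
#' @return An object of class `peak_table`.
#' @export
peak_table <- function(intensities, features, samples, nonneg = TRUE) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  features <- tibble::as_tibble(features)
  samples <- tibble::as_tibble(samples)
  need_f <- c("feature_id", "mz", "rt")
  if (!all(need_f %in% names(features))) {
    stop("`features` needs columns: ", paste(need_f, collapse = ", "),
         call. = FALSE)
  }
  need_s <- c("sample_id", "class", "is_qc")
  if (!all(need_s %in% names(samples))) {
    stop("`samples` needs columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) != nrow(intensities) || nrow(features) != ncol(intensities)) {
    stop("metadata dimensions do not match the intensity matrix", call. = FALSE)
  }
  features$feature_id <- as.character(features$feature_id)
  samples$sample_id <- as.character(samples$sample_id)
  samples$is_qc <- as.logical(samples$is_qc)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id", call. = FALSE)
  }
  obs <- intensities[!is.na(intensities)]
  if (any(!is.finite(obs))) {
    stop("observed intensities must be finite", call. = FALSE)
  }
  if (nonneg && any(obs < 0)) {
    stop("observed intensities must be non-negative", call. = FALSE)
  }
  dimnames(intensities) <- list(samples$sample_id, features$feature_id)
  structure(
    list(intensities = intensities, features = features, samples = samples),
    class = "peak_table"
  )
}

# internal: swap in a new value matrix, keeping metadata; no sign check
set_intensities <- function(table, values) {
  stopifnot(all(dim(values) == dim(table$intensities)))
  dimnames(values) <- dimnames(table$intensities)
  table$intensities <- values
  table
}

#' @export
print.peak_table <- function(x, ...) {
  n <- nrow(x$intensities); p <- ncol(x$intensities)
  miss <- mean(is.na(x$intensities))
  cls <- table(x$samples$class[!x$samples$is_qc], useNA = "no")
  cat(sprintf("<peak_table> %d samples (%d QC) x %d features, %.1f%% missing\n",
              n, sum(x$samples$is_qc), p, 100 * miss))
  if (length(cls)) {
    cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' Number of samples / features in a peak table
#' @param table a `peak_table`.
#' @return An integer count.
#' @export
n_samples <- function(table) nrow(table$intensities)

#' @rdname n_samples
#' @export
n_features <- function(table) ncol(table$intensities)

#' Missingness mask of a peak table
#'
#' @param table a `peak_table`.
#' @return Logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(table) is.na(table$intensities)

#' Does the table contain any missing cells?
#' @param table a `peak_table`.
#' @return `TRUE` if every cell is observed.
#' @export
is_complete <- function(table) !anyNA(table$intensities)

#' Long-format view of a peak table
#'
#' One row per cell, joined with the sample and feature metadata; missing
#' cells appear with `intensity = NA`.
#'
#' @param x a `peak_table`.
#' @param ... unused.
#' @return A tibble with columns `sample_id`, `feature_id`, `intensity`,
#'   `class`, `is_qc`, `mz`, `rt`.
#' @export
as_tibble.peak_table <- function(x, ...) {
  long <- tibble::tibble(
    sample_id = rep(x$samples$sample_id, times = ncol(x$intensities)),
    feature_id = rep(x$features$feature_id, each = nrow(x$intensities)),
    intensity = as.vector(x$intensities)
  )
  long <- dplyr::left_join(long, x$samples, by = "sample_id")
  dplyr::left_join(long, x$features, by = "feature_id")
}

# internal: indices of non-QC samples belonging to a class label
class_rows <- function(table, label) {
  which(!table$samples$is_qc & !is.na(table$samples$class) &
          table$samples$class == label)
}

# internal: non-QC class labels present, in stable order
class_labels <- function(table) {
  lab <- table$samples$class[!table$samples$is_qc]
  unique(lab[!is.na(lab)])
}

#' Subset a peak table
#'
#' @param x a `peak_table`.
#' @param i sample index (logical, integer or sample_id character vector).
#' @param j feature index (logical, integer or feature_id character vector).
#' @param ... unused.
#' @return A `peak_table` restricted to the selected rows/columns.
#' @export
`[.peak_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$features$feature_id)
  peak_table(x$intensities[i, j, drop = FALSE],
             x$features[j, , drop = FALSE],
             x$samples[i, , drop = FALSE],
             nonneg = FALSE)
}
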