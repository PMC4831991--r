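#' Read an XCMS-style peak table
#'
#' Reads a delimited peak table in the common XCMS export layout: features in
#' rows, with leading columns `feature_id`, `mz`, `rt`, followed by one
#' column per sample. The matrix is transposed on input so that internally
#' samples are rows and features are columns (per-sample normalisation acts
#' row-wise, per-feature scaling column-wise). Empty cells and `NA` are read
#' as missing; zeros are treated as missing by default because XCMS reports
#' unfilled peaks as zero or `NA` depending on settings.
#'
#' @param path path to the peak-table file (TSV by default, see `delim`).
#' @param sample_meta path to a sample metadata CSV with columns
#'   `sample_id`, `class`, `is_qc`, or a data frame with those columns. If
#'   `NULL`, all samples are labelled as non-QC with class `NA`.
#' @param zeros_as_missing treat exact zeros as missing cells (default
#'   `TRUE`).
#' @param delim field delimiter of the peak-table file.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path, sample_meta = NULL, zeros_as_missing = TRUE,
                            delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    feature_id = readr::col_character(),
    mz = readr::col_double(),
    rt = readr::col_double(),
    .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(raw))) {
    stop("malformed header: expected leading columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  sample_ids <- setdiff(names(raw), need)
  if (length(sample_ids) == 0L) stop("no sample columns found", call. = FALSE)
  if (anyDuplicated(raw$feature_id)) {
    stop("duplicate feature_id in peak table", call. = FALSE)
  }
  mat <- t(as.matrix(raw[, sample_ids]))   # samples x features
  if (zeros_as_missing) mat[!is.na(mat) & mat == 0] <- NA_real_
  if (any(mat[!is.na(mat)] < 0)) {
    stop("negative intensity in peak table", call. = FALSE)
  }
  if (is.null(sample_meta)) {
    samples <- tibble::tibble(sample_id = sample_ids, class = NA_character_,
                              is_qc = FALSE)
  } else {
    samples <- if (is.data.frame(sample_meta)) {
      tibble::as_tibble(sample_meta)
    } else {
      readr::read_csv(sample_meta, col_types = readr::cols(
        sample_id = readr::col_character(),
        class = readr::col_character(),
        is_qc = readr::col_logical()
      ), progress = FALSE, show_col_types = FALSE)
    }
    samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
    if (anyNA(samples$sample_id)) {
      stop("sample metadata does not cover all sample columns", call. = FALSE)
    }
  }
  peak_table(mat,
             features = raw[, need],
             samples = samples)
}

#' Write a peak table
#'
#' Writes the XCMS-style layout read by [read_peak_table()]: features in
#' rows, columns `feature_id`, `mz`, `rt`, then one column per sample;
#' missing cells are written as `NA`. Optionally writes the sample metadata
#' alongside.
#'
#' @param table a `peak_table`.
#' @param path output path for the peak table.
#' @param sample_meta optional path for the sample metadata CSV.
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path, sample_meta = NULL, delim = "\t") {
  wide <- dplyr::bind_cols(
    table$features[, c("feature_id", "mz", "rt")],
    tibble::as_tibble(t(table$intensities))
  )
  readr::write_delim(wide, path, delim = delim, na = "NA", progress = FALSE)
  if (!is.null(sample_meta)) {
    readr::write_csv(table$samples, sample_meta, progress = FALSE)
  }
  invisible(path)
}
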