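#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the Shapiro-Wilk test used throughout the univariate
#' and score-separation screens; errors on constant input instead of
#' propagating an opaque failure.
#'
#' @param values numeric vector, 3 to 5000 observations.
#' @return A list with elements `statistic` (W) and `p.value`.
#' @export
test_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    stop("Shapiro-Wilk requires between 3 and 5000 values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("normality test undefined for constant values", call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

# internal: two-group test on observed values. Mann-Whitney uses the exact
# null when both groups are small (< 8) and the tie-corrected normal
# approximation otherwise; the t-test is the pooled-variance (equal
# variance) form.
two_group_p <- function(a, b, test) {
  if (test == "t") {
    if (stats::sd(c(a, b)) == 0) return(1)
    stats::t.test(a, b, var.equal = TRUE)$p.value
  } else {
    exact <- length(a) < 8 && length(b) < 8
    suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
    )
  }
}

#' Two-class univariate screen with FDR control
#'
#' Tests every feature for a difference between two classes on its observed
#' values (QC samples are excluded first), then applies Benjamini-Hochberg
#' false-discovery-rate adjustment across the tested features. Features
#' with fewer than `min_per_class` observed values in either class are not
#' tested (p and q are `NA`) and do not count towards the BH family size,
#' so imputation choices cannot leak into the univariate screen through
#' under-observed features.
#'
#' @param table a `peak_table`.
#' @param classes length-2 character vector of class labels to compare;
#'   default the first two labels present.
#' @param test `"mann-whitney"` (default) or `"t"` (pooled variance).
#' @param alpha significance boundary on the adjusted p-value (default
#'   0.05).
#' @param min_per_class minimum observed values per class per feature
#'   (default 3).
#' @return A tibble with columns `feature_id`, `n_a`, `n_b`, `p`, `q`,
#'   `test`, `significant`.
#' @export
univariate_screen <- function(table, classes = NULL,
                              test = c("mann-whitney", "t"),
                              alpha = 0.05, min_per_class = 3) {
  test <- match.arg(test)
  if (is.null(classes)) classes <- class_labels(table)[1:2]
  if (length(classes) != 2 || anyNA(classes)) {
    stop("need two class labels", call. = FALSE)
  }
  ia <- class_rows(table, classes[1])
  ib <- class_rows(table, classes[2])
  if (length(ia) == 0 || length(ib) == 0) {
    stop("empty class: ", paste(classes, collapse = ", "), call. = FALSE)
  }
  mat <- table$intensities
  p_feat <- numeric(ncol(mat)); na_ct <- nb_ct <- integer(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    a <- mat[ia, j]; a <- a[!is.na(a)]
    b <- mat[ib, j]; b <- b[!is.na(b)]
    na_ct[j] <- length(a); nb_ct[j] <- length(b)
    p_feat[j] <- if (length(a) < min_per_class || length(b) < min_per_class)
      NA_real_ else two_group_p(a, b, test)
  }
  q <- rep(NA_real_, length(p_feat))
  q[!is.na(p_feat)] <- stats::p.adjust(p_feat[!is.na(p_feat)], method = "BH")
  tibble::tibble(
    feature_id = table$features$feature_id,
    n_a = na_ct, n_b = nb_ct, p = p_feat, q = q, test = test,
    significant = !is.na(q) & q < alpha
  )
}
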