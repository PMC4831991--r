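# small in-code fixtures shared across tests

# hand-built table: values chosen so row/column statistics are easy to
# verify by hand
toy_table <- function(values, n_qc = 0, classes = NULL) {
  n <- nrow(values); p <- ncol(values)
  if (is.null(classes)) {
    classes <- rep(c("A", "B"), length.out = n - n_qc)
  }
  peak_table(
    values,
    features = tibble::tibble(
      feature_id = paste0("F", seq_len(p)),
      mz = 100 + seq_len(p), rt = 10 * seq_len(p)
    ),
    samples = tibble::tibble(
      sample_id = paste0("S", seq_len(n)),
      class = c(classes, rep(NA_character_, n_qc)),
      is_qc = c(rep(FALSE, n - n_qc), rep(TRUE, n_qc))
    )
  )
}

# random complete positive table for property-style tests
random_table <- function(n = 12, p = 20, n_qc = 3, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(exp(stats::rnorm(n * p, mean = 8, sd = 1)), n, p)
    toy_table(vals, n_qc = n_qc)
  })
}

# complete table with a planted, well-separated spectrum: suitable for
# checking NIPALS against the SVD (iid-random tables have near-degenerate
# eigenvalues where any power method hits its accuracy floor)
structured_table <- function(n = 18, p = 12, seed = 1) {
  withr::with_seed(seed, {
    Tm <- matrix(stats::rnorm(n * 3), n, 3) %*% diag(c(40, 15, 6))
    P <- qr.Q(qr(matrix(stats::rnorm(p * 3), p, 3)))
    X <- Tm %*% t(P) + matrix(stats::rnorm(n * p, sd = 0.3), n, p)
    toy_table(X - min(X) + 1, n_qc = 0)
  })
}

# rebuild a table around a modified value matrix (public-API counterpart of
# the package-internal setter)
set_intensities_for_test <- function(tab, mat) {
  peak_table(mat, tab$features, tab$samples, nonneg = FALSE)
}

# small generated two-class dataset used by the heavier model tests;
# reduced size keeps the suite quick
small_config <- function(n_features = 150, ...) {
  generator_config(n_per_class = c(A = 12, B = 12), n_qc = 6,
                   n_features = n_features, ...)
}
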