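#' Principal component analysis by NIPALS, tolerant of missing values
#'
#' Extracts components one at a time with the NIPALS algorithm, computing
#' every inner product over observed cells only, so tables with missing
#' values need no prior imputation. Features are mean-centred over their
#' observed cells internally. After each component the fitted rank-one term
#' is subtracted from the observed cells (deflation). Explained variance of
#' a component is its fitted sum of squares over observed cells as a
#' percentage of the total centred observed sum of squares; on complete
#' data scores, loadings and variances coincide with the singular value
#' decomposition (up to sign).
#'
#' Per-component class-separation p-values mirror the score testing used in
#' two-class studies: Shapiro-Wilk is run on each class's scores and a
#' pooled-variance t-test is used when both are compatible with normality,
#' a Mann-Whitney U test otherwise. QC samples receive scores but are
#' excluded from the separation test.
#'
#' @param table a `peak_table`.
#' @param n_comp number of components (default 2).
#' @param classes optional length-2 class labels for the separation test;
#'   default the first two labels present (skipped if fewer than 2).
#' @param tol convergence tolerance on the relative change of the score
#'   vector (default 1e-12; tight enough that complete-data components
#'   match the SVD well below 1e-8).
#' @param max_iter iteration cap per component; non-convergence warns and
#'   truncates the model.
#' @return An object of class `pca_model`: list with `scores`
#'   (n x n_comp), `loadings` (p x n_comp, unit columns), `var_pct`,
#'   `score_tests` (tibble: component, p, test), `n_comp`, plus the sample
#'   and feature metadata for plotting.
#' @export
fit_pca_nipals <- function(table, n_comp = 2, classes = NULL, tol = 1e-12,
                           max_iter = 5000) {
  mat <- table$intensities
  n <- nrow(mat); p <- ncol(mat)
  n_comp <- min(n_comp, n - 1, p)
  ctr <- colMeans(mat, na.rm = TRUE)
  X <- sweep(mat, 2, ctr)
  miss <- is.na(X)
  O <- 1 - miss          # numeric observed indicator
  total_ss <- sum(X[!miss]^2)

  scores <- matrix(0, n, n_comp)
  loadings <- matrix(0, p, n_comp)
  var_pct <- numeric(n_comp)
  kept <- 0L
  for (a in seq_len(n_comp)) {
    Xf <- X; Xf[miss] <- 0
    start <- which.max(colSums(Xf^2))
    t_vec <- Xf[, start]
    if (all(t_vec == 0)) break
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      denom_p <- as.vector(crossprod(O, t_vec^2))
      p_vec <- as.vector(crossprod(Xf, t_vec)) / pmax(denom_p, 1e-300)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      denom_t <- as.vector(O %*% p_vec^2)
      t_new <- as.vector(Xf %*% p_vec) / pmax(denom_t, 1e-300)
      if (sqrt(sum((t_new - t_vec)^2)) <= tol * sqrt(sum(t_new^2))) {
        t_vec <- t_new; converged <- TRUE; break
      }
      t_vec <- t_new
    }
    if (!converged) {
      warning("NIPALS component ", a, " did not converge; model truncated",
              call. = FALSE)
      break
    }
    kept <- a
    scores[, a] <- t_vec
    loadings[, a] <- p_vec
    fit <- outer(t_vec, p_vec)
    var_pct[a] <- 100 * sum(fit[!miss]^2) / total_ss
    X <- X - fit
    X[miss] <- NA
  }
  if (kept == 0L) stop("no PCA component could be extracted", call. = FALSE)
  scores <- scores[, seq_len(kept), drop = FALSE]
  loadings <- loadings[, seq_len(kept), drop = FALSE]
  var_pct <- var_pct[seq_len(kept)]
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(kept))
  rownames(scores) <- table$samples$sample_id
  rownames(loadings) <- table$features$feature_id

  if (is.null(classes)) {
    labs <- class_labels(table)
    classes <- if (length(labs) >= 2) labs[1:2] else NULL
  }
  score_tests <- tibble::tibble(component = character(), p = numeric(),
                                test = character())
  if (!is.null(classes)) {
    ia <- class_rows(table, classes[1])
    ib <- class_rows(table, classes[2])
    score_tests <- purrr::map_dfr(seq_len(kept), function(a) {
      sa <- scores[ia, a]; sb <- scores[ib, a]
      normal <- tryCatch(
        test_normality(sa)$p.value > 0.05 && test_normality(sb)$p.value > 0.05,
        error = function(e) FALSE
      )
      use <- if (normal) "t" else "mann-whitney"
      tibble::tibble(component = paste0("PC", a),
                     p = two_group_p(sa, sb, use), test = use)
    })
  }
  structure(list(
    scores = scores, loadings = loadings, var_pct = var_pct,
    score_tests = score_tests, n_comp = kept,
    samples = table$samples, features = table$features, center = ctr
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d component(s); variance %% = %s\n", x$n_comp,
              paste(sprintf("%.1f", x$var_pct), collapse = ", ")))
  if (nrow(x$score_tests)) {
    cat("  score separation p:",
        paste(sprintf("%s=%.3g", x$score_tests$component, x$score_tests$p),
              collapse = ", "), "\n")
  }
  invisible(x)
}
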