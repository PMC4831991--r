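# internal: PLS1 by NIPALS on centred X (n x p) and centred y.
# Returns weights W, loadings P, y-loadings q and scores T for A components.
pls1_nipals <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  qv <- numeric(A)
  for (a in seq_len(A)) {
    w <- as.vector(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) { A <- a - 1L; break }
    w <- w / nw
    t_vec <- as.vector(X %*% w)
    tt <- sum(t_vec^2)
    p_vec <- as.vector(crossprod(X, t_vec)) / tt
    q_a <- sum(y * t_vec) / tt
    X <- X - tcrossprod(t_vec, p_vec)
    y <- y - q_a * t_vec
    W[, a] <- w; P[, a] <- p_vec; Tm[, a] <- t_vec; qv[a] <- q_a
  }
  list(W = W[, seq_len(A), drop = FALSE], P = P[, seq_len(A), drop = FALSE],
       T = Tm[, seq_len(A), drop = FALSE], q = qv[seq_len(A)],
       y_res = y, A = A)
}

# internal: regression coefficients for the first a components
pls1_coef <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  q <- fit$q[seq_len(a)]
  W %*% solve(crossprod(P, W), q)
}

# internal: stratified fold assignment, seeded
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Two-class PLS-DA with tenfold cross-validated Q2
#'
#' Fits partial least squares regression (PLS1, NIPALS) of a centred binary
#' class indicator on the feature matrix, after removing QC samples. The
#' table must be complete: cross-validation is not well defined with
#' missing cells, so permutations without imputation are reported as
#' not-evaluable upstream rather than silently imputed here. R-squared is
#' the in-model fraction of indicator variance explained; Q-squared is
#' `1 - PRESS/TSS` under stratified tenfold cross-validation (seeded). The
#' reported component count maximises Q-squared over `1..max_comp`.
#'
#' @param table a complete `peak_table`.
#' @param classes length-2 class labels; default the first two present.
#' @param max_comp maximum number of latent variables scanned (default 5).
#' @param n_folds cross-validation folds (default 10); every class must
#'   have at least `n_folds` members.
#' @param seed integer seed for the fold split.
#' @return An object of class `plsda_model`: list with `r2` and `q2`
#'   (per-component vectors), `n_comp` (Q2-optimal), `scores`, `loadings`,
#'   `weights`, `classes`, `samples`.
#' @export
fit_plsda <- function(table, classes = NULL, max_comp = 5, n_folds = 10,
                      seed = 1) {
  keep <- !table$samples$is_qc
  sub <- table[which(keep), ]
  if (!is_complete(sub)) {
    stop("PLS-DA requires a complete table (no missing values)",
         call. = FALSE)
  }
  if (is.null(classes)) classes <- class_labels(sub)[1:2]
  rows <- c(class_rows(sub, classes[1]), class_rows(sub, classes[2]))
  sub <- sub[rows, ]
  labels <- sub$samples$class
  if (any(table(labels) < n_folds)) {
    stop("every class needs at least n_folds members", call. = FALSE)
  }
  X <- sub$intensities
  y <- as.numeric(labels == classes[1])
  n <- nrow(X)
  max_comp <- min(max_comp, n - 2, ncol(X))

  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  tss <- sum(yc^2)
  fit <- pls1_nipals(Xc, yc, max_comp)
  A <- fit$A
  r2 <- vapply(seq_len(A), function(a) {
    res <- yc - as.vector(Xc %*% pls1_coef(fit, a))
    1 - sum(res^2) / tss
  }, numeric(1))

  fold <- stratified_folds(labels, n_folds, seed)
  press <- numeric(A)
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    xm <- colMeans(X[tr, , drop = FALSE]); ym <- mean(y[tr])
    cv <- pls1_nipals(sweep(X[tr, , drop = FALSE], 2, xm), y[tr] - ym, A)
    Xte <- sweep(X[te, , drop = FALSE], 2, xm)
    for (a in seq_len(cv$A)) {
      pred <- ym + as.vector(Xte %*% pls1_coef(cv, a))
      press[a] <- press[a] + sum((y[te] - pred)^2)
    }
    if (cv$A < A) press[(cv$A + 1):A] <- NA
  }
  q2 <- 1 - press / tss
  n_opt <- which.max(q2)

  colnames(fit$T) <- colnames(fit$P) <- colnames(fit$W) <-
    paste0("LV", seq_len(A))
  rownames(fit$T) <- sub$samples$sample_id
  rownames(fit$P) <- rownames(fit$W) <- sub$features$feature_id
  structure(list(
    r2 = r2, q2 = q2, n_comp = n_opt,
    scores = fit$T, loadings = fit$P, weights = fit$W,
    classes = classes, samples = sub$samples, n_folds = n_folds, seed = seed
  ), class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "<plsda_model> %d component(s) (Q2-optimal); R2 = %.3f, Q2 = %.3f\n",
    x$n_comp, x$r2[x$n_comp], x$q2[x$n_comp]))
  invisible(x)
}
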