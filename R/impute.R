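#' Small-value replacement imputation
#'
#' Every missing cell is replaced by half of the minimum observed intensity
#' of the entire matrix — the conventional fill when non-detections are
#' assumed to lie below the limit of detection.
#'
#' @param table a `peak_table`.
#' @return A complete `peak_table`.
#' @export
impute_small_value <- function(table) {
  mat <- table$intensities
  if (!anyNA(mat)) return(table)
  mat[is.na(mat)] <- 0.5 * min(mat, na.rm = TRUE)
  set_intensities(table, mat)
}

#' Mean / median replacement imputation
#'
#' Missing cells of a feature are replaced by that feature's mean
#' (respectively median) over its observed cells.
#'
#' @param table a `peak_table`; every feature needs at least one observed
#'   value.
#' @return A complete `peak_table`.
#' @export
impute_mean <- function(table) impute_feature_stat(table, base::mean)

#' @rdname impute_mean
#' @export
impute_median <- function(table) impute_feature_stat(table, stats::median)

impute_feature_stat <- function(table, fun) {
  mat <- table$intensities
  if (!anyNA(mat)) return(table)
  for (j in which(colSums(is.na(mat)) > 0)) {
    obs <- mat[, j][!is.na(mat[, j])]
    if (length(obs) == 0L) {
      stop("feature ", table$features$feature_id[j],
           " has no observed values", call. = FALSE)
    }
    mat[is.na(mat[, j]), j] <- fun(obs)
  }
  set_intensities(table, mat)
}

# internal: feature-feature Euclidean distances over jointly observed
# samples, scaled to full-length equivalent by sqrt(n / n_joint).
# Features with no joint observations get distance Inf.
feature_distances <- function(mat) {
  O <- !is.na(mat)
  X0 <- mat; X0[!O] <- 0
  mode(O) <- "numeric"
  sq <- crossprod(X0^2, O)          # sum over joint of x_i^2
  cross <- crossprod(X0)            # sum over joint of x_i x_j
  J <- crossprod(O)                 # joint observation counts
  D2 <- (sq + t(sq) - 2 * cross) * nrow(mat) / J
  D2[J == 0] <- Inf
  D2[D2 < 0] <- 0                   # numerical noise
  diag(D2) <- Inf
  sqrt(D2)
}

#' K-nearest-neighbour imputation
#'
#' Neighbours are features: the distance between two features is the
#' Euclidean distance of their responses across samples, computed over
#' jointly observed samples and rescaled by `sqrt(n / n_joint)` so sparsely
#' co-observed pairs are not favoured. A missing cell of feature `f` at
#' sample `s` becomes the unweighted mean of the values at `s` among the
#' `k` features nearest to `f` that are observed at `s`; if none of the `k`
#' is observed there, the feature's own mean is used. Each missing cell thus
#' receives its own value rather than a feature-wide constant.
#'
#' @param table a `peak_table`.
#' @param k number of neighbour features (default 10).
#' @return A complete `peak_table`.
#' @export
impute_knn <- function(table, k = 10) {
  mat <- table$intensities
  if (k >= ncol(mat)) stop("k must be smaller than the number of features",
                           call. = FALSE)
  if (!anyNA(mat)) return(table)
  D <- feature_distances(mat)
  feat_means <- colMeans(mat, na.rm = TRUE)
  for (j in which(colSums(is.na(mat)) > 0)) {
    ord <- order(D[, j])
    ord <- ord[is.finite(D[ord, j])]
    nb <- utils::head(ord, k)
    for (s in which(is.na(mat[, j]))) {
      vals <- table$intensities[s, nb]
      vals <- vals[!is.na(vals)]
      mat[s, j] <- if (length(vals)) mean(vals) else feat_means[j]
    }
  }
  set_intensities(table, mat)
}

#' Bayesian principal-component-analysis imputation
#'
#' Fits a probabilistic PCA model with automatic-relevance-determination
#' priors on the loading columns by expectation-maximisation, treating
#' missing cells as latent: each sweep computes posterior expected scores
#' from the observed coordinates of every sample, re-imputes missing cells
#' from the model's reconstruction, and updates loadings (shrunk by the ARD
#' penalty, which prunes unneeded axes), mean and noise variance.
#' Initialisation is deterministic (eigendecomposition of the mean-imputed
#' covariance), so the result is reproducible without a seed.
#'
#' @param table a `peak_table`.
#' @param n_axes number of latent axes; `NULL` (default) uses
#'   `min(n_samples, n_features) - 1`, relying on ARD to prune. `0`
#'   degenerates to feature-mean imputation.
#' @param tol convergence threshold on the maximum relative change of
#'   imputed cells (default 1e-4).
#' @param max_iter maximum sweeps (default 200); non-convergence warns and
#'   returns the best iterate.
#' @return A complete `peak_table`.
#' @export
impute_bpca <- function(table, n_axes = NULL, tol = 1e-4, max_iter = 200) {
  mat <- table$intensities
  if (!anyNA(mat)) return(table)
  n <- nrow(mat); p <- ncol(mat)
  if (is.null(n_axes)) n_axes <- min(n, p) - 1
  stopifnot(n_axes >= 0, n_axes <= min(n, p) - 1)
  if (n_axes == 0) return(impute_mean(table))
  q <- n_axes

  miss <- is.na(mat)
  Y <- mat
  mu <- colMeans(mat, na.rm = TRUE)
  Y[miss] <- matrix(mu, n, p, byrow = TRUE)[miss]

  # deterministic start: principal axes of the mean-imputed covariance.
  # The noise variance is initialised from a half-rank residual: with the
  # full q = min(n,p) - 1 axes the mean-imputed matrix is fitted exactly,
  # which would start sigma2 at zero and freeze the mean fill in place (a
  # fixed point of fill-then-fit EM); an honest starting noise level keeps
  # the score posterior regularised so the model can move off it.
  Yc <- sweep(Y, 2, mu)
  sv <- svd(Yc, nu = 0, nv = q)
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(n), q)
  k0 <- max(1L, floor(q / 2))
  sigma2 <- max(mean(Yc^2) - sum(sv$d[seq_len(k0)]^2) / (n * p), 1e-8)
  alpha <- rep(1, q)

  miss_list <- lapply(seq_len(n), function(i) which(miss[i, ]))
  for (iter in seq_len(max_iter)) {
    EX <- matrix(0, n, q)
    S <- matrix(0, q, q)       # sum of E[x x']
    old_imp <- Y[miss]
    # per-row Gram matrices via downdating: W_o'W_o = W'W - W_m'W_m
    WtW <- crossprod(W)
    Yc0 <- sweep(Y, 2, mu); Yc0[miss] <- 0
    R0 <- Yc0 %*% W          # row i = W_o'(y_o - mu_o)
    tr_term <- 0
    for (i in seq_len(n)) {
      m <- miss_list[[i]]
      Wm <- W[m, , drop = FALSE]
      G <- WtW - crossprod(Wm)              # W_o' W_o
      M <- G + sigma2 * diag(q)
      Minv <- chol2inv(chol(M))
      x <- Minv %*% R0[i, ]
      EX[i, ] <- x
      S <- S + tcrossprod(x) + sigma2 * Minv
      tr_term <- tr_term + sigma2 * sum(G * Minv)  # tr(W_o'W_o Cov x_i)
      if (length(m)) Y[i, m] <- mu[m] + Wm %*% x
    }
    mu <- colMeans(Y)
    Yc <- sweep(Y, 2, mu)
    W <- t(solve(S + sigma2 * diag(alpha, q), crossprod(EX, Yc)))
    alpha <- p / (colSums(W^2) + 1e-12)
    resid <- Yc - EX %*% t(W)
    sigma2 <- max((sum(resid[!miss]^2) + tr_term) / sum(!miss), 1e-12)
    rel <- max(abs(Y[miss] - old_imp) / pmax(abs(old_imp), 1e-12))
    if (rel < tol) break
  }
  if (iter == max_iter && rel >= tol) {
    warning("BPCA imputation did not converge in ", max_iter,
            " sweeps; returning best iterate", call. = FALSE)
  }
  mat[miss] <- Y[miss]
  set_intensities(table, mat)
}

#' Random-forest imputation
#'
#' Iterative random-forest regression in the missForest style: missing
#' cells are initialised with feature means; features are visited in order
#' of ascending missing count, each regressed on all other features using
#' the samples where it is observed, and its missing cells replaced by the
#' forest's predictions. Sweeps repeat until the normalised sum of squared
#' differences between successive imputations first increases (the previous
#' iterate is returned) or `max_iter` is reached. Stochastic but
#' reproducible under a fixed seed.
#'
#' @param table a `peak_table`; no feature may be fully missing.
#' @param n_trees trees per forest (default 100).
#' @param max_iter maximum sweeps (default 10).
#' @param mtry predictors tried per split; default `floor(sqrt(p))`, the
#'   missForest convention.
#' @param seed integer seed.
#' @return A complete `peak_table`.
#' @export
impute_rf <- function(table, n_trees = 100, max_iter = 10, mtry = NULL,
                      seed = 1) {
  mat <- table$intensities
  if (!anyNA(mat)) return(table)
  miss <- is.na(mat)
  if (any(colSums(!miss) == 0)) {
    stop("feature with no observed values cannot be imputed", call. = FALSE)
  }
  Y <- mat
  mu <- colMeans(mat, na.rm = TRUE)
  Y[miss] <- matrix(mu, nrow(mat), ncol(mat), byrow = TRUE)[miss]
  targets <- which(colSums(miss) > 0)
  targets <- targets[order(colSums(miss)[targets])]
  colnames(Y) <- paste0("V", seq_len(ncol(Y)))
  if (is.null(mtry)) mtry <- max(floor(sqrt(ncol(Y) - 1)), 1)

  withr::with_seed(seed, {
    prev <- Y
    prev_diff <- Inf
    for (iter in seq_len(max_iter)) {
      old <- Y
      for (j in targets) {
        obs <- which(!miss[, j])
        fit <- ranger::ranger(
          x = Y[obs, -j, drop = FALSE], y = Y[obs, j],
          num.trees = n_trees, mtry = mtry, num.threads = 1,
          seed = sample.int(.Machine$integer.max, 1)
        )
        Y[miss[, j], j] <- stats::predict(
          fit, data = Y[miss[, j], -j, drop = FALSE],
          num.threads = 1
        )$predictions
      }
      diff <- sum((Y[miss] - old[miss])^2) / max(sum(Y[miss]^2), 1e-12)
      if (diff > prev_diff) { Y <- old; break }
      prev_diff <- diff
      if (diff == 0) break
    }
  })
  mat[miss] <- Y[miss]
  set_intensities(table, mat)
}

#' Apply an imputation method by name
#'
#' Dispatches the closed imputation vocabulary (`none`, `SV`, `MN`, `MD`,
#' `KNN`, `BPCA`, `RF`) used in processing permutations.
#'
#' @param table a `peak_table`.
#' @param method one of `"none"`, `"SV"`, `"MN"`, `"MD"`, `"KNN"`,
#'   `"BPCA"`, `"RF"`.
#' @param knn_k neighbours for KNN.
#' @param rf_trees,rf_max_iter forest size and sweep cap for RF.
#' @param seed seed for the stochastic (RF) method.
#' @return A `peak_table` (complete unless `method = "none"`).
#' @export
impute_by_name <- function(table, method, knn_k = 10, rf_trees = 100,
                           rf_max_iter = 10, seed = 1) {
  switch(method,
    none = table,
    SV = impute_small_value(table),
    MN = impute_mean(table),
    MD = impute_median(table),
    KNN = impute_knn(table, k = knn_k),
    BPCA = impute_bpca(table),
    RF = impute_rf(table, n_trees = rf_trees, max_iter = rf_max_iter,
                   seed = seed),
    stop("unknown mvi method: ", method, call. = FALSE)
  )
}

#' Assess imputation methods by NRMSE on held-out cells
#'
#' Starting from a complete table, masks `floor(rate * n_cells)` cells
#' completely at random, runs each imputation method, and scores it by the
#' normalised root mean squared error: the RMSE over the masked cells of
#' (original - imputed), divided by the mean of the complete original
#' matrix. Sum normalisation is applied before masking (flag-controlled),
#' matching the processing state in which imputation is compared.
#'
#' @param table_complete a complete `peak_table` (filter out features with
#'   missing values first).
#' @param methods imputation methods to assess (default all six).
#' @param rate missing fraction to inject (default 0.10).
#' @param seed integer seed for the mask (and RF).
#' @param sum_normalise sum-normalise before masking (default `TRUE`).
#' @param ... passed to [impute_by_name()].
#' @return A tibble with columns `method`, `nrmse`, `n_masked`, `seed`.
#' @export
assess_mvi <- function(table_complete,
                       methods = c("SV", "MN", "MD", "KNN", "BPCA", "RF"),
                       rate = 0.10, seed = 1, sum_normalise = TRUE, ...) {
  if (!is_complete(table_complete)) {
    stop("assess_mvi requires a complete table", call. = FALSE)
  }
  methods <- check_stage(methods, "mvi")
  methods <- setdiff(methods, "none")
  base <- if (sum_normalise) normalise_sum(table_complete) else table_complete
  masked <- inject_missing(base, rate = rate, mnar_weight = 0, seed = seed)
  hold <- is.na(masked$intensities) & !is.na(base$intensities)
  truth <- base$intensities[hold]
  denom <- mean(base$intensities)
  purrr::map_dfr(methods, function(m) {
    imp <- impute_by_name(masked, m, seed = seed, ...)
    tibble::tibble(
      method = m,
      nrmse = sqrt(mean((truth - imp$intensities[hold])^2)) / denom,
      n_masked = sum(hold),
      seed = seed
    )
  })
}
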