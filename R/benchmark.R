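# internal: normalise a permutation descriptor (grid row, named list or character
# vector) into a named list of four stage choices
as_permutation <- function(perm) {
  if (is.data.frame(perm)) perm <- as.list(perm[1, ])
  if (is.character(perm) && is.null(names(perm)) && length(perm) == 4) {
    names(perm) <- c("normalisation", "mvi", "transformation", "scaling")
  }
  perm <- as.list(perm)
  need <- c("normalisation", "mvi", "transformation", "scaling")
  if (!all(need %in% names(perm))) {
    stop("a permutation needs fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (st in need) perm[[st]] <- check_stage(perm[[st]], st)
  perm[c("normalisation", "mvi", "transformation", "scaling")]
}

#' Run one processing permutation
#'
#' Applies the four processing stages in the fixed pipeline order
#' normalise, impute, transform, scale; `"none"` stages are skipped. For
#' glog transformation the offset is estimated from the QC samples of the
#' table as it stands after normalisation and imputation, unless an
#' explicit `glog_lambda` is supplied.
#'
#' @param table a filtered `peak_table`.
#' @param perm a row of [enumerate_grid()], a named list, or an unnamed
#'   character vector `c(normalisation, mvi, transformation, scaling)`.
#' @param glog_lambda optional fixed glog offset (number or `glog_params`).
#' @param seed seed for stochastic stages (RF imputation).
#' @param knn_k,rf_trees,rf_max_iter imputation tuning parameters.
#' @return The processed `peak_table`; `attr(, "permutation")` records the
#'   stage choices.
#' @export
run_permutation <- function(table, perm, glog_lambda = NULL, seed = 1,
                            knn_k = 10, rf_trees = 100, rf_max_iter = 10) {
  perm <- as_permutation(perm)
  out <- switch(perm$normalisation,
                SUM = normalise_sum(table),
                PQN = normalise_pqn(table))
  out <- impute_by_name(out, perm$mvi, knn_k = knn_k, rf_trees = rf_trees,
                        rf_max_iter = rf_max_iter, seed = seed)
  if (perm$transformation == "glog" && is.null(glog_lambda)) {
    glog_lambda <- optimize_lambda(out)
  }
  out <- transform_table(out, perm$transformation, lambda = glog_lambda)
  out <- scale_table(out, perm$scaling)
  attr(out, "permutation") <- perm
  out
}

#' Score a processed table against spike-in ground truth (univariate)
#'
#' Runs the univariate screen and splits the significant features into true
#' positives (spiked features) and false positives (everything else).
#'
#' @param processed a processed `peak_table`.
#' @param plan spike plan tibble from [construct_modified_dataset()] (may
#'   be empty).
#' @param classes,test,alpha passed to [univariate_screen()].
#' @return A one-row tibble: `total_significant`, `tp`, `fp`.
#' @export
score_univariate <- function(processed, plan, classes = NULL,
                             test = "mann-whitney", alpha = 0.05) {
  scr <- univariate_screen(processed, classes = classes, test = test,
                           alpha = alpha)
  sig <- scr$feature_id[scr$significant]
  tp <- sum(sig %in% plan$feature_id)
  tibble::tibble(total_significant = length(sig), tp = tp,
                 fp = length(sig) - tp)
}

#' Score a processed table against spike-in ground truth (PCA)
#'
#' Fits a two-component NIPALS PCA, ranks all features by absolute loading
#' on PC1, PC2 and their combination (Euclidean norm of the two loadings),
#' and summarises where the spiked features land. Two qualitative flags
#' operationalise "driven by fold change, not abundance": the fold-change
#' effect holds when the Spearman correlation between `|ln(factor)|` and
#' combined loading over the spiked features is positive with p < 0.05; an
#' abundance effect is declared when the ten best-ranked spiked features do
#' not cover all three abundance tertiles, or when the spiked features'
#' pre-processing mean responses correlate with their combined loadings
#' (Spearman p < 0.05).
#'
#' @param processed a processed `peak_table`.
#' @param plan spike plan tibble (columns `feature_id`, `tertile`,
#'   `factor`, `mean_response`).
#' @param classes passed to [fit_pca_nipals()] for the score-separation
#'   test.
#' @param flag_alpha significance boundary for the two Spearman tests.
#' @return A one-row tibble with PC1/PC2 variance percentages, score
#'   p-values, spiked-feature rank ranges (best rank and the worst of the
#'   ten best, per axis), and the two flags.
#' @export
score_pca <- function(processed, plan, classes = NULL, flag_alpha = 0.05) {
  model <- fit_pca_nipals(processed, n_comp = 2, classes = classes)
  L <- abs(model$loadings)
  comb <- if (model$n_comp >= 2) sqrt(L[, 1]^2 + L[, 2]^2) else L[, 1]
  axes <- list(pc1 = L[, 1],
               pc2 = if (model$n_comp >= 2) L[, 2] else rep(NA_real_,
                                                            nrow(L)),
               comb = comb)
  idx <- match(plan$feature_id, rownames(model$loadings))
  rank_summary <- purrr::imap_dfc(axes, function(v, nm) {
    if (anyNA(v) || length(idx) == 0) {
      return(tibble::tibble("rank_best_{nm}" := NA_real_,
                            "rank_top10_{nm}" := NA_real_))
    }
    rk <- sort(rank(-v, ties.method = "min")[idx])
    tibble::tibble(
      "rank_best_{nm}" := rk[1],
      "rank_top10_{nm}" := rk[min(10, length(rk))]
    )
  })

  fold_change_effect <- FALSE
  abundance_effect <- FALSE
  if (nrow(plan) >= 4) {
    fc <- suppressWarnings(
      stats::cor.test(abs(log(plan$factor)), comb[idx], method = "spearman")
    )
    fold_change_effect <- !is.na(fc$p.value) && fc$estimate > 0 &&
      fc$p.value < flag_alpha
    top10 <- plan$tertile[order(comb[idx], decreasing = TRUE)][1:min(10, nrow(plan))]
    ab <- suppressWarnings(
      stats::cor.test(plan$mean_response, comb[idx], method = "spearman")
    )
    abundance_effect <- length(unique(top10)) < 3 ||
      (!is.na(ab$p.value) && ab$p.value < flag_alpha)
  }
  p1 <- model$score_tests$p[model$score_tests$component == "PC1"]
  p2 <- model$score_tests$p[model$score_tests$component == "PC2"]
  tibble::tibble(
    var_pc1 = model$var_pct[1],
    var_pc2 = if (model$n_comp >= 2) model$var_pct[2] else NA_real_,
    p_pc1 = if (length(p1)) p1 else NA_real_,
    p_pc2 = if (length(p2)) p2 else NA_real_,
    !!!rank_summary,
    fold_change_effect = fold_change_effect,
    abundance_effect = abundance_effect
  )
}

#' Score a processed table against spike-in ground truth (PLS-DA)
#'
#' Fits the cross-validated PLS-DA model and records R2, Q2 and their
#' difference. Tables with residual missing values (no-imputation
#' permutations) are reported as not evaluable rather than failed.
#'
#' @param processed a processed `peak_table`.
#' @param classes,max_comp,n_folds,seed passed to [fit_plsda()].
#' @return A one-row tibble: `r2`, `q2`, `r2_minus_q2`, `n_comp`,
#'   `evaluable`.
#' @export
score_plsda <- function(processed, classes = NULL, max_comp = 5,
                        n_folds = 10, seed = 1) {
  sub <- processed[which(!processed$samples$is_qc), ]
  if (!is_complete(sub)) {
    return(tibble::tibble(r2 = NA_real_, q2 = NA_real_,
                          r2_minus_q2 = NA_real_, n_comp = NA_integer_,
                          evaluable = FALSE))
  }
  m <- fit_plsda(processed, classes = classes, max_comp = max_comp,
                 n_folds = n_folds, seed = seed)
  tibble::tibble(r2 = m$r2[m$n_comp], q2 = m$q2[m$n_comp],
                 r2_minus_q2 = m$r2[m$n_comp] - m$q2[m$n_comp],
                 n_comp = m$n_comp, evaluable = TRUE)
}

#' Run and score a grid of processing permutations
#'
#' Evaluates every permutation of the grid on a spiked table: applies the
#' pipeline stages (normalisation and imputation results are cached and
#' reused across permutations sharing them), then scores the processed
#' table under the univariate, PCA and PLS-DA criteria. Stage failures
#' (e.g. natural log of a non-positive value) are captured per permutation
#' and recorded as failed rows; they never abort the run.
#'
#' @param table a filtered `peak_table` (typically spiked and with injected
#'   missingness).
#' @param plan spike plan tibble; use an empty plan for null runs.
#' @param grid tibble from [enumerate_grid()] (default: the full 280-row
#'   grid).
#' @param classes length-2 class labels (default: first two present).
#' @param modes which criteria to score (subset of `"univariate"`, `"pca"`,
#'   `"plsda"`).
#' @param test,alpha univariate screen settings.
#' @param seed seed for stochastic stages and the CV fold split.
#' @param knn_k,rf_trees,rf_max_iter,max_comp,n_folds tuning parameters.
#' @param verbose print one line per permutation.
#' @return A tibble with one row per permutation: the stage columns, the
#'   scores of the requested modes, and columns `failed`, `error`.
#' @export
run_benchmark <- function(table, plan, grid = enumerate_grid(),
                          classes = NULL,
                          modes = c("univariate", "pca", "plsda"),
                          test = "mann-whitney", alpha = 0.05, seed = 1,
                          knn_k = 10, rf_trees = 100, rf_max_iter = 10,
                          max_comp = 5, n_folds = 10, verbose = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  norm_cache <- list()
  imp_cache <- list()
  lambda_cache <- list()

  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- tryCatch({
      nk <- g$normalisation
      if (is.null(norm_cache[[nk]])) {
        norm_cache[[nk]] <<- switch(nk, SUM = normalise_sum(table),
                                    PQN = normalise_pqn(table))
      }
      ik <- paste(nk, g$mvi, sep = "/")
      if (is.null(imp_cache[[ik]])) {
        imp_cache[[ik]] <<- impute_by_name(norm_cache[[nk]], g$mvi,
                                           knn_k = knn_k,
                                           rf_trees = rf_trees,
                                           rf_max_iter = rf_max_iter,
                                           seed = seed)
      }
      proc <- imp_cache[[ik]]
      lam <- NULL
      if (g$transformation == "glog") {
        if (is.null(lambda_cache[[ik]])) {
          lambda_cache[[ik]] <<- optimize_lambda(proc)
        }
        lam <- lambda_cache[[ik]]
      }
      proc <- transform_table(proc, g$transformation, lambda = lam)
      proc <- suppressWarnings(scale_table(proc, g$scaling))

      res <- tibble::tibble(failed = FALSE, error = NA_character_)
      if ("univariate" %in% modes) {
        res <- dplyr::bind_cols(res, score_univariate(
          proc, plan, classes = classes, test = test, alpha = alpha))
      }
      if ("pca" %in% modes) {
        res <- dplyr::bind_cols(res, score_pca(proc, plan,
                                               classes = classes))
      }
      if ("plsda" %in% modes) {
        res <- dplyr::bind_cols(res, score_plsda(
          proc, classes = classes, max_comp = max_comp, n_folds = n_folds,
          seed = seed))
      }
      res
    }, error = function(e) {
      tibble::tibble(failed = TRUE, error = conditionMessage(e))
    })
    if (verbose) {
      message(g$perm_id, if (out$failed[1]) paste0(" FAILED: ", out$error[1]))
    }
    dplyr::bind_cols(g, out)
  })
  dplyr::bind_rows(rows)
}

#' Rank benchmark outcomes
#'
#' Orders the permutation outcomes the way the benchmarking study reports
#' them. `univariate`: most true positives first, fewest false positives
#' second. `pca`: only permutations showing a fold-change effect and no
#' abundance effect are ranked, by PC1 score p-value (ascending) then
#' PC1+PC2 variance (descending). `plsda`: only evaluable rows with
#' `r2 - q2 < overfit_bound` are ranked, by R2 descending. Ties are broken
#' by permutation id, so the order is total and reproducible.
#'
#' @param outcomes tibble from [run_benchmark()].
#' @param mode `"univariate"`, `"pca"` or `"plsda"`.
#' @param overfit_bound maximum tolerated `r2 - q2` for PLS-DA ranking
#'   (default 0.20).
#' @return The filtered, ordered outcome tibble.
#' @export
rank_permutations <- function(outcomes, mode = c("univariate", "pca",
                                                 "plsda"),
                              overfit_bound = 0.20) {
  mode <- match.arg(mode)
  ok <- dplyr::filter(outcomes, !.data$failed)
  switch(mode,
    univariate = dplyr::arrange(ok, dplyr::desc(.data$tp), .data$fp,
                                .data$perm_id),
    pca = {
      keep <- dplyr::filter(ok, .data$fold_change_effect,
                            !.data$abundance_effect)
      dplyr::arrange(keep, .data$p_pc1,
                     dplyr::desc(.data$var_pc1 + .data$var_pc2),
                     .data$perm_id)
    },
    plsda = {
      keep <- dplyr::filter(ok, .data$evaluable,
                            .data$r2_minus_q2 < overfit_bound)
      dplyr::arrange(keep, dplyr::desc(.data$r2), .data$perm_id)
    }
  )
}
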