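#' Tidy a NIPALS PCA model
#'
#' @param x a `pca_model`.
#' @param matrix which quantity to return: `"scores"` (default, one row per
#'   sample and component, with class and QC metadata), `"loadings"` (one
#'   row per feature and component) or `"variance"` (one row per
#'   component, with the score-separation p-value where available).
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings", "variance"),
                           ...) {
  matrix <- match.arg(matrix)
  comp <- colnames(x$scores)
  switch(matrix,
    scores = tidyr::pivot_longer(
      dplyr::bind_cols(x$samples, tibble::as_tibble(x$scores)),
      dplyr::all_of(comp), names_to = "component", values_to = "score"
    ),
    loadings = tidyr::pivot_longer(
      dplyr::bind_cols(x$features["feature_id"],
                       tibble::as_tibble(x$loadings)),
      dplyr::all_of(comp), names_to = "component", values_to = "loading"
    ),
    variance = dplyr::left_join(
      tibble::tibble(component = comp, var_pct = x$var_pct),
      x$score_tests, by = "component"
    )
  )
}

#' @rdname tidy.pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_comp = x$n_comp,
    var_pc1 = x$var_pct[1],
    var_pc2 = if (x$n_comp >= 2) x$var_pct[2] else NA_real_,
    total_var_pct = sum(x$var_pct),
    p_pc1 = if (nrow(x$score_tests)) x$score_tests$p[1] else NA_real_
  )
}

#' Tidy a PLS-DA model
#'
#' @param x a `plsda_model`.
#' @param matrix `"components"` (default: per-component R2 and Q2),
#'   `"scores"` or `"loadings"`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.plsda_model <- function(x, matrix = c("components", "scores",
                                           "loadings"), ...) {
  matrix <- match.arg(matrix)
  comp <- colnames(x$scores)
  switch(matrix,
    components = tibble::tibble(
      component = comp, r2 = x$r2, q2 = x$q2,
      optimal = seq_along(comp) == x$n_comp
    ),
    scores = tidyr::pivot_longer(
      dplyr::bind_cols(x$samples, tibble::as_tibble(x$scores)),
      dplyr::all_of(comp), names_to = "component", values_to = "score"
    ),
    loadings = tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(feature_id = rownames(x$loadings)),
                       tibble::as_tibble(x$loadings)),
      dplyr::all_of(comp), names_to = "component", values_to = "loading"
    )
  )
}

#' @rdname tidy.plsda_model
#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(
    n_comp = x$n_comp,
    r2 = x$r2[x$n_comp],
    q2 = x$q2[x$n_comp],
    r2_minus_q2 = x$r2[x$n_comp] - x$q2[x$n_comp]
  )
}
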