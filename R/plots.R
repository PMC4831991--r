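# shared score-plot builder for PCA / PLS-DA models
score_plot <- function(samples, scores, xlab, ylab, title) {
  df <- dplyr::bind_cols(samples, tibble::as_tibble(scores[, 1:2]))
  names(df)[(ncol(df) - 1):ncol(df)] <- c(".x", ".y")
  df$group <- ifelse(df$is_qc, "QC", df$class)
  ggplot2::ggplot(df, ggplot2::aes(.data$.x, .data$.y,
                                   colour = .data$group,
                                   shape = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xlab, y = ylab, colour = NULL, shape = NULL,
                  title = title) +
    ggplot2::theme_bw()
}

#' Score plot for a NIPALS PCA model
#'
#' PC1 vs PC2 scores coloured by class, with QC samples as their own
#' group; axis labels carry the explained variance.
#'
#' @param object a `pca_model` with at least 2 components.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pca_model <- function(object, ...) {
  if (object$n_comp < 2) stop("need at least 2 components to plot",
                              call. = FALSE)
  score_plot(object$samples, object$scores,
             sprintf("PC1 (%.1f%%)", object$var_pct[1]),
             sprintf("PC2 (%.1f%%)", object$var_pct[2]),
             "PCA scores")
}

#' Score plot for a PLS-DA model
#'
#' @param object a `plsda_model` with at least 2 latent variables.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.plsda_model <- function(object, ...) {
  if (ncol(object$scores) < 2) stop("need at least 2 latent variables",
                                    call. = FALSE)
  score_plot(object$samples, object$scores, "LV1", "LV2",
             sprintf("PLS-DA scores (R2 = %.2f, Q2 = %.2f)",
                     object$r2[object$n_comp], object$q2[object$n_comp]))
}

#' Bar chart of imputation NRMSE results
#'
#' @param assessment tibble from [assess_mvi()] (one or more seeds bound
#'   together).
#' @return A ggplot object.
#' @export
plot_mvi_assessment <- function(assessment) {
  ggplot2::ggplot(assessment,
                  ggplot2::aes(stats::reorder(.data$method, .data$nrmse),
                               .data$nrmse)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "steelblue") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "NRMSE") +
    ggplot2::theme_bw()
}
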