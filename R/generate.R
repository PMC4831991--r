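#' Generator settings for synthetic two-class peak tables
#'
#' Defines the study conditions the generator emulates: a two-class
#' UHPLC-MS serum-style experiment with pooled QC replicates. Feature
#' intensities are log-normal with a low-rank latent covariance (metabolite
#' features co-vary in blocks, as correlated features of shared metabolites
#' do), a per-sample multiplicative scale models injection-volume and
#' sensitivity drift, and QC samples are technical replicates of the pooled
#' mean profile with a small technical CV.
#'
#' @param n_per_class integer vector of biological sample counts per class;
#'   names are the class labels (defaults to the unequal 22/24 split of a
#'   randomised two-class serum study).
#' @param n_qc number of pooled-QC injections.
#' @param n_features number of metabolite features.
#' @param latent_rank number of latent factors (feature clusters) driving
#'   feature-feature correlation; every feature loads positively on exactly
#'   one factor, emulating the positively correlated feature blocks that
#'   multi-feature metabolites produce.
#' @param base_log_mean_range interval (natural-log intensity units) from
#'   which per-feature base log-means are drawn uniformly.
#' @param loading_sd scale of latent factor loadings: a feature's loading
#'   magnitude is |N(0, loading_sd * sqrt(latent_rank))|, so the
#'   per-feature latent variance is latent_rank * loading_sd^2 on average
#'   (log-intensity units).
#' @param noise_sd per-cell idiosyncratic biological noise (log scale).
#' @param sample_scale_sd standard deviation (log scale) of the per-sample
#'   multiplicative scale factor.
#' @param qc_cv technical coefficient of variation of QC replicates; must be
#'   below the biological CV implied by `loading_sd`/`noise_sd`.
#' @param missing_rate fraction of cells masked by [inject_missing()] when
#'   the generator pipeline is asked for missingness.
#' @param mnar_weight fraction of masked cells selected
#'   abundance-dependently (below-limit-of-detection emulation); 0 = pure
#'   MCAR.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_per_class = c(A = 22, B = 24),
                             n_qc = 18,
                             n_features = 3000,
                             latent_rank = 3,
                             base_log_mean_range = log(c(1e4, 1e7)),
                             loading_sd = 0.20,
                             noise_sd = 0.25,
                             sample_scale_sd = 0.08,
                             qc_cv = 0.05,
                             missing_rate = 0.10,
                             mnar_weight = 0) {
  if (is.null(names(n_per_class))) {
    names(n_per_class) <- LETTERS[seq_along(n_per_class)]
  }
  stopifnot(all(n_per_class >= 1), n_qc >= 0, n_features >= 1,
            latent_rank >= 0, missing_rate >= 0, missing_rate < 1,
            mnar_weight >= 0, mnar_weight <= 1,
            qc_cv >= 0, loading_sd >= 0, noise_sd >= 0, sample_scale_sd >= 0)
  bio_cv <- sqrt(exp(latent_rank * loading_sd^2 + noise_sd^2) - 1)
  if (qc_cv >= bio_cv && (loading_sd > 0 || noise_sd > 0)) {
    stop("qc_cv must be below the biological CV (", signif(bio_cv, 3), ")",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a complete null two-class peak table
#'
#' Draws a complete (no missing cells) peak table with no induced class
#' effect: biological samples share one latent log-normal model and class
#' labels are assigned by randomisation. To mirror a null randomisation in
#' which no feature is significant, labels are re-drawn (up to 20 times)
#' until no feature has a Benjamini-Hochberg adjusted Mann-Whitney p-value
#' below 0.05 between the first two classes.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return A complete [peak_table()] with QC rows flagged.
#' @export
generate_peak_table <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(seed, {
    p <- config$n_features
    n_bio <- sum(config$n_per_class)
    r <- config$latent_rank

    mu <- stats::runif(p, config$base_log_mean_range[1],
                       config$base_log_mean_range[2])
    # cluster-structured loadings: each feature loads positively on one
    # latent factor, giving the positively correlated feature blocks that
    # multi-feature metabolites and co-regulated pathways produce
    L <- matrix(0, p, max(r, 1))
    if (r > 0) {
      cluster <- sample.int(r, p, replace = TRUE)
      L[cbind(seq_len(p), cluster)] <-
        abs(stats::rnorm(p, sd = config$loading_sd * sqrt(r)))
    }
    Z <- matrix(stats::rnorm(n_bio * max(r, 1)), n_bio, max(r, 1))
    eps <- matrix(stats::rnorm(n_bio * p, sd = config$noise_sd), n_bio, p)
    log_bio <- sweep(Z %*% t(L) + eps, 2, mu, "+")
    bio <- exp(log_bio)

    # pooled QC profile: mean over biological samples, technical noise only
    if (config$n_qc > 0) {
      pooled <- colMeans(bio)
      sdlog_qc <- sqrt(log(1 + config$qc_cv^2))
      qc <- matrix(rep(pooled, each = config$n_qc), config$n_qc, p) *
        exp(matrix(stats::rnorm(config$n_qc * p, sd = sdlog_qc),
                   config$n_qc, p))
    } else {
      qc <- matrix(numeric(0), 0, p)
    }

    mat <- rbind(bio, qc)
    scales <- exp(stats::rnorm(nrow(mat), sd = config$sample_scale_sd))
    mat <- mat * scales

    labels <- rep(names(config$n_per_class), config$n_per_class)
    assign_ok <- FALSE
    for (try in seq_len(20)) {
      lab <- sample(labels)
      cls <- names(config$n_per_class)[1:2]
      ia <- which(lab == cls[1]); ib <- which(lab == cls[2])
      pv <- vapply(seq_len(p), function(j) {
        suppressWarnings(stats::wilcox.test(mat[ia, j], mat[ib, j],
                                            exact = FALSE)$p.value)
      }, numeric(1))
      if (!any(stats::p.adjust(pv, "BH") < 0.05)) { assign_ok <- TRUE; break }
    }
    if (!assign_ok) {
      stop("could not find a null class randomisation in 20 attempts",
           call. = FALSE)
    }

    samples <- tibble::tibble(
      sample_id = c(sprintf("S%02d", seq_len(n_bio)),
                    if (config$n_qc > 0) sprintf("QC%02d", seq_len(config$n_qc))),
      class = c(lab, rep(NA_character_, config$n_qc)),
      is_qc = c(rep(FALSE, n_bio), rep(TRUE, config$n_qc))
    )
    features <- tibble::tibble(
      feature_id = sprintf("F%04d", seq_len(p)),
      mz = round(stats::runif(p, 100, 1000), 4),
      rt = round(stats::runif(p, 30, 900), 1)
    )
    peak_table(mat, features, samples)
  })
}

#' Inject missing values into a peak table
#'
#' Masks cells until the table's total missing count reaches
#' `floor(rate * n_cells)`; starting from a complete table exactly that many
#' cells are masked. Cells already missing are never re-selected. With
#' `mnar_weight = 0` the selection is uniform over observed cells (MCAR);
#' with `mnar_weight > 0` that fraction of the new mask is drawn with
#' probability decreasing in intensity, emulating censoring below the limit
#' of detection (MNAR).
#'
#' @param table a `peak_table`.
#' @param rate target overall missing fraction in `[0, 1)`.
#' @param mnar_weight fraction of masked cells selected
#'   abundance-dependently.
#' @param seed integer seed.
#' @param allow_empty if `FALSE` (default), masking that leaves a sample or
#'   feature with no observed value is an error.
#' @return The table with added missing cells.
#' @export
inject_missing <- function(table, rate, mnar_weight = 0, seed = 1,
                           allow_empty = FALSE) {
  stopifnot(rate >= 0, rate < 1, mnar_weight >= 0, mnar_weight <= 1)
  n_cells <- length(table$intensities)
  target <- floor(rate * n_cells)
  already <- sum(is.na(table$intensities))
  n_new <- target - already
  if (n_new <= 0) return(table)
  obs_idx <- which(!is.na(table$intensities))
  if (n_new > length(obs_idx)) {
    stop("requested missing rate exceeds available observed cells",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    n_mnar <- round(mnar_weight * n_new)
    picked <- integer(0)
    if (n_mnar > 0) {
      x <- table$intensities[obs_idx]
      # selection probability decreasing in intensity: inverse-rank weights
      w <- (length(x) + 1 - rank(x, ties.method = "average"))
      picked <- sample(obs_idx, n_mnar, prob = w)
    }
    rest <- setdiff(obs_idx, picked)
    if (n_new - n_mnar > 0) {
      picked <- c(picked, sample(rest, n_new - n_mnar))
    }
  })
  mat <- table$intensities
  mat[picked] <- NA_real_
  if (!allow_empty) {
    if (any(rowSums(!is.na(mat)) == 0) || any(colSums(!is.na(mat)) == 0)) {
      stop("masking left a sample or feature with no observed values; ",
           "set allow_empty = TRUE to permit this", call. = FALSE)
    }
  }
  set_intensities(table, mat)
}

#' Default spike-in fold-factor grid
#'
#' Multiplicative factors 0.1 to 2.0 in steps of 0.1 plus 2.5 to 10.0 in
#' steps of 0.5 (36 values).
#'
#' @return Numeric vector of 36 factors.
#' @export
default_factor_grid <- function() {
  c(seq(0.1, 2.0, by = 0.1), seq(2.5, 10.0, by = 0.5))
}

#' Construct a spike-in modified dataset
#'
#' Introduces known between-class differences to benchmark processing
#' pipelines: features are split into three abundance tertiles by their mean
#' response, `n_per_tertile` features are drawn at random from each tertile,
#' and each drawn feature's intensities in the target class are multiplied
#' by a fold factor sampled from `factor_grid`. All other cells are
#' untouched.
#'
#' @param table a `peak_table` (typically complete; spiking precedes
#'   missingness injection).
#' @param n_per_tertile features modified per abundance tertile (default 32,
#'   i.e. 96 spiked features in total).
#' @param factor_grid candidate fold factors; sampled without replacement
#'   per tertile when possible (with replacement only if `n_per_tertile`
#'   exceeds the grid size).
#' @param target_class class whose samples are modified (default the first
#'   class label).
#' @param seed integer seed.
#' @param tertile_method `"rank"` (equal feature counts per tertile,
#'   default) or `"range"` (thirds of the numeric range of mean responses).
#' @return A list with elements `table` (modified `peak_table`) and `plan`
#'   (tibble with `feature_id`, `tertile`, `factor`, `target_class`,
#'   `mean_response`).
#' @export
construct_modified_dataset <- function(table, n_per_tertile = 32,
                                       factor_grid = default_factor_grid(),
                                       target_class = NULL, seed = 1,
                                       tertile_method = c("rank", "range")) {
  tertile_method <- match.arg(tertile_method)
  if (is.null(target_class)) target_class <- class_labels(table)[1]
  rows <- class_rows(table, target_class)
  if (length(rows) == 0L) stop("target class not found", call. = FALSE)

  means <- colMeans(table$intensities, na.rm = TRUE)
  if (any(!is.finite(means))) {
    stop("every feature needs at least one observed value", call. = FALSE)
  }
  lev <- c("low", "medium", "high")
  if (tertile_method == "rank") {
    tert <- lev[ceiling(3 * rank(means, ties.method = "first") /
                          length(means))]
  } else {
    br <- min(means) + diff(range(means)) * c(0, 1 / 3, 2 / 3, 1)
    tert <- lev[findInterval(means, br, rightmost.closed = TRUE,
                             all.inside = TRUE)]
  }
  if (any(table(factor(tert, levels = lev)) < n_per_tertile)) {
    stop("fewer than n_per_tertile features in some tertile", call. = FALSE)
  }

  mat <- table$intensities
  plan <- withr::with_seed(seed, {
    purrr::map_dfr(lev, function(tl) {
      cand <- which(tert == tl)
      feat <- sample(cand, n_per_tertile)
      fac <- sample(factor_grid, n_per_tertile,
                    replace = n_per_tertile > length(factor_grid))
      tibble::tibble(
        feature_id = table$features$feature_id[feat],
        tertile = tl, factor = fac,
        target_class = target_class,
        mean_response = means[feat]
      )
    })
  })
  cols <- match(plan$feature_id, table$features$feature_id)
  mat[rows, cols] <- sweep(mat[rows, cols, drop = FALSE], 2, plan$factor, "*")
  list(table = set_intensities(table, mat), plan = plan)
}
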