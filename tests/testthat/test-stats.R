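test_that("normality test behaves under null and alternative", {
  expect_error(test_normality(rep(3, 10)), "constant")
  withr::with_seed(10, {
    # null: p-values roughly uniform
    p_null <- replicate(200, test_normality(rnorm(50))$p.value)
    ks <- stats::ks.test(p_null, "punif")$p.value
    expect_gt(ks, 0.01)
    # skewed alternative: high rejection rate
    p_exp <- replicate(100, test_normality(rexp(100))$p.value)
    expect_gt(mean(p_exp < 0.05), 0.9)
  })
})

test_that("univariate screen controls error and applies BH correctly", {
  tab <- generate_peak_table(small_config(n_features = 200), seed = 5)
  scr <- univariate_screen(tab)
  expect_equal(nrow(scr), 200)
  expect_true(all(scr$q >= scr$p, na.rm = TRUE))
  rate <- mean(scr$p < 0.05, na.rm = TRUE)
  expect_lt(rate, 0.15)   # null table: near-nominal pre-adjustment rate
  expect_equal(sum(scr$significant), 0)

  # identical groups: Mann-Whitney p = 1
  same <- toy_table(matrix(rep(c(1, 2, 3, 7), 4), 8, 2), n_qc = 0,
                    classes = rep(c("A", "B"), each = 4))
  same$intensities[1:4, ] <- same$intensities[5:8, ]
  scr_same <- univariate_screen(same)
  expect_equal(scr_same$p, c(1, 1))

  # under-observed features are excluded from the BH family
  vals <- matrix(runif(12 * 3, 1, 2), 12, 3)
  vals[1:10, 3] <- NA
  sparse <- toy_table(vals, n_qc = 0, classes = rep(c("A", "B"), each = 6))
  scr_sparse <- univariate_screen(sparse)
  expect_true(is.na(scr_sparse$p[3]))
  expect_equal(scr_sparse$q[1:2],
               stats::p.adjust(scr_sparse$p[1:2], "BH"))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  withr::with_seed(19, {
    for (i in 1:20) {
      p <- runif(50)
      expect_equal(stats::p.adjust(p, "BH"), brute_bh(p))
    }
  })
})

test_that("NIPALS PCA matches the SVD on complete data", {
  tab <- structured_table(n = 14, p = 10, seed = 6)
  model <- fit_pca_nipals(tab, n_comp = 4)
  X <- sweep(tab$intensities, 2, colMeans(tab$intensities))
  sv <- svd(X)
  for (a in 1:4) {
    expect_lt(min(max(abs(model$scores[, a] - sv$u[, a] * sv$d[a])),
                  max(abs(model$scores[, a] + sv$u[, a] * sv$d[a]))), 1e-8)
    expect_lt(min(max(abs(model$loadings[, a] - sv$v[, a])),
                  max(abs(model$loadings[, a] + sv$v[, a]))), 1e-8)
  }
  expect_equal(model$var_pct, 100 * sv$d[1:4]^2 / sum(sv$d^2),
               tolerance = 1e-10)
  expect_true(all(diff(model$var_pct) <= 1e-8))
  expect_lte(sum(model$var_pct), 100 + 1e-8)
})

test_that("PCA handles collinear and missing data", {
  # two exactly collinear features: PC1 carries all variance
  base <- c(1, 4, 2, 8, 5)
  tab <- toy_table(cbind(base, 3 * base), n_qc = 0,
                   classes = c("A", "B", "A", "B", "A"))
  model <- fit_pca_nipals(tab, n_comp = 2)
  expect_equal(model$var_pct[1], 100)

  # missing data: loadings stay unit length, variance stays bounded
  tab2 <- inject_missing(random_table(n = 16, p = 12, n_qc = 0, seed = 9),
                         0.1, seed = 9)
  m2 <- fit_pca_nipals(tab2, n_comp = 3)
  expect_equal(unname(colSums(m2$loadings^2)), rep(1, 3))
  expect_true(all(m2$var_pct >= 0 & m2$var_pct <= 100))
})

test_that("PCA separates well-separated classes along PC1", {
  withr::with_seed(33, {
    shift <- c(rep(0, 10), rep(6, 10))
    vals <- matrix(rnorm(20 * 8), 20, 8) + 20
    vals[, 1] <- vals[, 1] + shift
  })
  tab <- toy_table(vals, n_qc = 0, classes = rep(c("A", "B"), each = 10))
  model <- fit_pca_nipals(tab)
  expect_lt(model$score_tests$p[1], 1e-4)
})

test_that("PLS-DA separates signal and stays honest under the null", {
  withr::with_seed(44, {
    vals <- matrix(rnorm(24 * 15), 24, 15) + 10
    vals[, 1] <- vals[, 1] + c(rep(0, 12), rep(10, 12))
  })
  tab <- toy_table(vals, n_qc = 0, classes = rep(c("A", "B"), each = 12))
  m <- fit_plsda(tab, seed = 2)
  expect_gt(m$r2[1], 0.9)
  expect_gt(m$q2[m$n_comp], 0.5)
  # R2 is non-decreasing in the component count
  expect_true(all(diff(m$r2) >= -1e-10))
  # Q2 never exceeds R2 (up to numerical tolerance)
  expect_true(all(m$q2 <= m$r2 + 1e-8))

  # permuted labels: no cross-validated signal
  withr::with_seed(45, {
    null_q2 <- replicate(30, {
      shuf <- tab
      shuf$samples$class <- sample(shuf$samples$class)
      mm <- fit_plsda(shuf, max_comp = 2, seed = 3)
      max(mm$q2)
    })
  })
  expect_gte(mean(null_q2 <= 0.05), 0.9)

  expect_error(fit_plsda(tab, n_folds = 15), "n_folds")
  miss <- inject_missing(tab, 0.05, seed = 1)
  expect_error(fit_plsda(miss), "complete")
})

test_that("tidy, glance and autoplot methods return well-formed output", {
  tab <- random_table(n = 14, p = 10, n_qc = 2, seed = 12)
  pca <- fit_pca_nipals(tab)
  expect_equal(nrow(tidy(pca, "scores")), 14 * 2)
  expect_equal(nrow(tidy(pca, "loadings")), 10 * 2)
  expect_equal(nrow(glance(pca)), 1)
  expect_s3_class(autoplot(pca), "ggplot")

  vals <- tab$intensities
  plsda <- fit_plsda(tab, max_comp = 3, n_folds = 3, seed = 1)
  expect_equal(nrow(tidy(plsda)), 3)
  expect_equal(glance(plsda)$r2, plsda$r2[plsda$n_comp])
  expect_s3_class(autoplot(plsda), "ggplot")
})
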