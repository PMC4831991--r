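# shared small spiked dataset for benchmark tests (built once per run)
bench_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tab <- generate_peak_table(small_config(n_features = 120), seed = 4)
      mod <- construct_modified_dataset(tab, n_per_tertile = 8, seed = 4)
      miss <- inject_missing(mod$table, 0.08, seed = 4)
      cache <<- list(tab = tab, mod = mod, miss = miss)
    }
    cache
  }
})

test_that("run_permutation applies stages in order and is deterministic", {
  fx <- bench_fixture()
  # single active stage equals calling that stage directly
  out <- run_permutation(fx$miss, c("SUM", "none", "none", "none"))
  expect_equal(out$intensities, normalise_sum(fx$miss)$intensities)

  a <- run_permutation(fx$miss, c("PQN", "RF", "glog", "none"), seed = 5,
                       rf_trees = 30)
  b <- run_permutation(fx$miss, c("PQN", "RF", "glog", "none"), seed = 5,
                       rf_trees = 30)
  expect_identical(a$intensities, b$intensities)
  expect_equal(attr(a, "permutation")$transformation, "glog")

  expect_error(run_permutation(fx$miss, c("SUM", "bogus", "none", "none")),
               "unknown")
})

test_that("univariate scoring conserves counts and respects the plan", {
  fx <- bench_fixture()
  proc <- run_permutation(fx$miss, c("PQN", "none", "none", "none"))
  sc <- score_univariate(proc, fx$mod$plan)
  expect_equal(sc$tp + sc$fp, sc$total_significant)
  expect_lte(sc$tp, nrow(fx$mod$plan))

  # empty plan: everything significant is a false positive
  sc0 <- score_univariate(proc, fx$mod$plan[0, ])
  expect_equal(sc0$tp, 0L)
  expect_equal(sc0$fp, sc0$total_significant)
})

test_that("PCA scoring flags fold-change and abundance effects sensibly", {
  fx <- bench_fixture()
  proc <- run_permutation(fx$miss, c("PQN", "MN", "glog", "none"))
  sc <- score_pca(proc, fx$mod$plan)
  expect_true(sc$rank_best_comb >= 1)
  expect_true(sc$var_pc1 > 0 && sc$var_pc1 <= 100)

  # no spiking: no fold-change effect to find
  null_tab <- generate_peak_table(small_config(n_features = 100), seed = 9)
  null_proc <- run_permutation(inject_missing(null_tab, 0.05, seed = 9),
                               c("PQN", "MN", "none", "none"))
  sc0 <- score_pca(null_proc, fx$mod$plan[0, ])
  expect_false(sc0$fold_change_effect)

  # untransformed, unscaled data: loadings track abundance
  raw <- run_permutation(fx$miss, c("SUM", "MN", "none", "none"))
  sc_raw <- score_pca(raw, fx$mod$plan)
  expect_true(sc_raw$abundance_effect)
})

test_that("PLS-DA scoring marks incomplete tables as non-evaluable", {
  fx <- bench_fixture()
  with_missing <- run_permutation(fx$miss, c("PQN", "none", "none", "none"))
  sc <- score_plsda(with_missing)
  expect_false(sc$evaluable)
  expect_true(is.na(sc$r2))

  complete <- run_permutation(fx$miss, c("PQN", "KNN", "glog", "none"))
  sc2 <- score_plsda(complete, seed = 2)
  expect_true(sc2$evaluable)
  expect_gte(sc2$r2, sc2$q2)
})

test_that("the grid runner captures failures instead of aborting", {
  fx <- bench_fixture()
  # a table with a zero cell: nlog permutations must fail gracefully
  mat <- fx$miss$intensities
  mat[1, 1] <- 0
  zero_tab <- set_intensities_for_test(fx$miss, mat)
  grid <- enumerate_grid(list(normalisation = "SUM", mvi = "none",
                              transformation = c("none", "nlog"),
                              scaling = "none"))
  out <- run_benchmark(zero_tab, fx$mod$plan, grid, modes = "univariate")
  expect_equal(nrow(out), 2)
  nlog_row <- out[out$transformation == "nlog", ]
  expect_true(nlog_row$failed)
  expect_match(nlog_row$error, "non-positive")
  expect_false(out$failed[out$transformation == "none"])
})

test_that("benchmark outcomes rank deterministically per mode", {
  fx <- bench_fixture()
  grid <- enumerate_grid(list(mvi = c("none", "MN"),
                              transformation = c("none", "glog"),
                              scaling = "none"))
  out <- run_benchmark(fx$miss, fx$mod$plan, grid, seed = 3)
  expect_equal(nrow(out), 8)
  expect_true(all(out$tp + out$fp == out$total_significant, na.rm = TRUE))

  uni <- rank_permutations(out, "univariate")
  expect_true(all(diff(uni$tp) <= 0 | diff(uni$fp) >= 0))
  # duplicated outcomes keep a stable, total order
  expect_equal(rank_permutations(out[rev(seq_len(8)), ], "univariate"),
               uni)

  pca <- rank_permutations(out, "pca")
  expect_true(all(pca$fold_change_effect & !pca$abundance_effect))
  expect_true(!is.unsorted(pca$p_pc1))

  pls <- rank_permutations(out, "plsda")
  expect_true(all(pls$evaluable))
  expect_true(all(pls$r2_minus_q2 < 0.20))
  expect_true(!is.unsorted(-pls$r2))

  # mvi = none rows cannot be PLS-DA-evaluable with residual missingness
  expect_true(all(!out$evaluable[out$mvi == "none"]))
})
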