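test_that("WMW AUC matches pair-counting examples and handles errors", {
  expect_equal(auc_wmw(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_wmw(rep(2, 6), rep(c(1, 0), 3)), 0.5)
  expect_equal(auc_wmw(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(auc_wmw(1:3, c(1, 1, 1)), "both classes")
  expect_error(auc_wmw(1:3, c(1, 0)), "length")
})

test_that("inner selection picks j* by average inner AUC with small-j ties", {
  d <- toy_gaussian(20, 20, 30, delta = 4, n_informative = 10, seed = 1)
  sel <- inner_select_j(d, "FS1", "DLDA", grid = 5L, seed = 2)
  expect_identical(sel$j_star, 5L)  # singleton grid: forced choice

  # perfectly separable at every j: tie resolved toward the smallest grid value
  sel2 <- inner_select_j(d, "FS1", "DLDA", grid = c(2L, 4L, 8L), seed = 2)
  expect_true(all(sel2$mean_auc == 1))
  expect_identical(sel2$j_star, 2L)

  # pure noise: inner AUCs hover near 0.5 for every j
  d0 <- toy_gaussian(20, 20, 30, delta = 0, seed = 3)
  sel3 <- inner_select_j(d0, "FS1", "DLDA", grid = c(2L, 5L, 10L), seed = 4)
  expect_true(all(abs(sel3$mean_auc - 0.5) < 0.12))

  expect_error(inner_select_j(d, "FS1", "DLDA", grid = c(2L, 40L), seed = 1),
               "exceeds")
})

test_that("outer 10x5-CV is deterministic and honest on known signal", {
  d <- toy_gaussian(25, 35, 40, delta = 1.5, n_informative = 6, seed = 5)
  e1 <- outer_cv_10x5(d, "FS1", "DLDA", c(2L, 4L, 6L), seed = 6,
                      outer_repeats = 3L, inner_repeats = 2L)
  e2 <- outer_cv_10x5(d, "FS1", "DLDA", c(2L, 4L, 6L), seed = 6,
                      outer_repeats = 3L, inner_repeats = 2L)
  expect_identical(e1$auc, e2$auc)
  expect_identical(e1$fold_aucs, e2$fold_aucs)
  expect_equal(e1$ci, c(e1$auc - 1.96 * e1$sem, e1$auc + 1.96 * e1$sem))
  expect_true(e1$auc > 0.8 && e1$auc <= 1)
  expect_true(all(e1$j_star %in% c(2L, 4L, 6L)))
})

test_that("a data-independent rule collapses both estimators to its test AUC", {
  d <- toy_gaussian(15, 15, 10, delta = 1, seed = 7)
  rule <- fixed_score_rule(function(x) x[, 1])
  plain <- auc_wmw(d$values[, 1], d$labels)

  cv <- outer_cv_10x5(d, "FS1", rule, grid = 2L, seed = 8,
                      outer_repeats = 4L)
  expect_equal(cv$auc, plain, tolerance = 0.06)  # fold-averaged vs pooled

  lpo <- lpo_bootstrap(d, "FS1", rule, grid = 2L, B = 150, seed = 8)
  expect_equal(lpo$auc, plain, tolerance = 1e-10)
})

test_that("the LPO SEM tracks the estimator's true sampling variance", {
  # across independently drawn worlds of the same size, the delta-method SEM
  # should agree with the Monte-Carlo variance of the estimate within 2x
  prof <- difficulty_profile(40, 60, 8, seq(1.2, 0.6, length.out = 8), 0.4)
  grid <- c(2L, 4L, 8L)
  est <- t(vapply(1:20, function(s) {
    g <- generate_dataset(prof, seed = 900 + s)
    l <- lpo_bootstrap(g$train, "FS1", "DLDA", grid, B = 120, seed = s)
    c(auc = l$auc, sem2 = l$sem^2)
  }, numeric(2)))
  ratio <- mean(est[, "sem2"]) / var(est[, "auc"])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("LPO bootstrap covers pairs, errors on tiny B, stays deterministic", {
  d <- toy_gaussian(12, 14, 25, delta = 1.2, n_informative = 5, seed = 9)
  l1 <- lpo_bootstrap(d, "FS1", "DLDA", c(2L, 5L), B = 60, seed = 10,
                      inner_repeats = 2L)
  l2 <- lpo_bootstrap(d, "FS1", "DLDA", c(2L, 5L), B = 60, seed = 10,
                      inner_repeats = 2L)
  expect_identical(l1$auc, l2$auc)
  expect_identical(l1$sem, l2$sem)
  expect_true(l1$auc >= 0 && l1$auc <= 1)
  expect_gte(l1$sem, 0)
  expect_error(lpo_bootstrap(d, "FS1", "DLDA", c(2L, 5L), B = 2, seed = 1,
                             inner_repeats = 1L),
               "increase B")
})

test_that("conditional and mean validation behave at the extremes", {
  d <- toy_gaussian(15, 15, 12, delta = 5, n_informative = 4, seed = 11)
  # validation identical to training data, separable -> AUC 1
  res <- conditional_validation(d, d, "FS1", "DLDA", c(2L, 4L), seed = 12,
                                inner_repeats = 2L)
  expect_equal(res$auc, 1.0)

  # pure noise -> validation AUC near 1/2; deterministic under the seed
  d0 <- toy_gaussian(15, 15, 12, delta = 0, seed = 13)
  v0 <- toy_gaussian(20, 20, 12, delta = 0, seed = 14)
  r1 <- conditional_validation(d0, v0, "FS1", "DLDA", c(2L, 4L), seed = 15,
                               inner_repeats = 2L)
  r2 <- conditional_validation(d0, v0, "FS1", "DLDA", c(2L, 4L), seed = 15,
                               inner_repeats = 2L)
  expect_identical(r1$auc, r2$auc)
  expect_lt(abs(r1$auc - 0.5), 0.25)
})

test_that("mean validation decomposes variance sensibly", {
  d <- toy_gaussian(15, 15, 10, delta = 1, seed = 16)
  v <- toy_gaussian(25, 25, 10, delta = 1, seed = 17)
  rule <- fixed_score_rule(function(x) x[, 2])
  mv <- mean_validation(d, v, "FS1", rule, grid = 2L, B = 25, seed = 18)
  expect_lt(mv$var_train, 1e-20)  # no training sensitivity
  expect_equal(mv$mean_auc, auc_wmw(v$values[, 2], v$labels))

  mv2 <- mean_validation(d, v, "FS1", "DLDA", c(2L, 4L), B = 15, seed = 19,
                         inner_repeats = 2L)
  expect_gte(mv2$mean_auc, min(mv2$conditional_aucs))
  expect_lte(mv2$mean_auc, max(mv2$conditional_aucs))
  expect_gte(mv2$var_train, 0)
  expect_gte(mv2$var_test, 0)
})

test_that("RMSE comparison follows its definition", {
  expect_equal(rmse_compare(c(a = 0.8, b = 0.7), c(a = 0.8, b = 0.7)), 0)
  expect_equal(rmse_compare(c(0.9, 0.8), c(0.8, 0.5)), sqrt(0.05))
  expect_error(rmse_compare(c(a = 1), c(b = 1)), "mismatched")
  expect_error(rmse_compare(1:2, 1:3), "mismatched")
})

test_that("estimates are invariant to feature permutation", {
  d <- toy_gaussian(14, 16, 12, delta = 1.3, n_informative = 4, seed = 20)
  perm <- c(5:12, 1:4)
  dp <- make_ds(d$values[, perm], d$labels,
                feature_ids = d$feature_ids[perm])
  e1 <- outer_cv_10x5(d, "FS1", "DLDA", c(2L, 4L), seed = 21,
                      outer_repeats = 2L, inner_repeats = 2L)
  e2 <- outer_cv_10x5(dp, "FS1", "DLDA", c(2L, 4L), seed = 21,
                      outer_repeats = 2L, inner_repeats = 2L)
  expect_equal(e1$auc, e2$auc, tolerance = 1e-12)
})
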