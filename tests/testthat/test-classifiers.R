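specs <- c("LDA", "DLDA", "QDA", "LREG", "KNN3", "KNN11", "SVM05", "SVM2")

test_that("every algorithm separates well-separated clouds (training AUC 1)", {
  d <- toy_gaussian(12, 12, 4, delta = 6, seed = 1)
  for (nm in specs) {
    pred <- train_predictor(nm, d, 1:4)
    auc <- auc_wmw(score_samples(pred, d$values), d$labels)
    expect_equal(auc, 1.0, info = nm)
  }
})

test_that("scores are finite, oriented, and AUC-invariant to monotone maps", {
  d <- toy_gaussian(15, 15, 5, delta = 1.2, seed = 2)
  hold <- toy_gaussian(15, 15, 5, delta = 1.2, seed = 3)
  for (nm in specs) {
    pred <- train_predictor(nm, d, 1:5)
    sc <- score_samples(pred, hold$values)
    expect_true(all(is.finite(sc)), info = nm)
    a <- auc_wmw(sc, hold$labels)
    expect_gt(a, 0.5)  # orientation: larger favors the positive class
    expect_equal(auc_wmw(exp(3 * sc), hold$labels), a, info = nm)
  }
})

test_that("QDA feasibility: class size must exceed the feature count", {
  d <- toy_gaussian(8, 30, 10, delta = 1, seed = 4)
  expect_error(train_predictor("QDA", d, 1:10), "infeasible")
  # in the shrinkage band (j < n_c < j + 2) it falls back to pooled covariance
  d2 <- toy_gaussian(7, 30, 6, delta = 2, seed = 5)
  pred <- train_predictor("QDA", d2, 1:6)
  expect_true(all(is.finite(score_samples(pred, d2$values))))
})

test_that("DLDA equals LDA when the pooled sample covariance is diagonal", {
  # within-class residual columns chosen orthogonal with zero means, so the
  # pooled sample covariance is exactly diagonal and the two fits coincide
  r1 <- c(-1, -1, 1, 1) * 1.3
  r2 <- c(-1, 1, -1, 1) * 0.7
  x <- rbind(cbind(r1, r2), cbind(r1, r2)) +
    outer(rep(c(1, 0), each = 4), c(2, 1))
  d <- make_ds(x, rep(c(1L, 0L), each = 4))
  s_lda <- score_samples(train_predictor("LDA", d, 1:2), d$values)
  s_dlda <- score_samples(train_predictor("DLDA", d, 1:2), d$values)
  expect_equal(s_lda, s_dlda, tolerance = 1e-10)
})

test_that("KNN scores are neighbor fractions with deterministic ties", {
  d <- make_ds(cbind(c(0, 0.1, 0.2, 5, 5.1, 5.2)), c(1L, 1L, 1L, 0L, 0L, 0L))
  pred <- train_predictor("KNN3", d, 1L)
  sc <- score_samples(pred, cbind(c(0.05, 5.05)))
  expect_true(all(sc %in% c(0, 1 / 3, 2 / 3, 1)))
  expect_equal(sc, c(1, 0))  # positive cluster neighborly, negative not
  # exact distance ties resolved by training sample order, reproducibly
  d2 <- make_ds(cbind(c(0, 0, 0, 1, 1, 1)), c(1L, 0L, 1L, 0L, 1L, 0L))
  p2 <- train_predictor("KNN3", d2, 1L)
  expect_identical(score_samples(p2, cbind(0.0)),
                   score_samples(p2, cbind(0.0)))
})

test_that("logistic regression scores the class boundary at 0", {
  d <- make_ds(cbind(c(-2, -1, -1.5, 1, 1.5, 2)), c(0L, 0L, 0L, 1L, 1L, 1L))
  pred <- train_predictor("LREG", d, 1L)
  expect_lt(abs(score_samples(pred, cbind(0))), 1e-6)
})

test_that("training is deterministic and ignores extra features", {
  d <- toy_gaussian(10, 10, 6, delta = 1, seed = 7)
  for (nm in c("LDA", "DLDA", "LREG", "SVM05")) {
    p1 <- train_predictor(nm, d, 2:4)
    p2 <- train_predictor(nm, d, 2:4)
    expect_identical(score_samples(p1, d$values), score_samples(p2, d$values))
  }
  expect_error(score_samples(train_predictor("DLDA", d, 1:3),
                             d$values[, 1:4]), "feature")
})

test_that("KNN11 replicates vary less than KNN3 across bootstrap trainings", {
  wins <- 0
  for (s in 1:20) {
    d <- toy_gaussian(25, 35, 40, delta = 0.6, n_informative = 8,
                      seed = 100 + s)
    hold <- toy_gaussian(30, 40, 40, delta = 0.6, n_informative = 8,
                         seed = 200 + s)
    v <- sapply(c("KNN3", "KNN11"), function(nm) {
      aucs <- vapply(1:12, function(b) {
        bs <- stratified_bootstrap(d$labels, seed = s * 50 + b)
        pred <- train_predictor(nm, subset_samples(d, bs$idx), 1:8)
        auc_wmw(score_samples(pred, hold$values), hold$labels)
      }, numeric(1))
      var(aucs)
    })
    if (v["KNN11"] <= v["KNN3"]) wins <- wins + 1
  }
  expect_gte(wins, 11)  # majority of seeds
})

test_that("predictor serialization records spec and features", {
  d <- toy_gaussian(8, 8, 4, delta = 1, seed = 9)
  pred <- train_predictor("DLDA", d, c(2L, 4L))
  js <- jsonlite::fromJSON(serialize_predictor(pred))
  expect_equal(js$spec$name, "DLDA")
  expect_equal(js$feature_ids, c("F2", "F4"))
  expect_length(js$fit$w, 2)
})
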