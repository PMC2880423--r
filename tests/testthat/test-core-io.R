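test_that("dataset construction validates its invariants", {
  expect_error(make_ds(matrix(1:4, 2), c(1L, NA)), "binary")
  expect_error(make_ds(matrix(c(1, NaN, 3, 4), 2), c(1L, 0L)), "finite")
  expect_error(make_ds(matrix(1, 1, 3), 1L), "at least 2 samples")
  m <- matrix(rnorm(6), 2, 3)
  expect_error(make_ds(m, c(1L, 0L), sample_ids = c("a", "a")), "duplicate")
  d <- make_ds(m, c(1L, 0L))
  expect_equal(dim(d), c(2L, 3L))
  expect_error(assert_two_classes(make_ds(m, c(1L, 1L))), "both classes")
})

test_that("expression TSV write/read round-trips exactly", {
  d <- toy_gaussian(3, 4, 5, seed = 11)
  mp <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(d, mp, lp)
  d2 <- read_expression_tsv(mp, lp)
  expect_equal(unname(d2$values), unname(d$values))
  expect_identical(d2$labels, d$labels)
  expect_identical(d2$sample_ids, d$sample_ids)
  expect_identical(d2$feature_ids, d$feature_ids)

  # 2x2 identity case with an explicit endpoint mapping
  mp2 <- withr::local_tempfile(); lp2 <- withr::local_tempfile()
  writeLines(c("sample_id\tg1\tg2", "A\t1.5\t2.5", "B\t3.5\t4.5"), mp2)
  writeLines(c("sample_id\tclass_label", "A\tpCR", "B\tRD"), lp2)
  d3 <- read_expression_tsv(mp2, lp2, endpoint_spec("pCR", "pCR", 0.5))
  expect_identical(d3$labels, c(1L, 0L))
  expect_equal(dim(d3), c(2L, 2L))
})

test_that("malformed matrices and incomplete label files are rejected", {
  mp <- withr::local_tempfile(); lp <- withr::local_tempfile()
  writeLines(c("sample_id\tg1\tg2", "A\t1.0\t", "B\t3.0\t4.0"), mp)
  writeLines(c("sample_id\tclass_label", "A\t1", "B\t0"), lp)
  expect_error(read_expression_tsv(mp, lp), "missing|blank")
  writeLines(c("sample_id\tg1", "A\t1.0", "B\t2.0"), mp)
  writeLines(c("sample_id\tclass_label", "A\t1"), lp)
  expect_error(read_expression_tsv(mp, lp), "missing from label file")
})

test_that("stratified folds partition samples and preserve class balance", {
  f <- stratified_folds(rep(c(1L, 0L), each = 5), k = 5, seed = 3)
  for (fold in f) expect_equal(sum(fold <= 5), 1L)  # 1 pos + 1 neg each

  y <- c(rep(1L, 33), rep(0L, 97))
  f <- stratified_folds(y, 5, seed = 9)
  pos_per_fold <- vapply(f, function(i) sum(y[i] == 1L), integer(1))
  expect_true(all(pos_per_fold %in% c(6L, 7L)))

  # partition property over random label vectors
  for (s in 1:10) {
    set.seed(s)
    y <- sample(c(rep(1L, 5 + s), rep(0L, 20)))
    f <- stratified_folds(y, 4, seed = s)
    expect_identical(sort(unlist(f)), seq_along(y))
  }

  expect_identical(stratified_folds(y, 4, seed = 42),
                   stratified_folds(y, 4, seed = 42))
  expect_error(stratified_folds(c(1L, 0L, 0L, 0L), 2, seed = 1),
               "infeasible")
})

test_that("stratified bootstrap preserves class counts and OOB rate", {
  y <- c(rep(1L, 4), rep(0L, 6))
  bs <- stratified_bootstrap(y, seed = 5)
  expect_equal(sum(y[bs$idx] == 1L), 4L)
  expect_equal(sum(y[bs$idx] == 0L), 6L)
  expect_identical(bs, stratified_bootstrap(y, seed = 5))
  expect_setequal(union(bs$idx, bs$oob), seq_along(y))
  expect_length(intersect(bs$idx, bs$oob), 0)

  # expected OOB fraction per class approaches (1 - 1/m)^m
  y <- c(rep(1L, 100), rep(0L, 100))
  oob_frac <- vapply(1:1000, function(s) {
    length(intersect(stratified_bootstrap(y, seed = s)$oob, 1:100)) / 100
  }, numeric(1))
  expect_equal(mean(oob_frac), (1 - 1 / 100)^100, tolerance = 0.01)
})

test_that("chi-square test matches a direct sum-over-cells oracle", {
  set.seed(21)
  for (i in 1:15) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 12) + 1, r, cc)
    res <- chi_square_test(tab, yates = FALSE)
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- 0
    for (a in 1:r) for (b in 1:cc)
      stat <- stat + (tab[a, b] - exp_tab[a, b])^2 / exp_tab[a, b]
    expect_equal(res$statistic, stat)
    expect_equal(res$df, (r - 1) * (cc - 1))
    expect_equal(res$p_value, pchisq(stat, res$df, lower.tail = FALSE))
  }
})

test_that("chi-square degenerate and invalid tables are handled", {
  tab <- matrix(c(10, 20, 10, 20), 2, byrow = TRUE)  # identical rows
  res <- chi_square_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
  expect_error(chi_square_test(matrix(1:12, 3, 4), yates = TRUE), "2 x 2")
  expect_error(contingency_table(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("run_config validates grids and counts; JSON configs load", {
  expect_error(run_config(feature_grid = c(5, 3)), "strictly increasing")
  expect_error(run_config(inner_folds = 0), "positive")
  cfgf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(seed = 7, feature_grid = c(2, 4, 8),
                            fs_methods = c("FS1", "FS5"),
                            classifiers = "DLDA", n_bootstrap = 50),
                       cfgf, auto_unbox = TRUE)
  cfg <- read_run_config(cfgf)
  expect_identical(cfg$seed, 7L)
  expect_identical(cfg$feature_grid, c(2L, 4L, 8L))
  expect_identical(cfg$classifiers, "DLDA")
})

test_that("GMT files read as named member lists", {
  gf <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg2\tg4"), gf)
  sets <- read_gmt(gf)
  expect_named(sets, c("setA", "setB"))
  expect_identical(sets$setB, c("g2", "g4"))
})
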