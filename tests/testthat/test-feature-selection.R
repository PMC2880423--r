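test_that("FS1 reproduces the Welch t hand computation", {
  d <- make_ds(cbind(g = c(1, 2, 3, 4, 5, 6)), c(1L, 1L, 1L, 0L, 0L, 0L))
  r <- rank_features(d, "FS1")
  expect_equal(r$criterion, 3 / sqrt(1 / 3 + 1 / 3), tolerance = 1e-6)
  expect_equal(abs(welch_t(d$values, d$labels)), r$criterion,
               ignore_attr = TRUE)
})

test_that("FS5 orders by absolute mean difference", {
  x <- cbind(A = c(0, 0, 1, 1), B = c(0, 1, 0, 1))
  d <- make_ds(x, c(1L, 1L, 0L, 0L))
  r <- rank_features(d, "FS5")
  expect_identical(r$order[1], 1L)      # |dmu| 1 vs 0
  expect_equal(r$criterion, c(1, 0))
})

test_that("criteria are translation invariant and ties break by feature id", {
  d <- toy_gaussian(6, 6, 5, delta = 0.8, seed = 3)
  d_shift <- make_ds(d$values + 100, d$labels)
  for (m in c("FS1", "FS4", "FS5")) {
    expect_equal(rank_features(d, m)$criterion,
                 rank_features(d_shift, m)$criterion, tolerance = 1e-8)
    expect_identical(rank_features(d, m)$order, rank_features(d_shift, m)$order)
  }
  # exact duplicate features tie; lower index wins
  dd <- make_ds(cbind(d$values[, 1], d$values[, 1], d$values[, 2]), d$labels)
  r <- rank_features(dd, "FS1")
  expect_lt(match(1L, r$order), match(2L, r$order))
})

test_that("FS1 and FS5 agree when all features share class variances", {
  # same within-class noise vector, different shifts: identical variances
  set.seed(5)
  base <- rnorm(20)
  shifts <- c(0.3, 1.1, 0.7, 2.0, 0.1)
  x <- sapply(shifts, function(s) base + s * rep(c(1, 0), each = 10))
  d <- make_ds(x, rep(c(1L, 0L), each = 10))
  expect_identical(rank_features(d, "FS1")$order, rank_features(d, "FS5")$order)
})

test_that("FS4 matches the BSS/WSS definition computed by loops", {
  d <- toy_gaussian(7, 9, 4, delta = 1, seed = 6)
  r <- rank_features(d, "FS4")
  x <- d$values; y <- d$labels
  bw <- sapply(seq_len(ncol(x)), function(j) {
    gm <- mean(x[, j]); bss <- 0; wss <- 0
    for (cls in c(0L, 1L)) {
      xi <- x[y == cls, j]
      bss <- bss + length(xi) * (mean(xi) - gm)^2
      wss <- wss + sum((xi - mean(xi))^2)
    }
    bss / wss
  })
  expect_equal(r$criterion, sort(bw, decreasing = TRUE), tolerance = 1e-10)
})

test_that("FS2 greedy filter drops correlated features as specified", {
  # duplicated feature: lower-ranked copy removed
  set.seed(7)
  v <- rnorm(12) + rep(c(1.5, 0), each = 6)
  d <- make_ds(matrix(c(v, v, rnorm(12)), ncol = 3),
               rep(c(1L, 0L), each = 6))
  r <- rank_features(d, "FS2")
  expect_false(all(c(1L, 2L) %in% r$order))

  # pairwise-uncorrelated features all retained in FS1 order
  d2 <- toy_gaussian(30, 30, 4, delta = 0.5, seed = 8)
  expect_identical(rank_features(d2, "FS2")$order,
                   rank_features(d2, "FS1")$order)

  # chain: corr(A,B) and corr(B,C) above threshold, corr(A,C) below,
  # ranked A > B > C -> keep A, drop B, keep C
  set.seed(9)
  n <- 1000
  R <- matrix(c(1, .8, .6, .8, 1, .8, .6, .8, 1), 3)
  z <- matrix(rnorm(n * 3), n, 3) %*% chol(R)
  y <- rep(c(1L, 0L), each = n / 2)
  z <- z + outer(as.numeric(y), c(1, 0.8, 0.6))
  d3 <- make_ds(z, y)
  stopifnot(identical(rank_features(d3, "FS1")$order, c(1L, 2L, 3L)))
  r3 <- rank_features(d3, "FS2")
  expect_identical(r3$order, c(1L, 3L))
})

test_that("FS2 postcondition: retained pairs satisfy |r| <= threshold", {
  for (s in 1:5) {
    d <- toy_gaussian(25, 25, 12, delta = 0.6, n_informative = 6, seed = s)
    r <- rank_features(d, "FS2")
    if (length(r$order) > 1) {
      cors <- cor(d$values[, r$order])
      expect_lte(max(abs(cors[upper.tri(cors)])), 0.75 + 1e-12)
    }
  }
})

test_that("FS3 merges correlated features into averaged meta-features", {
  # two shifted copies (r = 1): one meta-feature, values = constituents' mean
  x <- cbind(a = c(1, 3, 5, 7, 2, 4), b = c(3, 5, 7, 9, 4, 6),
             c = c(0.4, -1, 2, 0.3, -0.2, 1.1))
  d <- make_ds(x, c(1L, 1L, 1L, 0L, 0L, 0L))
  r <- rank_features(d, "FS3")
  grp <- r$meta_map[[which(vapply(r$meta_map, length, 1L) == 2L)]]
  expect_setequal(grp, c(1L, 2L))
  fs <- top_features(r, length(r$order))
  vals <- transform_features(d$values, fs)
  meta_col <- which(vapply(fs$groups, length, 1L) == 2L)
  expect_equal(unname(vals[, meta_col]), (x[, 1] + x[, 2]) / 2)

  # no correlations above threshold: FS3 == FS1
  d2 <- toy_gaussian(30, 30, 4, delta = 0.5, seed = 8)
  r2 <- rank_features(d2, "FS3")
  expect_identical(r2$order, rank_features(d2, "FS1")$order)
  expect_true(all(vapply(r2$meta_map, length, 1L) == 1L))

  # constituent sets are disjoint
  d3 <- toy_gaussian(20, 20, 10, delta = 1, seed = 10)
  r3 <- rank_features(d3, "FS3")
  all_members <- unlist(r3$meta_map)
  expect_identical(anyDuplicated(all_members), 0L)
})

test_that("rankings never read held-out rows", {
  d <- toy_gaussian(20, 20, 15, delta = 0.8, seed = 13)
  train_rows <- 1:30
  d_mut <- d
  d_mut$values[31:40, ] <- matrix(rnorm(10 * 15, sd = 50), 10)
  for (m in c("FS1", "FS2", "FS3", "FS4", "FS5")) {
    r1 <- rank_features(subset_samples(d, train_rows), m)
    r2 <- rank_features(subset_samples(d_mut, train_rows), m)
    expect_identical(r1$order, r2$order)
    expect_equal(r1$criterion, r2$criterion)
  }
})

test_that("lazy filtering to j equals filtering the whole list", {
  d <- toy_gaussian(25, 25, 20, delta = 0.7, n_informative = 10, seed = 14)
  full <- rank_features(d, "FS2")
  lazy <- rank_features(d, "FS2", j = 4)
  expect_identical(lazy$order[1:4], full$order[1:4])
  expect_error(top_features(lazy, 10), "only")
})
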