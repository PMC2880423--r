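#' Derive a child seed from a master seed
#'
#' Every stochastic operation in the package draws its own child seed from
#' (master seed, operation name, iteration index), so that adding or
#' reordering operations never perturbs the streams of the others.
#'
#' @param master master integer seed.
#' @param op operation name (character scalar).
#' @param iter iteration index (default 0).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(master, op, iter = 0L) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  # splitmix-style integer mix kept inside 2^31 via double arithmetic
  x <- (as.numeric(master) * 2654435761 + h * 40503 + as.numeric(iter) * 69069 + 12345)
  as.integer(x %% 2147483629)
}

#' Stratified k-fold partition
#'
#' Splits sample indices into `k` disjoint folds preserving the class
#' proportions: per-fold class counts differ from exact proportionality by
#' less than one sample.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed; same seed, same folds.
#' @return list of `k` integer index vectors partitioning `seq_along(labels)`.
#' @export
stratified_folds <- function(labels, k, seed) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  labels <- as.integer(labels)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < k))
    stop(sprintf("infeasible stratification: a class has fewer than k = %d members", k))
  folds <- vector("list", k)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  for (cls in c(1L, 0L)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    assign_to <- rep(seq_len(k), length.out = length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_to == f])
  }
  lapply(folds, sort)
}

#' Stratified bootstrap resample
#'
#' Samples with replacement within each class, preserving the exact class
#' counts of `labels`; also returns the complementary out-of-bag index set.
#'
#' @param labels binary 0/1 vector.
#' @param seed integer seed.
#' @return list with `idx` (bootstrap index multiset, class counts preserved)
#'   and `oob` (indices appearing in no bootstrap draw).
#' @export
stratified_bootstrap <- function(labels, seed) {
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos) || !length(neg)) stop("both classes must be non-empty")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  idx <- c(pos[sample.int(length(pos), replace = TRUE)],
           neg[sample.int(length(neg), replace = TRUE)])
  list(idx = idx, oob = setdiff(seq_along(labels), idx))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
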