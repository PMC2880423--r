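#' Vectorized unequal-variance (Welch) t statistics
#'
#' @param x samples-by-features matrix.
#' @param y binary 0/1 labels (1 = positive class, taken as group 1).
#' @return signed t statistic per column. A feature with zero variance in
#'   both classes gets 0 when the class means agree and +/-Inf otherwise
#'   (maximally separating, ranks first by absolute value).
#' @export
welch_t <- function(x, y) {
  st <- .class_stats(x, y)
  se2 <- st$v1 / st$n1 + st$v2 / st$n2
  d <- st$m1 - st$m2
  t <- ifelse(se2 == 0, ifelse(d == 0, 0, sign(d) * Inf), d / sqrt(pmax(se2, 1e-300)))
  t
}

# BSS/WSS: between- to within-group sum of squares per feature
.bss_wss <- function(x, y) {
  st <- .class_stats(x, y)
  gm <- (st$n1 * st$m1 + st$n2 * st$m2) / (st$n1 + st$n2)
  bss <- st$n1 * (st$m1 - gm)^2 + st$n2 * (st$m2 - gm)^2
  wss <- (st$n1 - 1) * st$v1 + (st$n2 - 1) * st$v2
  ifelse(wss == 0, ifelse(bss == 0, 0, Inf), bss / pmax(wss, 1e-300))
}

#' Univariate feature ranking (FS1-FS5)
#'
#' The five selection rules, each computed strictly on the dataset passed in
#' (callers hand in the training view only, which is what makes the
#' resampling loops leakage-free):
#' \describe{
#'   \item{FS1}{absolute Welch t, descending.}
#'   \item{FS2}{FS1 followed by a greedy correlation filter: walking down the
#'     ranking, a feature is dropped if its Pearson correlation with any
#'     already-retained feature exceeds `r_threshold`.}
#'   \item{FS3}{as FS2, but dropped features are merged into the retained
#'     feature they correlate with, forming meta-features whose value is the
#'     unweighted mean of their constituents; meta-feature t scores are
#'     recomputed on the averaged values.}
#'   \item{FS4}{between- to within-group sum-of-squares ratio, descending.}
#'   \item{FS5}{absolute difference in class means, descending.}
#' }
#' Ties in any criterion are broken by ascending feature index for
#' cross-platform determinism.
#'
#' @param dataset an `expression_dataset` (training view).
#' @param method one of `"FS1"`..`"FS5"`.
#' @param j for FS2/FS3, stop filtering once `j` retained features/meta-features
#'   exist (lazy filtering; result for the top `j` equals filtering the whole
#'   list). `NULL` processes the entire ranking.
#' @param r_threshold correlation threshold for FS2/FS3.
#' @return a `feature_ranking`: `method`, `order` (column indices, best
#'   first; for FS3 these are the retained representative's index),
#'   `criterion` (nonincreasing), `meta_map` (FS3: list of constituent index
#'   vectors parallel to `order`), `feature_ids`.
#' @export
rank_features <- function(dataset, method = c("FS1", "FS2", "FS3", "FS4", "FS5"),
                          j = NULL, r_threshold = 0.75) {
  method <- match.arg(method)
  assert_two_classes(dataset)
  x <- dataset$values
  y <- dataset$labels
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("each class needs >= 2 samples for ranking")
  crit <- unname(switch(method,
                 FS1 = , FS2 = , FS3 = abs(welch_t(x, y)),
                 FS4 = .bss_wss(x, y),
                 FS5 = {st <- .class_stats(x, y); abs(st$m1 - st$m2)}))
  ord <- order(-crit, seq_along(crit))
  res <- structure(list(method = method, order = ord, criterion = crit[ord],
                        meta_map = NULL, feature_ids = dataset$feature_ids),
                   class = "feature_ranking")
  if (method == "FS2") res <- decorrelate_fs2(res, dataset, r_threshold, j)
  if (method == "FS3") res <- metafeatures_fs3(res, dataset, r_threshold, j)
  res
}

# greedy walk shared by FS2/FS3: returns retained indices and, if collect_map,
# the constituent groups (dropped features attached to the highest-ranked
# retained feature whose correlation exceeds the threshold)
.greedy_filter <- function(ord, x, r_threshold, j, collect_map) {
  retained <- integer(0)
  groups <- list()
  xs <- scale(x[, ord, drop = FALSE])      # correlation via crossprod of scaled cols
  xs[is.na(xs)] <- 0                       # zero-variance: correlation treated as 0
  n1 <- nrow(xs) - 1
  kept_cols <- NULL
  for (i in seq_along(ord)) {
    v <- xs[, i]
    if (!length(retained)) r <- numeric(0)
    else r <- as.numeric(crossprod(kept_cols, v)) / n1
    hit <- which(abs(r) > r_threshold)
    if (!length(hit)) {
      retained <- c(retained, ord[i])
      kept_cols <- cbind(kept_cols, v)
      if (collect_map) groups[[length(retained)]] <- ord[i]
      # lazy filtering: once j features/groups are retained the walk stops;
      # features ranked below this point are never consulted
      if (!is.null(j) && length(retained) >= j) break
    } else if (collect_map) {
      groups[[hit[1L]]] <- c(groups[[hit[1L]]], ord[i])
    }
  }
  list(retained = retained, groups = groups)
}

#' Correlation filtering of a t-test ranking (FS2)
#'
#' @param ranking a `feature_ranking` produced by the FS1 criterion on the
#'   same training subset.
#' @param dataset the training view the ranking came from.
#' @param r_threshold Pearson threshold; every retained pair satisfies
#'   |r| <= threshold on the training data.
#' @param j stop once `j` features are retained (lazy).
#' @return filtered `feature_ranking` (original order preserved).
#' @export
decorrelate_fs2 <- function(ranking, dataset, r_threshold = 0.75, j = NULL) {
  g <- .greedy_filter(ranking$order, dataset$values, r_threshold, j, FALSE)
  keep_pos <- match(g$retained, ranking$order)
  structure(list(method = "FS2", order = g$retained,
                 criterion = ranking$criterion[keep_pos],
                 meta_map = NULL, feature_ids = ranking$feature_ids),
            class = "feature_ranking")
}

#' Meta-feature construction from correlated features (FS3)
#'
#' Same greedy walk as FS2, but each dropped feature is merged into the
#' (highest-ranked) retained feature it exceeds the correlation threshold
#' with. A meta-feature's expression value is the unweighted mean of its
#' constituents' values; meta-feature t scores are recomputed on the averaged
#' values and the meta-features re-ranked by them.
#'
#' @inheritParams decorrelate_fs2
#' @return `feature_ranking` with `meta_map`: per retained entry, the integer
#'   constituent column indices (length 1 = plain feature).
#' @export
metafeatures_fs3 <- function(ranking, dataset, r_threshold = 0.75, j = NULL) {
  g <- .greedy_filter(ranking$order, dataset$values, r_threshold, j, TRUE)
  if (!is.null(j) && length(g$retained) > j) {
    g$retained <- g$retained[seq_len(j)]
    g$groups <- g$groups[seq_len(j)]
  }
  vals <- vapply(g$groups, function(cols)
    rowMeans(dataset$values[, cols, drop = FALSE]), numeric(nrow(dataset$values)))
  tnew <- abs(welch_t(vals, dataset$labels))
  ord2 <- order(-tnew, seq_along(tnew))
  structure(list(method = "FS3", order = g$retained[ord2],
                 criterion = tnew[ord2],
                 meta_map = g$groups[ord2],
                 feature_ids = ranking$feature_ids),
            class = "feature_ranking")
}

#' Top-j selection from a ranking
#'
#' @param ranking a `feature_ranking`.
#' @param j number of (meta-)features to take.
#' @return a `feature_set`: list with `groups` (list of integer column index
#'   vectors; length > 1 marks an FS3 meta-feature) and `ids` (display ids,
#'   constituents joined by `+`).
#' @export
top_features <- function(ranking, j) {
  if (j > length(ranking$order))
    stop(sprintf("requested %d features but ranking holds only %d",
                 j, length(ranking$order)))
  groups <- if (is.null(ranking$meta_map)) as.list(ranking$order[seq_len(j)])
            else ranking$meta_map[seq_len(j)]
  ids <- vapply(groups, function(g)
    paste(ranking$feature_ids[g], collapse = "+"), character(1))
  structure(list(groups = groups, ids = ids), class = "feature_set")
}

#' Apply a feature set to an expression matrix
#'
#' Plain features are copied; meta-features are the mean of their stored
#' constituents, so validation samples are transformed exactly as the
#' training samples were.
#'
#' @param x samples-by-features matrix over the full feature space.
#' @param feature_set a `feature_set` from [top_features()].
#' @return samples-by-j numeric matrix.
#' @export
transform_features <- function(x, feature_set) {
  out <- vapply(feature_set$groups, function(g) {
    if (length(g) == 1L) x[, g] else rowMeans(x[, g, drop = FALSE])
  }, numeric(nrow(x)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(x))
  colnames(out) <- feature_set$ids
  out
}
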