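#' Wilcoxon-Mann-Whitney AUC
#'
#' The empirical probability that a randomly chosen positive sample scores
#' above a randomly chosen negative one, with ties counted 1/2:
#' the average over all (positive, negative) pairs of the WMW kernel.
#'
#' @param scores continuous scores, larger = more positive.
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_wmw <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("AUC requires both classes present")
  cpp_auc(as.numeric(scores), labels)
}

#' Mark a fixed, data-independent scoring rule
#'
#' Wraps a function of a feature matrix into an object usable wherever a
#' classifier spec is expected. Because the rule ignores the training data,
#' resampling estimators applied to it collapse to the plain test AUC of the
#' rule — the degenerate case used to validate the estimators.
#'
#' @param fun function(samples-by-features matrix) -> numeric scores.
#' @return a `fixed_rule` object.
#' @export
fixed_score_rule <- function(fun) {
  structure(list(fun = fun), class = "fixed_rule")
}

.is_fast_combo <- function(fs_method, spec) {
  !inherits(spec, "fixed_rule") &&
    fs_method %in% c("FS1", "FS4", "FS5") &&
    (if (is.character(spec)) spec else spec$name) == "DLDA"
}

.crit_type <- function(fs_method) c(FS1 = 1L, FS4 = 4L, FS5 = 5L)[[fs_method]]

#' Inner-loop selection of the feature count j*
#'
#' Repeated (5x) stratified 5-fold cross-validation entirely inside the given
#' training view: in every fold, features are re-ranked on the fold-training
#' part, the classifier is trained on the top j, and the left-out fold is
#' scored. Per-j AUCs are averaged over all folds and repeats; j* is the grid
#' value with the highest average AUC, ties resolved toward the smallest j.
#'
#' @param dataset training view (`expression_dataset`).
#' @param fs_method `"FS1"`..`"FS5"`.
#' @param spec classifier name, [classifier_spec()], or [fixed_score_rule()].
#' @param grid strictly increasing candidate feature counts.
#' @param seed integer seed (fold splits are a deterministic function of it).
#' @param inner_repeats,inner_folds resampling design.
#' @param use_fast use the compiled single-pass path when available
#'   (FS1/FS4/FS5 with DLDA); results are identical to the generic path.
#' @param rows optional integer row indices defining the training view inside
#'   `dataset` (duplicates allowed, e.g. bootstrap multisets); default all
#'   rows. Operations never read rows outside this view.
#' @return a `feature_count_selection`: `grid`, `mean_auc` per j, `j_star`.
#' @export
inner_select_j <- function(dataset, fs_method, spec, grid, seed,
                           inner_repeats = 5L, inner_folds = 5L,
                           use_fast = TRUE, rows = NULL) {
  grid <- as.integer(grid)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (max(grid) > ncol(dataset$values))
    stop(sprintf("grid value %d exceeds the %d available features",
                 max(grid), ncol(dataset$values)))
  if (inherits(spec, "fixed_rule")) {
    return(structure(list(grid = grid, mean_auc = rep(NA_real_, length(grid)),
                          j_star = grid[1L]),
                     class = "feature_count_selection"))
  }
  if (is.character(spec)) spec <- classifier_spec(spec)
  if (is.null(rows)) rows <- seq_len(nrow(dataset$values))
  y_sub <- dataset$labels[rows]
  fast <- use_fast && .is_fast_combo(fs_method, spec)
  sub <- if (!fast) subset_samples(dataset, rows) else NULL
  auc_sum <- numeric(length(grid))
  n_eval <- 0L
  for (r in seq_len(inner_repeats)) {
    folds <- stratified_folds(y_sub, inner_folds, child_seed(seed, "inner_folds", r))
    if (fast) {
      foldid <- integer(length(rows))
      for (f in seq_along(folds)) foldid[folds[[f]]] <- f
      aucmat <- cpp_cv_grid_auc(dataset$values, dataset$labels, rows, foldid,
                                inner_folds, grid, .crit_type(fs_method))
      auc_sum <- auc_sum + colSums(aucmat)
      n_eval <- n_eval + inner_folds
      next
    }
    for (f in seq_len(inner_folds)) {
      test_sub <- folds[[f]]
      train_sub <- sort(unlist(folds[-f], use.names = FALSE))
      tr <- subset_samples(sub, train_sub)
      ranking <- rank_features(tr, fs_method, j = max(grid))
      if (length(ranking$order) < max(grid))
        stop(sprintf("grid value %d exceeds the %d features retained by %s",
                     max(grid), length(ranking$order), fs_method))
      aucs <- vapply(grid, function(j) {
        pred <- train_predictor(spec, tr, top_features(ranking, j))
        auc_wmw(score_samples(pred, sub$values[test_sub, , drop = FALSE]),
                y_sub[test_sub])
      }, numeric(1))
      auc_sum <- auc_sum + aucs
      n_eval <- n_eval + 1L
    }
  }
  mean_auc <- auc_sum / n_eval
  structure(list(grid = grid, mean_auc = mean_auc,
                 j_star = grid[which.max(mean_auc)]),
            class = "feature_count_selection")
}

# full pipeline on one training view (dataset rows `rows`): tune j*, rank on
# the whole view, train the final model. The fast combo skips dataset copies.
.train_model <- function(dataset, rows, fs_method, spec, grid, seed,
                         inner_repeats = 5L, inner_folds = 5L, use_fast = TRUE) {
  if (inherits(spec, "fixed_rule"))
    return(list(predictor = spec, j_star = NA_integer_, selection = NULL))
  if (is.character(spec)) spec <- classifier_spec(spec)
  sel <- inner_select_j(dataset, fs_method, spec, grid, seed,
                        inner_repeats, inner_folds, use_fast, rows = rows)
  if (use_fast && .is_fast_combo(fs_method, spec)) {
    crit <- cpp_rank_criterion(dataset$values, dataset$labels, rows,
                               .crit_type(fs_method))
    ord <- order(-crit, seq_along(crit))[seq_len(sel$j_star)]
    fit <- .fit_dlda(dataset$values[rows, ord, drop = FALSE],
                     dataset$labels[rows])
    fset <- structure(list(groups = as.list(ord),
                           ids = dataset$feature_ids[ord]),
                      class = "feature_set")
    pred <- structure(list(spec = spec, feature_set = fset, fit = fit,
                           center = NULL, scale = NULL,
                           p_full = ncol(dataset$values)),
                      class = "trained_predictor")
  } else {
    tr <- subset_samples(dataset, rows)
    ranking <- rank_features(tr, fs_method, j = sel$j_star)
    pred <- train_predictor(spec, tr, top_features(ranking, sel$j_star))
  }
  list(predictor = pred, j_star = sel$j_star, selection = sel)
}

.score_any <- function(predictor, x) {
  if (inherits(predictor, "fixed_rule")) predictor$fun(x)
  else score_samples(predictor, x)
}

#' Outer 10x5 cross-validation estimate
#'
#' Ten repeats of stratified 5-fold cross-validation. Each fold runs the full
#' inner pipeline (feature-count tuning, re-ranking, training) on 80% of the
#' data and scores the held-out 20%. The estimate is the grand mean of the 50
#' fold AUCs; the SEM is the average over the 10 repeats of SD(fold AUCs)/
#' sqrt(5), and the 95% CI is AUC +/- 1.96 SEM. Fold splits are a
#' deterministic function of the seed, so different models evaluated under
#' the same seed reuse identical splits.
#'
#' @inheritParams inner_select_j
#' @param outer_repeats,outer_folds outer design (default 10 x 5).
#' @param folds_list optional precomputed splits: list over repeats of lists
#'   of fold index vectors (as produced internally); pass the same object to
#'   several models to share splits explicitly.
#' @return a `performance_estimate`: `estimator`, `auc`, `sem`, `ci`,
#'   `fold_aucs` (matrix repeats x folds), `j_star` (per fold, same shape).
#' @export
outer_cv_10x5 <- function(dataset, fs_method, spec, grid, seed,
                          outer_repeats = 10L, outer_folds = 5L,
                          inner_repeats = 5L, inner_folds = 5L,
                          folds_list = NULL, use_fast = TRUE) {
  y <- dataset$labels
  if (is.null(folds_list))
    folds_list <- lapply(seq_len(outer_repeats), function(r)
      stratified_folds(y, outer_folds, child_seed(seed, "outer_cv", r)))
  fold_aucs <- matrix(NA_real_, outer_repeats, outer_folds)
  j_mat <- matrix(NA_integer_, outer_repeats, outer_folds)
  for (r in seq_len(outer_repeats)) {
    folds <- folds_list[[r]]
    for (f in seq_along(folds)) {
      test_idx <- folds[[f]]
      train_idx <- sort(unlist(folds[-f], use.names = FALSE))
      fit <- .train_model(dataset, train_idx, fs_method, spec,
                          grid, child_seed(seed, "outer_cv_inner", r * 1000L + f),
                          inner_repeats, inner_folds, use_fast)
      sc <- .score_any(fit$predictor, dataset$values[test_idx, , drop = FALSE])
      fold_aucs[r, f] <- auc_wmw(sc, y[test_idx])
      j_mat[r, f] <- fit$j_star
    }
  }
  sem <- mean(apply(fold_aucs, 1, stats::sd) / sqrt(outer_folds))
  est <- mean(fold_aucs)
  structure(list(estimator = "CV10x5", auc = est, sem = sem,
                 ci = c(est - 1.96 * sem, est + 1.96 * sem),
                 fold_aucs = fold_aucs, j_star = j_mat),
            class = "performance_estimate")
}

#' Leave-pair-out bootstrap estimate of the mean AUC
#'
#' Draws `B` stratified bootstrap training sets; each runs the full inner
#' pipeline and yields a scoring rule. Every (positive, negative) case pair
#' is then evaluated only by the rules trained on bootstrap samples
#' containing neither case, and the WMW kernel is averaged per pair over
#' those rules; the mean AUC averages over all covered pairs. The SEM uses
#' the delta-method-after-bootstrap (infinitesimal-jackknife) construction —
#' per case, the covariance across replicates between its bootstrap inclusion
#' count and the replicate's pair-averaged performance — plus a pair-level
#' two-sample U-statistic term for finite-test variability.
#'
#' @inheritParams inner_select_j
#' @param B number of bootstrap replicates (paper-scale: 5000).
#' @return a `performance_estimate` with `estimator = "LPO"`, `auc`, `sem`,
#'   `ci`, `n_uncovered` (pairs never out-of-bag together, excluded), and
#'   `var_train`/`var_test` components of `sem^2`.
#' @export
lpo_bootstrap <- function(dataset, fs_method, spec, grid, B, seed,
                          inner_repeats = 5L, inner_folds = 5L,
                          use_fast = TRUE) {
  if (B < 1L) stop("B must be >= 1")
  y <- dataset$labels
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("both classes need >= 2 samples for the LPO bootstrap")
  n <- length(y); n1 <- length(pos); n2 <- length(neg)
  sumI <- cnt <- matrix(0, n1, n2)
  incl <- matrix(0L, n, B)          # bootstrap inclusion counts per case
  Ahat <- rep(NA_real_, B)          # per-replicate pair-averaged performance
  for (b in seq_len(B)) {
    bs <- stratified_bootstrap(y, child_seed(seed, "lpo_boot", b))
    incl[, b] <- tabulate(bs$idx, nbins = n)
    fit <- .train_model(dataset, bs$idx, fs_method, spec, grid,
                        child_seed(seed, "lpo_inner", b),
                        inner_repeats, inner_folds, use_fast)
    sc <- .score_any(fit$predictor, dataset$values)
    op <- intersect(bs$oob, pos); on <- intersect(bs$oob, neg)
    if (length(op) && length(on)) {
      ii <- match(op, pos); jj <- match(on, neg)
      I <- outer(sc[op], sc[on], ">") + 0.5 * outer(sc[op], sc[on], "==")
      sumI[ii, jj] <- sumI[ii, jj] + I
      cnt[ii, jj] <- cnt[ii, jj] + 1
      Ahat[b] <- mean(I)
    }
  }
  covered <- cnt > 0
  n_unc <- sum(!covered)
  if (n_unc > 0.5 * n1 * n2)
    stop("most case pairs have no qualifying bootstrap replicate; increase B")
  if (n_unc > 0)
    message(n_unc, " of ", n1 * n2, " case pairs never out-of-bag together; excluded")
  pbar <- sumI / ifelse(covered, cnt, NA)
  est <- mean(pbar[covered])

  ok <- !is.na(Ahat)
  Ac <- Ahat[ok] - mean(Ahat[ok])
  Nc <- sweep(incl[, ok, drop = FALSE], 1, rowMeans(incl[, ok, drop = FALSE]))
  Ci <- as.numeric(Nc %*% Ac) / sum(ok)
  var_train <- sum(Ci^2)
  v10 <- rowMeans(pbar, na.rm = TRUE)
  v01 <- colMeans(pbar, na.rm = TRUE)
  var_test <- stats::var(v10) / n1 + stats::var(v01) / n2
  sem <- sqrt(var_train + var_test)
  structure(list(estimator = "LPO", auc = est, sem = sem,
                 ci = c(est - 1.96 * sem, est + 1.96 * sem),
                 var_train = var_train, var_test = var_test,
                 n_uncovered = n_unc, B = as.integer(B)),
            class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("<%s> AUC = %.4f, SEM = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$estimator, x$auc, x$sem, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Conditional validation AUC
#'
#' One full pipeline on the training set (feature-count tuning strictly
#' inside it), scored once on the fixed validation set. The result is
#' conditional on this particular finite training set.
#'
#' @inheritParams inner_select_j
#' @param train,validation `expression_dataset`s over the same feature space.
#' @return list: `auc`, `j_star`.
#' @export
conditional_validation <- function(train, validation, fs_method, spec, grid,
                                   seed, inner_repeats = 5L, inner_folds = 5L,
                                   use_fast = TRUE) {
  if (ncol(train$values) != ncol(validation$values))
    stop("train and validation feature spaces differ")
  fit <- .train_model(train, seq_len(nrow(train$values)), fs_method, spec, grid,
                      child_seed(seed, "conditional"), inner_repeats,
                      inner_folds, use_fast)
  list(auc = auc_wmw(.score_any(fit$predictor, validation$values),
                     validation$labels),
       j_star = fit$j_star)
}

#' Mean validation AUC and variance decomposition
#'
#' Bootstraps the training set `B` times, runs the full pipeline on each
#' resample and scores the fixed validation set, giving `B` conditional
#' AUCs. Reports their mean (the mean validation AUC), their variance
#' (`var_train`: instability under training-set resampling) and the
#' two-sample U-statistic variance of the WMW estimator at the averaged
#' pair-indicator distribution (`var_test`: finite validation set).
#'
#' @inheritParams conditional_validation
#' @param B bootstrap replicates.
#' @return a `validation_result`: `mean_auc`, `conditional_aucs`,
#'   `var_train`, `var_test`.
#' @export
mean_validation <- function(train, validation, fs_method, spec, grid, B, seed,
                            inner_repeats = 5L, inner_folds = 5L,
                            use_fast = TRUE) {
  if (ncol(train$values) != ncol(validation$values))
    stop("train and validation feature spaces differ")
  yv <- validation$labels
  pos <- which(yv == 1L); neg <- which(yv == 0L)
  pair_sum <- matrix(0, length(pos), length(neg))
  aucs <- numeric(B)
  for (b in seq_len(B)) {
    bs <- stratified_bootstrap(train$labels, child_seed(seed, "meanval_boot", b))
    fit <- .train_model(train, bs$idx, fs_method, spec, grid,
                        child_seed(seed, "meanval_inner", b),
                        inner_repeats, inner_folds, use_fast)
    sc <- .score_any(fit$predictor, validation$values)
    I <- outer(sc[pos], sc[neg], ">") + 0.5 * outer(sc[pos], sc[neg], "==")
    pair_sum <- pair_sum + I
    aucs[b] <- mean(I)
  }
  pbar <- pair_sum / B
  v10 <- rowMeans(pbar); v01 <- colMeans(pbar)
  structure(list(mean_auc = mean(aucs), conditional_aucs = aucs,
                 var_train = stats::var(aucs),
                 var_test = stats::var(v10) / length(pos) +
                            stats::var(v01) / length(neg)),
            class = "validation_result")
}

#' RMSE between internal estimates and validation performance
#'
#' Root mean square difference over a model grid between each model's
#' internal mean AUC (from 10x5-CV or the LPO bootstrap) and its mean
#' validation AUC.
#'
#' @param internal_estimates named numeric vector of internal mean AUCs, one
#'   per (feature selection, classifier) model.
#' @param validation_results named numeric vector of mean validation AUCs
#'   over the same models (names must match).
#' @return the RMSE (scalar, >= 0).
#' @export
rmse_compare <- function(internal_estimates, validation_results) {
  if (length(internal_estimates) != length(validation_results))
    stop("mismatched model grids")
  if (!is.null(names(internal_estimates)) && !is.null(names(validation_results)) &&
      !identical(names(internal_estimates), names(validation_results)))
    stop("mismatched model grids (names differ)")
  sqrt(mean((as.numeric(internal_estimates) - as.numeric(validation_results))^2))
}
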