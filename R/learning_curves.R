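#' Cross-validated performance at increasing training-set sizes
#'
#' For each requested size, draws `n_rep` independent stratified subsamples
#' of the dataset and evaluates each by a single stratified 5-fold
#' cross-validation in which the full inner pipeline (feature-count tuning,
#' re-ranking, training) is re-run per fold, so all model parameters are
#' recalculated at every size.
#'
#' @inheritParams inner_select_j
#' @param sizes integer training sizes (e.g. `seq(60, 220, by = 20)`).
#' @param n_rep random subsamples per size (default 10).
#' @param cv_folds folds of the assessment CV (default 5).
#' @return a data.frame of learning-curve points: `size`, `rep`, `auc` (one
#'   row per replicate), with per-size means/SDs available via
#'   `aggregate`. Sizes infeasible for the design are skipped with a message.
#' @export
subsample_performance <- function(dataset, sizes, n_rep = 10L, fs_method,
                                  spec, grid, seed, cv_folds = 5L,
                                  inner_repeats = 5L, inner_folds = 5L,
                                  use_fast = TRUE) {
  y <- dataset$labels
  n <- length(y)
  rows <- list()
  for (s in as.integer(sizes)) {
    n_pos <- round(s * mean(y == 1L))
    # every CV training part (4/5 of the subsample) must keep both classes
    # k-feasible for the inner 5-fold split
    feasible <- s <= n && min(n_pos, s - n_pos) >= cv_folds &&
      min(n_pos, s - n_pos) * (cv_folds - 1) / cv_folds >= inner_folds
    if (!feasible) {
      message("size ", s, " infeasible for the resampling design; skipped")
      next
    }
    for (r in seq_len(n_rep)) {
      sub_idx <- .stratified_subsample(y, s, child_seed(seed, "lc_subsample",
                                                       s * 1000L + r))
      sub <- subset_samples(dataset, sub_idx)
      folds <- stratified_folds(sub$labels, cv_folds,
                                child_seed(seed, "lc_folds", s * 1000L + r))
      aucs <- vapply(seq_along(folds), function(f) {
        test_idx <- folds[[f]]
        train_idx <- sort(unlist(folds[-f], use.names = FALSE))
        fit <- .train_model(sub, train_idx, fs_method, spec,
                            grid, child_seed(seed, "lc_inner",
                                             s * 100000L + r * 100L + f),
                            inner_repeats, inner_folds, use_fast)
        auc_wmw(.score_any(fit$predictor, sub$values[test_idx, , drop = FALSE]),
                sub$labels[test_idx])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(size = s, rep = r,
                                              auc = mean(aucs))
    }
  }
  if (!length(rows)) stop("no feasible sizes")
  do.call(rbind, rows)
}

.stratified_subsample <- function(y, size, seed) {
  n_pos <- round(size * mean(y == 1L))
  n_neg <- size - n_pos
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  pos <- which(y == 1L); neg <- which(y == 0L)
  sort(c(pos[sample.int(length(pos), n_pos)],
         neg[sample.int(length(neg), n_neg)]))
}

#' Fit the inverse-size learning-curve model Y = a + b / n
#'
#' Ordinary least squares of the replicate-level AUCs on 1/n. Fitting on
#' replicates (not size means) leaves residual degrees of freedom for the
#' two-sided t test of the slope, which is how a slope p-value can be
#' reported with only ~10 distinct sizes. The intercept `a` is the projected
#' asymptotic performance Y(Inf); `b < 0` means performance grows with n.
#'
#' @param points data.frame with columns `size` and `auc` (one row per
#'   replicate), as returned by [subsample_performance()].
#' @return a `learning_curve_fit`: `a`, `b`, `p_value` (slope), `ci`
#'   (95% confidence intervals for a and b), `predict(n)` function, and the
#'   underlying `lm` fit.
#' @export
fit_learning_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("size", "auc") %in% names(points)))
  if (length(unique(points$size)) < 3L)
    stop("need at least 3 distinct training sizes")
  fit <- stats::lm(auc ~ I(1 / size), data = points)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))  # exact fits: se = 0
  p_slope <- if (nrow(sm$coefficients) >= 2L && !is.na(sm$coefficients[2L, 4L]))
    sm$coefficients[2L, 4L] else 1
  ci <- suppressWarnings(stats::confint(fit))
  a <- unname(cf[1L]); b <- unname(cf[2L])
  if (is.na(b)) { b <- 0; p_slope <- 1 }
  # (near-)exact fits leave no residual variance for the slope t test: call
  # the slope flat when it is numerically zero, certain otherwise
  if (sm$sigma < 1e-9 * max(abs(points$auc), 1))
    p_slope <- if (abs(b) < 1e-8) 1 else 0
  structure(list(a = a, b = b, p_value = p_slope, ci = ci,
                 predict = function(n) a + b / n, fit = fit),
            class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf("<learning_curve_fit> Y(n) = %.4f + (%.3f)/n; slope p = %.3g; Y(Inf) = %.4f\n",
              x$a, x$b, x$p_value, x$a))
  invisible(x)
}
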