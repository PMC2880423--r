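#' Run the full factorial benchmark (feature selection x classifier)
#'
#' Evaluates every configured combination on one endpoint: both internal
#' estimators (10x5-CV and LPO bootstrap) on the training set and, when a
#' validation set is supplied, the conditional and mean validation AUCs with
#' their variance decomposition. All models share one set of outer CV splits
#' (derived once from the master seed), so that differences between models
#' are not confounded with split-to-split variability. A model failure is
#' recorded in its row without aborting the grid.
#'
#' @param config a [run_config()].
#' @param train training `expression_dataset`.
#' @param validation optional validation `expression_dataset` (same feature
#'   space).
#' @param mean_val_B bootstrap replicates for the mean-validation AUC
#'   (defaults to `config$n_bootstrap`, capped at 200 — it converges fast).
#' @return a `factorial_result` list: `table` (one row per model),
#'   `rmse` (per estimator, when a validation set was supplied), and
#'   `folds_list` (the shared outer splits). The table has columns
#'   `fs`, `classifier`, `j_star_mode`, `cv_auc`, `cv_sem`, `lpo_auc`,
#'   `lpo_sem`, `conditional_auc`, `mean_validation_auc`, `var_train`,
#'   `var_test`, `error`.
#' @export
run_factorial <- function(config, train, validation = NULL,
                          mean_val_B = min(config$n_bootstrap, 200L)) {
  stopifnot(inherits(config, "run_config"))
  grid <- config$feature_grid
  seed <- config$seed
  folds_list <- lapply(seq_len(config$outer_repeats), function(r)
    stratified_folds(train$labels, config$outer_folds,
                     child_seed(seed, "outer_cv", r)))
  combos <- expand.grid(fs = config$fs_methods, classifier = config$classifiers,
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fs <- combos$fs[i]; clf <- combos$classifier[i]
    row <- data.frame(fs = fs, classifier = clf, j_star_mode = NA_integer_,
                      cv_auc = NA_real_, cv_sem = NA_real_,
                      lpo_auc = NA_real_, lpo_sem = NA_real_,
                      conditional_auc = NA_real_,
                      mean_validation_auc = NA_real_,
                      var_train = NA_real_, var_test = NA_real_,
                      error = NA_character_)
    res <- tryCatch({
      if ("CV10x5" %in% config$outer_estimators) {
        cv <- outer_cv_10x5(train, fs, clf, grid, seed,
                            outer_repeats = config$outer_repeats,
                            outer_folds = config$outer_folds,
                            inner_repeats = config$inner_repeats,
                            inner_folds = config$inner_folds,
                            folds_list = folds_list)
        row$cv_auc <- cv$auc; row$cv_sem <- cv$sem
        jtab <- table(cv$j_star)
        row$j_star_mode <- as.integer(names(jtab)[which.max(jtab)])
      }
      if ("LPO" %in% config$outer_estimators) {
        lpo <- lpo_bootstrap(train, fs, clf, grid, config$n_bootstrap, seed,
                             inner_repeats = config$inner_repeats,
                             inner_folds = config$inner_folds)
        row$lpo_auc <- lpo$auc; row$lpo_sem <- lpo$sem
      }
      if (!is.null(validation)) {
        cond <- conditional_validation(train, validation, fs, clf, grid, seed,
                                       inner_repeats = config$inner_repeats,
                                       inner_folds = config$inner_folds)
        row$conditional_auc <- cond$auc
        if (is.na(row$j_star_mode)) row$j_star_mode <- cond$j_star
        mv <- mean_validation(train, validation, fs, clf, grid, mean_val_B,
                              seed, inner_repeats = config$inner_repeats,
                              inner_folds = config$inner_folds)
        row$mean_validation_auc <- mv$mean_auc
        row$var_train <- mv$var_train; row$var_test <- mv$var_test
      }
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  rmse <- NULL
  if (!is.null(validation)) {
    ok <- !is.na(tab$mean_validation_auc)
    rmse <- c(
      CV10x5 = if (any(ok & !is.na(tab$cv_auc)))
        rmse_compare(tab$cv_auc[ok & !is.na(tab$cv_auc)],
                     tab$mean_validation_auc[ok & !is.na(tab$cv_auc)]) else NA_real_,
      LPO = if (any(ok & !is.na(tab$lpo_auc)))
        rmse_compare(tab$lpo_auc[ok & !is.na(tab$lpo_auc)],
                     tab$mean_validation_auc[ok & !is.na(tab$lpo_auc)]) else NA_real_)
  }
  structure(list(table = tab, rmse = rmse, folds_list = folds_list,
                 config = config),
            class = "factorial_result")
}

#' Top-k nominally best models
#'
#' Ranks the factorial table by conditional validation AUC (descending),
#' breaking ties by the LPO estimate, then by feature-selection method and
#' classifier name for full determinism.
#'
#' @param table the `table` element of a [run_factorial()] result (or a
#'   `factorial_result`).
#' @param k how many rows to return (default 5).
#' @return the top-k rows of the table.
#' @export
report_best_models <- function(table, k = 5L) {
  if (inherits(table, "factorial_result")) table <- table$table
  if (!nrow(table)) stop("empty model table")
  ord <- order(-table$conditional_auc, -table$lpo_auc,
               table$fs, table$classifier)
  table[ord[seq_len(min(k, nrow(table)))], , drop = FALSE]
}
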