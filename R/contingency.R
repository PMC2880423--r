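#' Build a validated contingency table
#'
#' @param counts r x c matrix of non-negative integers (r, c >= 2).
#' @param row_labels,col_labels optional dimension labels.
#' @return a `contingency_table` (an integer matrix with class attribute).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("grand total must be positive")
  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", class(counts)))
}

#' Pearson chi-square test on a contingency table
#'
#' Thin validated wrapper around [stats::chisq.test()]. With `yates = TRUE`
#' (2 x 2 tables only) the 0.5 continuity correction is applied; otherwise the
#' plain Pearson statistic with df = (r-1)(c-1) is used. P-values are never
#' truncated; round only when formatting reports.
#'
#' @param table a matrix or `contingency_table`.
#' @param yates apply the continuity correction (2 x 2 only).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, yates = FALSE) {
  tab <- unclass(contingency_table(table))
  if (yates && !(nrow(tab) == 2L && ncol(tab) == 2L))
    stop("Yates correction applies only to 2 x 2 tables")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic),
       df = unname(res$parameter),
       p_value = res$p.value)
}

#' Fisher's exact test (optional companion to the chi-square)
#' @param table a 2 x 2 matrix or `contingency_table`.
#' @return two-sided p-value.
#' @export
fisher_exact_test <- function(table) {
  tab <- unclass(contingency_table(table))
  stats::fisher.test(tab)$p.value
}
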