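#' Construct an expression dataset
#'
#' The universal input record for all modeling operations: a samples-by-features
#' real-valued matrix plus a binary endpoint label per sample (1 = positive
#' class). All downstream code works on integer column/row indices; sample and
#' feature identifiers matter only at the I/O boundary.
#'
#' @param values numeric matrix, rows = samples, columns = features.
#' @param labels binary vector (0/1, or logical) of length `nrow(values)`.
#' @param sample_ids,feature_ids optional unique identifier vectors; defaults
#'   are taken from `dimnames(values)` or generated.
#' @param endpoint_name name of the endpoint the labels encode.
#' @return an object of class `expression_dataset` with elements `values`
#'   (matrix with dimnames), `labels` (integer 0/1), `sample_ids`,
#'   `feature_ids`, `endpoint_name`.
#' @export
expression_dataset <- function(values, labels,
                               sample_ids = NULL, feature_ids = NULL,
                               endpoint_name = "endpoint") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  if (n < 2L || p < 1L) stop("need at least 2 samples and 1 feature")
  if (anyNA(values) || !all(is.finite(values)))
    stop("expression values must be finite and non-missing")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- colnames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(p))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (length(sample_ids) != n) stop("sample_ids length != number of rows")
  if (length(feature_ids) != p) stop("feature_ids length != number of columns")
  if (length(labels) != n) stop("labels length must equal the number of samples")
  if (is.logical(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, labels = labels,
         sample_ids = sample_ids, feature_ids = feature_ids,
         endpoint_name = endpoint_name),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d samples x %d features, endpoint '%s' (%d pos / %d neg)\n",
              nrow(x$values), ncol(x$values), x$endpoint_name,
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Check both classes are represented
#' @param dataset an `expression_dataset`.
#' @return invisibly `TRUE`; errors if a class is empty.
#' @export
assert_two_classes <- function(dataset) {
  if (sum(dataset$labels == 1L) < 1L || sum(dataset$labels == 0L) < 1L)
    stop("both classes must be present for modeling operations")
  invisible(TRUE)
}

#' Row-subset a dataset
#'
#' @param dataset an `expression_dataset`.
#' @param idx integer row indices (duplicates allowed, e.g. bootstrap multisets;
#'   sample ids are then made unique mechanically).
#' @return an `expression_dataset` on the selected rows.
#' @export
subset_samples <- function(dataset, idx) {
  ids <- dataset$sample_ids[idx]
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  expression_dataset(dataset$values[idx, , drop = FALSE],
                     dataset$labels[idx],
                     sample_ids = ids,
                     feature_ids = dataset$feature_ids,
                     endpoint_name = dataset$endpoint_name)
}

#' Endpoint description
#'
#' @param name endpoint name (e.g. "pCR").
#' @param positive_label the raw label value mapped to 1 at load time.
#' @param prevalence fraction of positive-class samples, strictly in (0,1).
#' @return an `endpoint_spec` list.
#' @export
endpoint_spec <- function(name, positive_label, prevalence) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be strictly between 0 and 1")
  structure(list(name = name, positive_label = as.character(positive_label),
                 prevalence = prevalence),
            class = "endpoint_spec")
}

#' Read an expression matrix and labels from TSV
#'
#' Matrix file: header row of feature ids, first column sample ids.
#' Label file: two tab-separated columns `sample_id`, `class_label` (with
#' header). Labels are normalized to 0/1 at load time: `positive_label` (or,
#' when omitted, the label value "1") maps to 1.
#'
#' @param path path to the matrix TSV.
#' @param label_path path to the 2-column label TSV.
#' @param endpoint optional `endpoint_spec`; its `positive_label` controls the
#'   label polarity.
#' @return an `expression_dataset`. Samples present in the matrix but missing
#'   from the label file are rejected with an error.
#' @export
read_expression_tsv <- function(path, label_path, endpoint = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("malformed matrix TSV: need sample id column plus features: ", path)
  sample_ids <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1L, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric or blank cell in %s (first at data line %d)",
                 path, if (length(bad)) bad[1L] else NA_integer_))
  }
  if (anyNA(mat)) {
    line <- which(rowSums(is.na(mat)) > 0L)[1L]
    stop(sprintf("missing value in %s at data line %d", path, line))
  }
  lab <- utils::read.delim(label_path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(lab) < 2L) stop("label file must have two columns: ", label_path)
  missing <- setdiff(sample_ids, lab[[1L]])
  if (length(missing))
    stop("samples missing from label file: ", paste(missing, collapse = ", "))
  raw_lab <- lab[[2L]][match(sample_ids, lab[[1L]])]
  pos <- if (is.null(endpoint)) "1" else endpoint$positive_label
  labels <- as.integer(raw_lab == pos)
  expression_dataset(mat, labels, sample_ids = sample_ids,
                     endpoint_name = if (is.null(endpoint)) "endpoint" else endpoint$name)
}

#' Write an expression dataset to TSV
#'
#' Inverse of [read_expression_tsv()]; values are written with full double
#' precision so a read-back reproduces them exactly.
#'
#' @param dataset an `expression_dataset`.
#' @param path matrix TSV path.
#' @param label_path label TSV path.
#' @return invisibly the two paths.
#' @export
write_expression_tsv <- function(dataset, path, label_path) {
  df <- data.frame(sample_id = dataset$sample_ids,
                   dataset$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = dataset$sample_ids, class_label = dataset$labels)
  utils::write.table(lab, label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, label_path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line — set name, description, then tab-separated
#' member ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(parts[-c(1L, 2L)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}

#' Run configuration
#'
#' Collects the knobs of a full factorial evaluation: master seed, outer
#' estimators, bootstrap replicates `B`, resampling design (5x5 inner,
#' 10x5 outer), the feature-count grid, feature-selection methods and
#' classifier specs to cross.
#'
#' @param seed master integer seed; all stochastic steps derive child seeds
#'   from it (see [child_seed()]).
#' @param outer_estimators subset of `c("CV10x5","LPO")`.
#' @param n_bootstrap bootstrap replicates for the leave-pair-out estimator.
#' @param inner_repeats,inner_folds inner-loop design (feature-count tuning).
#' @param outer_repeats,outer_folds outer cross-validation design.
#' @param feature_grid strictly increasing positive integers: candidate
#'   feature counts.
#' @param fs_methods subset of `c("FS1","FS2","FS3","FS4","FS5")`.
#' @param classifiers character vector of classifier names (see
#'   [classifier_spec()]).
#' @param output_dir where drivers write their tables.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       outer_estimators = c("CV10x5", "LPO"),
                       n_bootstrap = 5000L,
                       inner_repeats = 5L, inner_folds = 5L,
                       outer_repeats = 10L, outer_folds = 5L,
                       feature_grid = c(2:15),
                       fs_methods = paste0("FS", 1:5),
                       classifiers = c("LDA", "DLDA", "QDA", "LREG",
                                       "KNN3", "KNN11", "SVM05", "SVM2"),
                       output_dir = "results") {
  outer_estimators <- match.arg(outer_estimators, c("CV10x5", "LPO"),
                                several.ok = TRUE)
  counts <- c(n_bootstrap, inner_repeats, inner_folds, outer_repeats, outer_folds)
  if (any(counts < 1L)) stop("all repeat/fold counts must be positive")
  feature_grid <- as.integer(feature_grid)
  if (any(feature_grid < 1L) || is.unsorted(feature_grid, strictly = TRUE))
    stop("feature_grid must be strictly increasing positive integers")
  fs_methods <- match.arg(fs_methods, paste0("FS", 1:5), several.ok = TRUE)
  structure(list(seed = as.integer(seed),
                 outer_estimators = outer_estimators,
                 n_bootstrap = as.integer(n_bootstrap),
                 inner_repeats = as.integer(inner_repeats),
                 inner_folds = as.integer(inner_folds),
                 outer_repeats = as.integer(outer_repeats),
                 outer_folds = as.integer(outer_folds),
                 feature_grid = feature_grid,
                 fs_methods = fs_methods,
                 classifiers = classifiers,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path file whose top-level keys mirror [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, vals)
}
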