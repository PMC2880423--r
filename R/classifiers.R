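#' Classifier specification
#'
#' The eight fixed-hyperparameter algorithms used throughout the benchmark.
#' Hyperparameters are deliberately frozen (k in \{3, 11\}, RBF gamma in
#' \{0.5, 2\}, SVM cost C = 10): tuning them would have to happen inside the
#' inner resampling loop to avoid optimization bias, and is out of scope.
#'
#' @param name one of `"LDA"`, `"DLDA"`, `"QDA"`, `"LREG"`, `"KNN3"`,
#'   `"KNN11"`, `"SVM05"`, `"SVM2"`.
#' @return a `classifier_spec` list: `name`, `algorithm`, `k`, `gamma`,
#'   `cost`, `standardize` (distance/kernel methods standardize features by
#'   training mean/SD; discriminant and logistic models use raw values).
#' @export
classifier_spec <- function(name = c("LDA", "DLDA", "QDA", "LREG",
                                     "KNN3", "KNN11", "SVM05", "SVM2")) {
  name <- match.arg(name)
  spec <- switch(name,
    LDA   = list(algorithm = "lda"),
    DLDA  = list(algorithm = "dlda"),
    QDA   = list(algorithm = "qda"),
    LREG  = list(algorithm = "lreg"),
    KNN3  = list(algorithm = "knn", k = 3L),
    KNN11 = list(algorithm = "knn", k = 11L),
    SVM05 = list(algorithm = "svm", gamma = 0.5, cost = 10),
    SVM2  = list(algorithm = "svm", gamma = 2.0, cost = 10))
  spec$name <- name
  spec$standardize <- spec$algorithm %in% c("knn", "svm")
  structure(spec, class = "classifier_spec")
}

# ridge-stabilized Cholesky: escalates lambda until the factorization succeeds
.safe_chol <- function(S) {
  lam <- 0
  base <- mean(diag(S)); if (!is.finite(base) || base <= 0) base <- 1
  for (i in 0:8) {
    R <- tryCatch(chol(S + diag(lam, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    lam <- if (lam == 0) 1e-8 * base else lam * 10
  }
  stop("covariance matrix singular even after ridge regularization")
}

.fit_lda <- function(x, y) {
  pos <- y == 1L
  m1 <- colMeans(x[pos, , drop = FALSE]); m0 <- colMeans(x[!pos, , drop = FALSE])
  n1 <- sum(pos); n0 <- sum(!pos)
  xc <- x
  xc[pos, ] <- sweep(x[pos, , drop = FALSE], 2, m1)
  xc[!pos, ] <- sweep(x[!pos, , drop = FALSE], 2, m0)
  S <- crossprod(xc) / (n1 + n0 - 2)
  R <- .safe_chol(S)
  w <- backsolve(R, backsolve(R, m1 - m0, transpose = TRUE))
  b <- -0.5 * sum((m1 + m0) * w) + log(n1 / n0)
  list(w = w, b = b)
}

.fit_dlda <- function(x, y) {
  st <- .class_stats(x, y)
  vp <- ((st$n1 - 1) * st$v1 + (st$n2 - 1) * st$v2) / (st$n1 + st$n2 - 2)
  vp[vp <= 0] <- 1e-12
  w <- (st$m1 - st$m2) / vp
  b <- -0.5 * sum((st$m1 + st$m2) * w) + log(st$n1 / st$n2)
  list(w = w, b = b)
}

.fit_qda <- function(x, y, pooled_S = NULL) {
  j <- ncol(x)
  fit_class <- function(rows) {
    m <- colMeans(x[rows, , drop = FALSE])
    xc <- sweep(x[rows, , drop = FALSE], 2, m)
    n <- length(rows)
    S <- if (n - 1L >= j + 1L) crossprod(xc) / (n - 1) else NULL
    list(m = m, S = S, n = n)
  }
  c1 <- fit_class(which(y == 1L)); c0 <- fit_class(which(y == 0L))
  if (min(c1$n, c0$n) <= j)
    stop(sprintf("QDA infeasible: class size %d <= %d features",
                 min(c1$n, c0$n), j))
  if (is.null(c1$S) || is.null(c0$S)) {
    # per-class n in (j, j+2): shrink that class fully toward the pooled covariance
    if (is.null(pooled_S)) {
      pos <- y == 1L
      xc <- x
      xc[pos, ] <- sweep(x[pos, , drop = FALSE], 2, c1$m)
      xc[!pos, ] <- sweep(x[!pos, , drop = FALSE], 2, c0$m)
      pooled_S <- crossprod(xc) / (length(y) - 2)
    }
    if (is.null(c1$S)) c1$S <- pooled_S
    if (is.null(c0$S)) c0$S <- pooled_S
  }
  mk <- function(cl, prior) {
    R <- .safe_chol(cl$S)
    list(m = cl$m, R = R, logdet = 2 * sum(log(diag(R))), logprior = log(prior))
  }
  n <- c1$n + c0$n
  list(c1 = mk(c1, c1$n / n), c0 = mk(c0, c0$n / n))
}

.score_qda_class <- function(xnew, cl) {
  z <- backsolve(cl$R, t(sweep(xnew, 2, cl$m)), transpose = TRUE)
  -0.5 * colSums(z^2) - 0.5 * cl$logdet + cl$logprior
}

.fit_lreg <- function(x, y) {
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                         family = stats::binomial(),
                                         control = list(maxit = 50)))
  if (!fit$converged)
    warning("logistic regression did not converge within 50 iterations; using last iterate")
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  coef
}

#' Train a classifier on a selected feature set
#'
#' Fits the algorithm on exactly the given (meta-)features of the training
#' view. Distance/kernel methods (KNN, SVM) standardize features by the
#' training mean and SD; discriminant and logistic models see raw values.
#' Training is deterministic: no internal randomness.
#'
#' @param spec a [classifier_spec()] (or its name).
#' @param dataset training `expression_dataset`.
#' @param feature_set a `feature_set` from [top_features()], or an integer
#'   vector of column indices.
#' @return a `trained_predictor`; use [score_samples()] to obtain continuous
#'   scores oriented so that larger favors the positive class.
#' @export
train_predictor <- function(spec, dataset, feature_set) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  assert_two_classes(dataset)
  if (is.numeric(feature_set))
    feature_set <- structure(list(groups = as.list(as.integer(feature_set)),
                                  ids = dataset$feature_ids[as.integer(feature_set)]),
                             class = "feature_set")
  x <- transform_features(dataset$values, feature_set)
  y <- dataset$labels
  center <- scl <- NULL
  if (spec$standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scl, "/")
  }
  fit <- switch(spec$algorithm,
    lda = .fit_lda(x, y),
    dlda = .fit_dlda(x, y),
    qda = .fit_qda(x, y),
    lreg = .fit_lreg(x, y),
    knn = list(xtr = x, ytr = y, k = spec$k),
    svm = {
      m <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                      gamma = spec$gamma, cost = spec$cost, scale = FALSE)
      dv <- attr(stats::predict(m, x, decision.values = TRUE), "decision.values")[, 1L]
      # orient decision values so larger favors the positive class
      flip <- if (auc_wmw(dv, y) < 0.5) -1 else 1
      list(model = m, flip = flip)
    })
  structure(list(spec = spec, feature_set = feature_set, fit = fit,
                 center = center, scale = scl,
                 p_full = ncol(dataset$values)),
            class = "trained_predictor")
}

#' Score new samples with a trained predictor
#'
#' Continuous scores, larger = positive class: posterior log-odds for the
#' discriminant models, the linear predictor for logistic regression, the
#' fraction of positive neighbors among k for KNN (distance ties broken by
#' training sample order), and the oriented decision value for the SVM.
#'
#' @param predictor a `trained_predictor`.
#' @param newdata an `expression_dataset` or a samples-by-features matrix over
#'   the same (full) feature space the predictor was trained on.
#' @return numeric score vector, one per sample.
#' @export
score_samples <- function(predictor, newdata) {
  x_full <- if (inherits(newdata, "expression_dataset")) newdata$values else newdata
  if (ncol(x_full) != predictor$p_full)
    stop(sprintf("newdata has %d features but the predictor was trained on a %d-feature space",
                 ncol(x_full), predictor$p_full))
  x <- transform_features(x_full, predictor$feature_set)
  if (!is.null(predictor$center))
    x <- sweep(sweep(x, 2, predictor$center), 2, predictor$scale, "/")
  fit <- predictor$fit
  switch(predictor$spec$algorithm,
    lda = , dlda = drop(x %*% fit$w) + fit$b,
    qda = .score_qda_class(x, fit$c1) - .score_qda_class(x, fit$c0),
    lreg = drop(cbind(1, x) %*% fit),
    knn = .score_knn(fit, x),
    svm = {
      dv <- attr(stats::predict(fit$model, x, decision.values = TRUE),
                 "decision.values")[, 1L]
      fit$flip * dv
    })
}

# fraction of positive training neighbors among the k nearest; distance ties
# broken deterministically by training-sample index
.score_knn <- function(fit, xnew) {
  d2 <- outer(rowSums(xnew^2), rowSums(fit$xtr^2), "+") - 2 * xnew %*% t(fit$xtr)
  k <- fit$k
  apply(d2, 1, function(row) {
    nb <- order(row, seq_along(row))[seq_len(min(k, length(row)))]
    mean(fit$ytr[nb] == 1L)
  })
}

#' Serialize a trained predictor to a JSON-compatible record
#'
#' Captures the spec, selected (meta-)feature ids and fitted parameters so a
#' predictor can be stored and reapplied to a validation matrix.
#'
#' @param predictor a `trained_predictor`.
#' @param path optional file to write JSON to.
#' @return (invisibly, when writing) the JSON string.
#' @export
serialize_predictor <- function(predictor, path = NULL) {
  rec <- list(spec = unclass(predictor$spec),
              feature_ids = predictor$feature_set$ids,
              feature_groups = predictor$feature_set$groups,
              center = predictor$center, scale = predictor$scale,
              fit = if (predictor$spec$algorithm %in% c("lda", "dlda", "lreg"))
                      predictor$fit else "non-serializable model object omitted")
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
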