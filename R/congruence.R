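#' Build the 0/1 feature-selection matrix
#'
#' One row per feature of the universe, one column per selection method;
#' entry 1 marks the features each method selected (its top j*). Meta-feature
#' selections are expanded to their constituent features.
#'
#' @param rankings named list of `feature_ranking` objects, one per method.
#' @param j_star_per_method integer vector (recycled) of selected counts, in
#'   the same order as `rankings`.
#' @param universe character vector of all feature ids under consideration
#'   (defaults to the first ranking's full feature space).
#' @return binary matrix (features x methods) with dimnames.
#' @export
build_selection_matrix <- function(rankings, j_star_per_method,
                                   universe = NULL) {
  if (is.null(universe)) universe <- rankings[[1L]]$feature_ids
  j_star_per_method <- rep_len(as.integer(j_star_per_method), length(rankings))
  m <- matrix(0L, length(universe), length(rankings),
              dimnames = list(universe, names(rankings)))
  for (k in seq_along(rankings)) {
    fs <- top_features(rankings[[k]], j_star_per_method[k])
    feat_ids <- rankings[[k]]$feature_ids[unlist(fs$groups, use.names = FALSE)]
    if (!all(feat_ids %in% universe))
      stop("selected feature outside the universe: ",
           paste(setdiff(feat_ids, universe), collapse = ", "))
    m[feat_ids, k] <- 1L
  }
  m
}

# Cohen's kappa for two binary raters over the same objects; undefined when a
# rater is constant (no variability to correct for chance)
.cohen_kappa <- function(a, b) {
  if (min(mean(a), mean(b)) == 0 || max(mean(a), mean(b)) == 1)
    return(NA_real_)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  (po - pe) / (1 - pe)
}

# Fleiss' kappa for n raters x N objects, binary categories
.fleiss_kappa <- function(m) {
  n_rater <- ncol(m)
  r1 <- rowSums(m)                # raters saying 1, per object
  p1 <- mean(m)                   # overall category-1 proportion
  P_i <- (r1 * (r1 - 1) + (n_rater - r1) * (n_rater - r1 - 1)) /
    (n_rater * (n_rater - 1))
  Pbar <- mean(P_i)
  Pe <- p1^2 + (1 - p1)^2
  if (Pe == 1) return(NA_real_)
  (Pbar - Pe) / (1 - Pe)
}

#' Congruence of feature selections (kappa)
#'
#' Chance-corrected agreement of the selection indicators: the multi-rater
#' Fleiss kappa over all methods plus the matrix of pairwise Cohen kappas
#' (with their average). Pairs involving a constant column (all 0 or all 1
#' over the universe) have undefined kappa; they are flagged and excluded
#' from the pairwise average.
#'
#' @param matrix binary selection matrix from [build_selection_matrix()]
#'   (>= 2 columns).
#' @return a `kappa_congruence` list: `fleiss`, `pairwise` (symmetric
#'   matrix), `mean_pairwise`, `n_undefined_pairs`.
#' @export
kappa_congruence <- function(matrix) {
  if (ncol(matrix) < 2L) stop("kappa needs at least 2 selection methods")
  storage.mode(matrix) <- "integer"
  if (!all(matrix %in% c(0L, 1L))) stop("selection matrix must be binary")
  k <- ncol(matrix)
  pw <- diag(1, k)
  dimnames(pw) <- list(colnames(matrix), colnames(matrix))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pw[i, j] <- pw[j, i] <- .cohen_kappa(matrix[, i], matrix[, j])
  }
  off <- pw[upper.tri(pw)]
  structure(list(fleiss = .fleiss_kappa(matrix),
                 pairwise = pw,
                 mean_pairwise = mean(off, na.rm = TRUE),
                 n_undefined_pairs = sum(is.na(off))),
            class = "kappa_congruence")
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per gene set: with a universe of size M, a
#' set of size K (after intersection with the universe) and a selection of
#' size n overlapping the set in k features, p = P(X >= k) for
#' X ~ Hypergeometric(M, K, n). Results are sorted by ascending p; following
#' the benchmark's reporting rule, `top_n` defaults to the selection size.
#'
#' @param selected character vector of selected feature ids (subset of the
#'   universe).
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all feature ids.
#' @param top_n how many top sets to mark for reporting (default:
#'   `length(selected)`).
#' @return data.frame: `set`, `overlap`, `set_size`, `selected_size`,
#'   `universe_size`, `p`, `q` (BH-adjusted, a modern extra), `rank`,
#'   `top` (logical).
#' @export
hypergeometric_enrichment <- function(selected, gene_sets, universe,
                                      top_n = length(selected)) {
  if (!length(universe)) stop("empty universe")
  if (!length(selected)) stop("empty selection")
  if (!all(selected %in% universe))
    stop("selected features must be a subset of the universe")
  M <- length(universe); n <- length(selected)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(selected, set))
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K,
               selected_size = n, universe_size = M, p = p)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, out$set), , drop = FALSE]
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$rank <- seq_len(nrow(out))
  out$top <- out$rank <= top_n
  rownames(out) <- NULL
  out
}
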