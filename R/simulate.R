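#' Difficulty profile for the synthetic generator
#'
#' Describes a two-class Gaussian expression world: class-conditional
#' multivariate normal features with unit within-class SD, a mean shift
#' `delta[i]` (in SD units) for each informative feature in the positive
#' class, optional equicorrelated feature blocks built by a common-factor
#' construction, and a stratified disjoint train/validation split.
#'
#' @param n_samples total samples (train + validation).
#' @param n_features total features p.
#' @param n_informative number of features with non-zero mean shift.
#' @param effect_sizes vector of per-informative-feature shifts (recycled or
#'   length `n_informative`), in within-class SD units.
#' @param prevalence positive-class fraction, strictly in (0,1).
#' @param block_spec list of `c(size, rho)` pairs; blocks are laid down among
#'   informative features first, then among noise features.
#' @param validation_fraction fraction of samples held out as the disjoint
#'   validation set.
#' @return a `difficulty_profile` list.
#' @export
difficulty_profile <- function(n_samples, n_features, n_informative,
                               effect_sizes, prevalence,
                               block_spec = list(),
                               validation_fraction = 0) {
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("validation_fraction must be in [0,1)")
  delta <- rep_len(as.numeric(effect_sizes), max(n_informative, 0L))
  if (length(block_spec)) {
    sizes <- vapply(block_spec, `[[`, numeric(1), 1L)
    rhos <- vapply(block_spec, `[[`, numeric(1), 2L)
    if (any(sizes < 2)) stop("block size must be >= 2")
    if (any(abs(rhos) >= 1)) stop("|rho| must be < 1")
    if (sum(sizes) > n_features) stop("infeasible block spec: blocks exceed p")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_sizes = delta,
                 prevalence = prevalence,
                 block_spec = block_spec,
                 validation_fraction = validation_fraction),
            class = "difficulty_profile")
}

#' Preset difficulty profiles
#'
#' Three named worlds emulating an easy endpoint (ER-like: many strong
#' informative features), a moderately difficult one (pCR-like: a few hundred
#' informative features) and a hard one (pCR-within-ER-negative-like: a
#' handful of informative features at a small sample size). Cohort sizes and
#' prevalences follow the 130/100 (50-case for hard) train/validation design;
#' effect-size spectra are calibrated so that permutation-test significant
#' feature counts land near 1500 / 250 / 5 on average (see the methods
#' vignette for the calibration rationale).
#'
#' @return named list of three `difficulty_profile` objects:
#'   `easy`, `moderate`, `hard`.
#' @export
preset_profiles <- function() {
  p_array <- 10000L  # one common array size across endpoints, as on a real platform
  list(
    easy = difficulty_profile(
      n_samples = 230L, n_features = p_array, n_informative = 1500L,
      # top-heavy spectrum: a molecularly distinct easy endpoint has a core of
      # very strong markers plus a long tail of weaker correlated ones
      effect_sizes = 0.75 + 2.25 * (seq(1500L, 1L) / 1500L)^4,
      prevalence = 0.38,
      block_spec = rep(list(c(10, 0.85)), 10),
      validation_fraction = 100 / 230),
    moderate = difficulty_profile(
      n_samples = 230L, n_features = p_array, n_informative = 250L,
      effect_sizes = seq(1.15, 0.85, length.out = 250L),
      prevalence = 0.25,
      block_spec = rep(list(c(5, 0.85)), 4),
      validation_fraction = 100 / 230),
    hard = difficulty_profile(
      n_samples = 90L, n_features = p_array, n_informative = 5L,
      effect_sizes = seq(1.5, 1.1, length.out = 5L),
      prevalence = 0.54,
      validation_fraction = 40 / 90)
  )
}

# delta' Sigma^{-1} delta for the block-equicorrelation covariance,
# computed blockwise in closed form.
.mahalanobis_sq <- function(delta_full, blocks) {
  in_block <- rep(FALSE, length(delta_full))
  total <- 0
  for (b in blocks) {
    d <- delta_full[b$cols]
    m <- length(d); rho <- b$rho
    in_block[b$cols] <- TRUE
    total <- total + (sum(d^2) - rho * sum(d)^2 / (1 - rho + rho * m)) / (1 - rho)
  }
  total + sum(delta_full[!in_block]^2)
}

#' Generate a synthetic two-class expression dataset with known ground truth
#'
#' Uninformative features are i.i.d. N(0,1); informative feature i is shifted
#' by `delta[i]` in the positive class; each correlated block shares a common
#' latent factor giving pairwise correlation rho and unit variance. The
#' validation split is drawn from the same distribution (no batch effect) and
#' is stratified and disjoint from the training set.
#'
#' @param profile a [difficulty_profile()].
#' @param seed integer seed.
#' @return list with `train` and `validation` (`expression_dataset`s;
#'   `validation = NULL` if `validation_fraction = 0`) and `truth`, a
#'   `ground_truth` list: `informative_feature_ids`, `delta`, `blocks`, and
#'   the closed-form `bayes_auc` = Phi(sqrt(delta' Sigma^-1 delta) / sqrt(2)).
#' @export
generate_dataset <- function(profile, seed) {
  stopifnot(inherits(profile, "difficulty_profile"))
  p <- profile$n_features
  n <- profile$n_samples
  n_val <- as.integer(round(profile$validation_fraction * n))
  n_train <- n - n_val

  # lay out blocks: informative features first, remainder among noise features
  blocks <- list()
  if (length(profile$block_spec)) {
    cursor_info <- 1L
    cursor_noise <- profile$n_informative + 1L
    for (bs in profile$block_spec) {
      size <- as.integer(bs[1]); rho <- bs[2]
      if (cursor_info + size - 1L <= profile$n_informative) {
        cols <- cursor_info:(cursor_info + size - 1L); cursor_info <- cursor_info + size
      } else {
        if (cursor_noise + size - 1L > p) stop("infeasible block spec: blocks exceed p")
        cols <- cursor_noise:(cursor_noise + size - 1L); cursor_noise <- cursor_noise + size
      }
      blocks[[length(blocks) + 1L]] <- list(cols = cols, rho = rho)
    }
  }

  delta_full <- numeric(p)
  if (profile$n_informative > 0L)
    delta_full[seq_len(profile$n_informative)] <- profile$effect_sizes

  sim_one <- function(n_sub, seed_sub, prefix) {
    n_pos <- as.integer(round(profile$prevalence * n_sub))
    n_pos <- max(1L, min(n_sub - 1L, n_pos))
    labels <- c(rep(1L, n_pos), rep(0L, n_sub - n_pos))
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed_sub)
    x <- matrix(stats::rnorm(n_sub * p), n_sub, p)
    for (b in blocks) {
      z <- stats::rnorm(n_sub)
      x[, b$cols] <- sqrt(b$rho) * z + sqrt(1 - b$rho) * x[, b$cols]
    }
    if (profile$n_informative > 0L)
      x[labels == 1L, seq_len(profile$n_informative)] <-
        x[labels == 1L, seq_len(profile$n_informative), drop = FALSE] +
        rep(profile$effect_sizes, each = n_pos)
    expression_dataset(x, labels,
                       sample_ids = paste0(prefix, seq_len(n_sub)),
                       feature_ids = paste0("G", seq_len(p)),
                       endpoint_name = "synthetic")
  }

  train <- sim_one(n_train, child_seed(seed, "simulate_train"), "TR")
  validation <- if (n_val > 0L)
    sim_one(n_val, child_seed(seed, "simulate_validation"), "VA") else NULL

  bayes_auc <- stats::pnorm(sqrt(.mahalanobis_sq(delta_full, blocks)) / sqrt(2))
  truth <- structure(
    list(informative_feature_ids = paste0("G", seq_len(profile$n_informative)),
         delta = profile$effect_sizes,
         blocks = blocks,
         bayes_auc = bayes_auc),
    class = "ground_truth")
  list(train = train, validation = validation, truth = truth)
}
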