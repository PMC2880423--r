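# small dataset builders shared across tests

make_ds <- function(values, labels, ...) {
  expression_dataset(as.matrix(values), labels, ...)
}

# two-class Gaussian toy data: first `n_informative` features shifted by delta
toy_gaussian <- function(n_pos, n_neg, p, delta = 1, n_informative = p,
                         seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm((n_pos + n_neg) * p), n_pos + n_neg, p)
  if (n_informative > 0)
    x[seq_len(n_pos), seq_len(n_informative)] <-
      x[seq_len(n_pos), seq_len(n_informative)] + delta
  make_ds(x, c(rep(1L, n_pos), rep(0L, n_neg)))
}

# a preset profile with its validation set replaced by a large holdout
profile_with_holdout <- function(profile, n_holdout) {
  n_train <- profile$n_samples -
    as.integer(round(profile$validation_fraction * profile$n_samples))
  difficulty_profile(n_train + n_holdout, profile$n_features,
                     profile$n_informative, profile$effect_sizes,
                     profile$prevalence, profile$block_spec,
                     validation_fraction = n_holdout / (n_train + n_holdout))
}

# exhaustive pair-counting AUC oracle (independent of the implementation)
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
}
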