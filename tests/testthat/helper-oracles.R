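# Independent brute-force oracles used to cross-check the implementation.

# Definition-based Pearson correlation (no stats::cor).
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All-pairs Mann-Whitney AUC with half credit for ties.
oracle_auc <- function(decision, truth) {
  pos <- decision[truth == 1]; neg <- decision[truth == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Plug-in information gain computed from an explicit joint table.
oracle_ig <- function(bins, labels) {
  H <- function(v) {
    p <- table(v) / length(v); p <- p[p > 0]
    -sum(p * log2(p))
  }
  cond <- 0
  for (b in unique(bins)) cond <- cond + mean(bins == b) * H(labels[bins == b])
  H(labels) - cond
}

# Fold results in the shape pooled_auc()/importance() expect.
fake_folds <- function(decision, truth, weights = NULL) {
  lapply(seq_along(decision), function(i) {
    list(decision = decision[i], truth = truth[i],
         w = if (is.null(weights)) NULL else weights[i, ],
         train_accuracy = 1)
  })
}

# A small cohort with one strongly planted analyte -> descriptor link,
# analytes measured for everyone.
planted_cohort <- function(seed, n = 51, effect = 2, levels = 1:4,
                           descriptor = "SY", feature = "leptin") {
  cohort_config(
    n_subjects = n, n_sf_subset = n,
    descriptor_specs = stats::setNames(list(levels), descriptor),
    analyte_names = c("IL6", feature),
    planted_effects = list(list(feature = feature, descriptor = descriptor,
                                effect = effect)),
    seed = seed)
}

# Reduced penalty grid used by compute-heavy Monte-Carlo checks.
fast_svm_cfg <- function(seed = 1, fold_mode = "n_minus_one") {
  svm_config(C_grid = c(0.01, 1, 100), fold_mode = fold_mode, seed = seed)
}
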