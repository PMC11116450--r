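# Nested leave-one-out linear SVM classification.
#
# Outer loop: one subject held out per fold ("n_minus_one" mode holds
# out subjects 1..N-1, matching the reported model counts of 50 for 51
# subjects and 24 for 25; "standard" mode holds out all N). Inner loop:
# 5-fold cross-validation over a penalty grid selects C on the training
# remainder. Features are z-scored with train-fold statistics (SVM
# weights are not comparable across unscaled features). Feature
# importance is the fold-averaged weight vector, min-max normalized on
# absolute values to [0, 1]; classifier performance is the Mann-Whitney
# AUC over the pooled held-out decision values.

#' SVM pipeline configuration
#'
#' @param C_grid ordered positive penalty values (default
#'   \code{10^(-3:3)}).
#' @param k_inner inner cross-validation folds for tuning (default 5).
#' @param fold_mode \code{"n_minus_one"} (N subjects -> N-1 outer
#'   folds) or \code{"standard"} (N folds).
#' @param seed integer seed controlling inner fold assignment.
#' @return object of class \code{svm_config}.
#' @export
svm_config <- function(C_grid = 10^(-3:3), k_inner = 5,
                       fold_mode = c("n_minus_one", "standard"), seed = 1) {
  fold_mode <- match.arg(fold_mode)
  if (!length(C_grid) || any(C_grid <= 0)) stop_config("C_grid must be positive")
  if (is.unsorted(C_grid)) stop_config("C_grid must be ascending")
  if (k_inner < 2) stop_config("k_inner must be >= 2")
  structure(list(C_grid = C_grid, k_inner = k_inner,
                 fold_mode = fold_mode, seed = seed),
            class = "svm_config")
}

# Fit a soft-margin linear SVM; returns weights w, intercept b and a
# decision function d(x) = x.w - b oriented so d > 0 predicts label 1.
fit_linear_svm <- function(x, y, C) {
  yf <- factor(y, levels = c(0, 1))
  m <- e1071::svm(x, yf, kernel = "linear", cost = C, scale = FALSE)
  w <- as.numeric(t(m$coefs) %*% m$SV)
  names(w) <- colnames(x)
  b <- m$rho
  # libsvm orients the decision value so positive means the class that
  # occurs first in the training data (m$labels[1] indexes m$levels);
  # flip so positive always means label 1.
  if (m$levels[m$labels[1]] == "0") { w <- -w; b <- -b }
  list(w = w, b = b,
       decide = function(newx) drop(as.matrix(newx) %*% w) - b)
}

# Stratified fold ids: within each class, shuffled round-robin.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- (sample(seq_along(idx)) %% k) + 1L
  }
  fold
}

#' Select the SVM penalty by inner k-fold cross-validation
#'
#' Mean accuracy over seeded stratified folds for each grid value; ties
#' break toward the smallest C (strongest regularization). If the
#' minority class has fewer members than k, k is reduced to that count.
#'
#' @param x numeric feature matrix.
#' @param y binary 0/1 labels.
#' @param cfg an \code{\link{svm_config}}.
#' @param seed seed for fold assignment (default from cfg).
#' @return the selected C; per-grid mean accuracies attached as
#'   attribute \code{"cv_accuracy"}.
#' @export
tune_C <- function(x, y, cfg = svm_config(), seed = cfg$seed) {
  x <- as.matrix(x)
  n_min <- min(table(factor(y, levels = c(0, 1))))
  if (n_min == 0) stop_degenerate("single-class labels: cannot tune C")
  k <- min(cfg$k_inner, n_min)
  if (length(cfg$C_grid) == 1) {
    C <- cfg$C_grid
    attr(C, "cv_accuracy") <- NA_real_
    return(C)
  }
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(cfg$C_grid, function(C) {
    hits <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      fit <- fit_linear_svm(x[tr, , drop = FALSE], y[tr], C)
      pred <- as.integer(fit$decide(x[!tr, , drop = FALSE]) > 0)
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  C <- cfg$C_grid[which.max(acc)]  # first max = smallest C
  attr(C, "cv_accuracy") <- acc
  C
}

#' Nested leave-one-out cross-validation
#'
#' For each outer fold, tunes C on the training remainder
#' (\code{\link{tune_C}}), z-scores features with train statistics, fits
#' the linear SVM and records the held-out decision value. A fold whose
#' training set is single-class is skipped with a warning.
#'
#' @param features numeric matrix / data frame (subjects x features).
#' @param labels binary 0/1 labels.
#' @param cfg an \code{\link{svm_config}}.
#' @return list of fold results, each with \code{held_out} (row index),
#'   \code{w} (weights on the z-scored scale), \code{b}, \code{C},
#'   \code{decision} (held-out decision value), \code{truth} and
#'   \code{train_accuracy}.
#' @export
nested_loo <- function(features, labels, cfg = svm_config()) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 5) stop_config("need at least 5 subjects")
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop_config("need >= 2 subjects in each class")
  outer <- if (cfg$fold_mode == "n_minus_one") seq_len(n - 1) else seq_len(n)

  folds <- vector("list", length(outer))
  ok <- logical(length(outer))
  for (j in seq_along(outer)) {
    i <- outer[j]
    tr <- setdiff(seq_len(n), i)
    ytr <- labels[tr]
    if (length(unique(ytr)) < 2) {
      warning(sprintf("fold %d skipped: single-class training set", i))
      next
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1          # constant-in-train feature: centered to 0
    xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    C <- tune_C(xs[tr, , drop = FALSE], ytr, cfg,
                seed = child_seed(cfg$seed, i))
    fit <- fit_linear_svm(xs[tr, , drop = FALSE], ytr, C)
    train_pred <- as.integer(fit$decide(xs[tr, , drop = FALSE]) > 0)
    folds[[j]] <- list(held_out = i,
                       w = fit$w, b = fit$b, C = as.numeric(C),
                       decision = fit$decide(xs[i, , drop = FALSE]),
                       truth = labels[i],
                       train_accuracy = mean(train_pred == ytr))
    ok[j] <- TRUE
  }
  folds[ok]
}

#' Fold-averaged normalized feature importance
#'
#' The mean weight across folds is taken per feature; importances are
#' the absolute mean weights min-max mapped to [0, 1]. If all absolute
#' mean weights are equal and nonzero they map to 1 (max-normalization
#' convention); all-zero weights yield all-zero importances with
#' attribute \code{"degenerate" = TRUE}. Signed mean weights are
#' attached as attribute \code{"mean_weight"} for audit.
#'
#' @param folds fold results from \code{\link{nested_loo}}.
#' @return named numeric vector of importances in [0, 1].
#' @export
importance <- function(folds) {
  if (!length(folds)) stop_config("no folds")
  W <- do.call(rbind, lapply(folds, `[[`, "w"))
  wbar <- colMeans(W)
  a <- abs(wbar)
  if (max(a) == 0) {
    imp <- a
    attr(imp, "degenerate") <- TRUE
  } else if (max(a) == min(a)) {
    imp <- rep(1, length(a))
    names(imp) <- names(a)
  } else {
    imp <- (a - min(a)) / (max(a) - min(a))
  }
  attr(imp, "mean_weight") <- wbar
  imp
}

#' Pooled held-out ROC-AUC
#'
#' Mann-Whitney AUC over the pooled held-out decision values: the
#' probability that a random positive scores above a random negative,
#' ties counting one half (midranks).
#'
#' @param folds fold results from \code{\link{nested_loo}}, or a list
#'   with numeric \code{decision} and binary \code{truth} entries.
#' @return AUC in [0, 1].
#' @export
pooled_auc <- function(folds) {
  d <- vapply(folds, `[[`, numeric(1), "decision")
  y <- vapply(folds, `[[`, numeric(1), "truth")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop_degenerate("AUC undefined: pooled held-out labels are single-class")
  r <- rank(d)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run one classification task
#'
#' Assembles the input features for a target descriptor, binarizes the
#' target at its selected threshold, and runs the nested-LOO pipeline.
#' Input sets: \code{"clinical"} (the remaining descriptors after
#' pruning features with |r| > 0.7 against the continuous target; the
#' target itself is always excluded), \code{"sf"} (the analyte panel on
#' the synovial-fluid subset) or \code{"tf"} (steady-state TF
#' activations, subjects matched by id).
#'
#' @param ct a \code{\link{cohort_table}}.
#' @param target descriptor name.
#' @param input_set \code{"clinical"}, \code{"sf"} or \code{"tf"}.
#' @param thresholds named list of binarization records (with at least
#'   \code{$threshold}), e.g. from \code{\link{binarize_cohort}}.
#' @param cfg an \code{\link{svm_config}}.
#' @param tf_table TF activation \code{cohort_table} from
#'   \code{\link{batch_simulate}} (required for \code{input_set = "tf"}).
#' @param prune_cutoff |r| cutoff for the clinical-input prune
#'   (default 0.7).
#' @return object of class \code{classifier_report}: \code{task},
#'   \code{folds}, \code{importance}, \code{auc},
#'   \code{mean_train_accuracy}, \code{threshold}, \code{features_used},
#'   \code{features_omitted}, \code{n_subjects}.
#' @export
run_task <- function(ct, target, input_set = c("clinical", "sf", "tf"),
                     thresholds, cfg = svm_config(), tf_table = NULL,
                     prune_cutoff = 0.7) {
  input_set <- match.arg(input_set)
  clin <- cohort_features(ct, "clinical")
  if (!target %in% colnames(clin)) stop_config("unknown target '%s'", target)
  thr <- thresholds[[target]]$threshold
  if (is.null(thr)) stop_config("no threshold for target '%s'", target)

  omitted <- character(0)
  if (input_set == "clinical") {
    cand <- clin[, setdiff(colnames(clin), target), drop = FALSE]
    rep_ <- prune_vs_target(cand, clin[[target]], cutoff = prune_cutoff)
    omitted <- rep_$dropped$feature
    feats <- cand[, rep_$kept, drop = FALSE]
  } else if (input_set == "sf") {
    feats <- cohort_features(ct, "analyte")
  } else {
    if (is.null(tf_table)) stop_config("tf_table required for input_set 'tf'")
    feats <- cohort_features(tf_table, "tf")
    feats <- feats[rownames(feats) %in% ct$data$subject_id, , drop = FALSE]
  }

  ids <- if (input_set == "clinical") ct$data$subject_id else rownames(feats)
  tgt <- clin[match(ids, ct$data$subject_id), target]
  keep <- stats::complete.cases(feats) & !is.na(tgt)
  feats <- feats[keep, , drop = FALSE]
  y <- binarize(tgt[keep], thr)

  folds <- nested_loo(feats, y, cfg)
  structure(list(task = paste(target, input_set, sep = "/"),
                 target = target, input_set = input_set,
                 folds = folds,
                 importance = importance(folds),
                 auc = pooled_auc(folds),
                 mean_train_accuracy =
                   mean(vapply(folds, `[[`, numeric(1), "train_accuracy")),
                 threshold = thr,
                 features_used = colnames(feats),
                 features_omitted = omitted,
                 n_subjects = nrow(feats)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: %d folds on %d subjects, AUC = %.3f\n",
              x$task, length(x$folds), x$n_subjects, x$auc))
  invisible(x)
}

#' Assemble the targets-by-features importance matrix
#'
#' Rows are targets, columns the union of features across reports;
#' features omitted for a given target (pruned, or the target itself)
#' are NA, matching the blank cells of an importance heatmap.
#'
#' @param reports list of \code{classifier_report}s sharing one input
#'   set.
#' @param path optional CSV output path.
#' @return numeric matrix (targets x features).
#' @export
importance_matrix <- function(reports, path = NULL) {
  sets <- unique(vapply(reports, `[[`, character(1), "input_set"))
  if (length(sets) != 1) stop_config("reports mix input sets: %s",
                                     paste(sets, collapse = ", "))
  feats <- unique(unlist(lapply(reports, `[[`, "features_used")))
  M <- matrix(NA_real_, length(reports), length(feats),
              dimnames = list(vapply(reports, `[[`, character(1), "target"),
                              feats))
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    M[i, r$features_used] <- as.numeric(r$importance[r$features_used])
  }
  if (!is.null(path))
    utils::write.csv(data.frame(target = rownames(M), M, check.names = FALSE),
                     path, row.names = FALSE, na = "")
  M
}
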