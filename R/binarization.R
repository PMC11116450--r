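# Supervised binarization of ordinal clinical descriptors.
#
# Each discrete non-binary descriptor is converted into a binary target by
# a grid search over midpoint thresholds: every candidate split is scored
# by running the nested leave-one-out SVM pipeline on the would-be labels
# and computing Youden's index J = sensitivity + specificity - 1 on the
# pooled held-out predictions. A descriptor is retained as a target only
# if the mean train-set accuracy across folds reaches 0.75.

#' Confusion counts from binary truth and prediction
#'
#' @param truth,pred binary (0/1) vectors of equal length; pairs with
#'   missing values are dropped.
#' @return list with fields \code{TP}, \code{FN}, \code{TN}, \code{FP}.
#' @export
confusion_counts <- function(truth, pred) {
  keep <- !(is.na(truth) | is.na(pred))
  truth <- truth[keep]; pred <- pred[keep]
  list(TP = sum(truth == 1 & pred == 1),
       FN = sum(truth == 1 & pred == 0),
       TN = sum(truth == 0 & pred == 0),
       FP = sum(truth == 0 & pred == 1))
}

#' Youden's index
#'
#' J = TP/(TP+FN) + TN/(TN+FP) - 1, i.e. sensitivity + specificity - 1,
#' in [-1, 1]. Maximizing J selects the threshold with the best combined
#' sensitivity and specificity.
#'
#' @param counts confusion counts as returned by
#'   \code{\link{confusion_counts}} (list or named vector with TP, FN,
#'   TN, FP, all nonnegative).
#' @return J, a number in [-1, 1].
#' @export
youden_index <- function(counts) {
  cn <- as.list(counts)
  tp <- cn$TP; fn <- cn$FN; tn <- cn$TN; fp <- cn$FP
  if (any(c(tp, fn, tn, fp) < 0)) stop_config("negative confusion count")
  if (tp + fn == 0 || tn + fp == 0)
    stop_degenerate("Youden's index undefined: one class is empty")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Candidate binarization thresholds
#'
#' Midpoints between consecutive distinct observed values, ascending.
#'
#' @param values numeric vector of ordinal scores (missing values
#'   ignored).
#' @return numeric vector of candidate thresholds.
#' @export
candidate_thresholds <- function(values) {
  u <- sort(unique(values[!is.na(values)]))
  if (length(u) < 2)
    stop_degenerate("constant descriptor: no candidate thresholds")
  (u[-length(u)] + u[-1]) / 2
}

#' Binarize a vector at a threshold
#'
#' Label 1 iff value > threshold (above threshold = worse symptoms on
#' WOMAC-style scales); missing stays missing.
#'
#' @param values numeric vector.
#' @param threshold cut point.
#' @return integer 0/1 vector of the same length.
#' @export
binarize <- function(values, threshold) {
  as.integer(values > threshold)
}

#' Select the binarization threshold for a descriptor
#'
#' Grid search over \code{\link{candidate_thresholds}}: each candidate's
#' labels are evaluated by \code{\link{nested_loo}} on the supplied
#' features; Youden's J is computed on the pooled held-out predictions
#' (decision value > 0), and mean train accuracy across folds feeds the
#' 0.75 retention gate. Candidates that leave either class with fewer
#' than 2 members are skipped (leave-one-out needs both classes in every
#' training set). Ties in J break toward the smallest threshold.
#'
#' @param features numeric data frame / matrix of input features (rows
#'   aligned with \code{descriptor}).
#' @param descriptor ordinal score vector to binarize.
#' @param cfg an \code{\link{svm_config}}.
#' @param accuracy_gate minimum mean train accuracy for retention
#'   (default 0.75).
#' @return object of class \code{binarization_result}: selected
#'   \code{threshold}, \code{youden} J at selection,
#'   \code{mean_train_accuracy}, \code{retained}, and the per-candidate
#'   \code{grid} data frame.
#' @export
select_threshold <- function(features, descriptor, cfg = svm_config(),
                             accuracy_gate = 0.75) {
  features <- as.matrix(features)
  keep <- stats::complete.cases(features) & !is.na(descriptor)
  features <- features[keep, , drop = FALSE]
  descriptor <- descriptor[keep]
  cand <- candidate_thresholds(descriptor)

  grid <- data.frame(threshold = cand, youden = NA_real_,
                     mean_train_accuracy = NA_real_, skipped = FALSE)
  for (i in seq_along(cand)) {
    y <- binarize(descriptor, cand[i])
    if (sum(y == 1) < 2 || sum(y == 0) < 2) {
      grid$skipped[i] <- TRUE
      next
    }
    folds <- nested_loo(features, y, cfg)
    pred <- as.integer(vapply(folds, `[[`, numeric(1), "decision") > 0)
    truth <- vapply(folds, `[[`, numeric(1), "truth")
    grid$youden[i] <- youden_index(confusion_counts(truth, pred))
    grid$mean_train_accuracy[i] <-
      mean(vapply(folds, `[[`, numeric(1), "train_accuracy"))
  }
  if (all(grid$skipped))
    stop_degenerate("no valid threshold: every candidate leaves a class with < 2 members")
  ok <- which(!grid$skipped)
  best <- ok[which.max(grid$youden[ok])]  # which.max: first max = smallest threshold
  structure(list(threshold = grid$threshold[best],
                 youden = grid$youden[best],
                 mean_train_accuracy = grid$mean_train_accuracy[best],
                 retained = grid$mean_train_accuracy[best] >= accuracy_gate,
                 grid = grid),
            class = "binarization_result")
}

#' @export
print.binarization_result <- function(x, ...) {
  cat(sprintf("<binarization_result> threshold %.3g, J = %.3f, mean train acc = %.3f, %s\n",
              x$threshold, x$youden, x$mean_train_accuracy,
              if (x$retained) "retained" else "dropped (gate 0.75)"))
  invisible(x)
}

#' Binarize every descriptor of a cohort and write a thresholds table
#'
#' Runs \code{\link{select_threshold}} for each clinical descriptor,
#' using the remaining descriptors (complete cases) as features.
#'
#' @param ct a \code{\link{cohort_table}}.
#' @param cfg an \code{\link{svm_config}}.
#' @param descriptors which descriptors to binarize (default: all
#'   clinical columns).
#' @return named list of \code{binarization_result}s.
#' @export
binarize_cohort <- function(ct, cfg = svm_config(), descriptors = NULL) {
  clin <- cohort_features(ct, "clinical")
  descriptors <- descriptors %||% colnames(clin)
  out <- list()
  for (dn in descriptors) {
    feats <- clin[, setdiff(colnames(clin), dn), drop = FALSE]
    out[[dn]] <- select_threshold(feats, clin[[dn]], cfg)
  }
  out
}

#' Write / read the thresholds YAML consumed by external validation
#'
#' @param results named list of \code{binarization_result}s (or a named
#'   list of lists with the same fields).
#' @param path YAML path.
#' @return \code{write_thresholds}: the path invisibly;
#'   \code{read_thresholds}: named list of threshold records.
#' @export
write_thresholds <- function(results, path) {
  rec <- lapply(results, function(r)
    list(threshold = r$threshold, youden = r$youden,
         mean_train_accuracy = r$mean_train_accuracy,
         retained = r$retained))
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) yaml::read_yaml(path)
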