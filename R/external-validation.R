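# Transfer of binarization thresholds to an external OAI-like table.
#
# Protocol: exclude subjects with knee-surgery history, drop subjects
# with less than 80% of variables completed, prune pairwise-correlated
# features (|r| > 0.7), rank the survivors by information gain and keep
# the top 50, then tune the SVM penalty and report seeded stratified
# 5-fold cross-validated accuracy per WOMAC-style target.

#' External validation protocol configuration
#'
#' @param flag_columns binary columns marking surgery history; flagged
#'   rows are excluded.
#' @param min_completeness completeness fraction threshold (default
#'   0.8, inclusive).
#' @param pairwise_cutoff |r| cutoff for pairwise pruning (default 0.7).
#' @param ig_top_k features kept after information-gain ranking
#'   (default 50).
#' @param svm_cfg an \code{\link{svm_config}} (its C grid and seed are
#'   used).
#' @param k_eval stratified cross-validation folds for the reported
#'   accuracy (default 5).
#' @param targets the WOMAC-style target columns (default: the six
#'   left/right pain, function and rigidity columns of
#'   \code{\link{generate_external_table}}).
#' @return object of class \code{validation_config}.
#' @export
validation_config <- function(flag_columns = "surgery_history",
                              min_completeness = 0.8,
                              pairwise_cutoff = 0.7,
                              ig_top_k = 50,
                              svm_cfg = svm_config(),
                              k_eval = 5,
                              targets = c("womac_pain_left", "womac_pain_right",
                                          "womac_func_left", "womac_func_right",
                                          "womac_rigidity_left",
                                          "womac_rigidity_right")) {
  if (k_eval < 2) stop_config("k_eval must be >= 2")
  structure(list(flag_columns = flag_columns,
                 min_completeness = min_completeness,
                 pairwise_cutoff = pairwise_cutoff,
                 ig_top_k = ig_top_k, svm_cfg = svm_cfg,
                 k_eval = k_eval, targets = targets),
            class = "validation_config")
}

#' Apply surgery-history exclusions and the completeness filter
#'
#' @param ct a \code{\link{cohort_table}}.
#' @param cfg a \code{\link{validation_config}}.
#' @return the filtered \code{cohort_table} with attribute
#'   \code{"removal_counts"} = c(flagged, incomplete).
#' @export
apply_exclusions <- function(ct, cfg = validation_config()) {
  dat <- ct$data
  miss <- setdiff(cfg$flag_columns, names(dat))
  if (length(miss)) stop_config("flag column absent: %s",
                                paste(miss, collapse = ", "))
  flagged <- rowSums(dat[, cfg$flag_columns, drop = FALSE] == 1, na.rm = TRUE) > 0
  dat <- dat[!flagged, , drop = FALSE]
  if (!nrow(dat)) stop_degenerate("exclusions removed every subject")
  ct2 <- cohort_table(dat, ct$kinds, ct$levels)
  feature_cols <- names(ct$kinds)[ct$kinds == "analyte"]
  ct3 <- completeness_filter(ct2, cfg$min_completeness, columns = feature_cols)
  attr(ct3, "removal_counts") <- c(flagged = sum(flagged),
                                   incomplete = attr(ct3, "n_removed"))
  attr(ct3, "n_removed") <- NULL
  ct3
}

#' Binarize the external targets at transferred thresholds
#'
#' Each target column is cut at the threshold selected on the cohort.
#' The thresholds file declares each threshold on the descriptor's own
#' scale; no rescaling is performed, and a missing target column is an
#' error. Targets whose binarization yields a single class are reported
#' and must be skipped downstream.
#'
#' @param ct a \code{\link{cohort_table}}.
#' @param thresholds named list of records with a \code{$threshold}
#'   field (see \code{\link{read_thresholds}}); names must cover the
#'   targets.
#' @param targets target column names.
#' @return data frame of 0/1 columns with attribute
#'   \code{"class_balance"} (per-target positive fraction) and
#'   \code{"single_class"} (logical per target).
#' @export
apply_thresholds <- function(ct, thresholds, targets = names(thresholds)) {
  dat <- ct$data
  miss <- setdiff(targets, names(dat))
  if (length(miss)) stop_config("target column absent: %s",
                                paste(miss, collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(dat)))
  bal <- numeric(0); single <- logical(0)
  for (t in targets) {
    thr <- thresholds[[t]]$threshold
    if (is.null(thr)) stop_config("no threshold declared for target '%s'", t)
    y <- binarize(dat[[t]], thr)
    out[[t]] <- y
    bal[t] <- mean(y, na.rm = TRUE)
    single[t] <- length(unique(stats::na.omit(y))) < 2
    if (single[t]) warning(sprintf("target '%s' binarizes to a single class", t))
  }
  attr(out, "class_balance") <- bal
  attr(out, "single_class") <- single
  out
}

# Stratified k-fold CV accuracy with a fixed C.
cv_accuracy <- function(x, y, C, k, seed) {
  fold <- stratified_folds(y, k, seed)
  hits <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    fit <- fit_linear_svm(xs[tr, , drop = FALSE], y[tr], C)
    pred <- as.integer(fit$decide(xs[!tr, , drop = FALSE]) > 0)
    hits <- hits + sum(pred == y[!tr])
  }
  hits / length(y)
}

#' Run the external validation protocol
#'
#' Pipeline: \code{\link{apply_exclusions}} ->
#' \code{\link{prune_pairwise}} -> per-target
#' \code{\link{rank_by_information_gain}} (top \code{ig_top_k}) ->
#' \code{\link{tune_C}} -> stratified k-fold CV accuracy. Counts after
#' every stage are recorded. Feature values still missing after the
#' completeness exclusion are imputed with the column median (the SVM
#' needs complete inputs; features are z-scored per CV training fold).
#'
#' @param ct the external \code{\link{cohort_table}}.
#' @param thresholds named threshold records covering
#'   \code{cfg$targets}.
#' @param cfg a \code{\link{validation_config}}.
#' @return object of class \code{validation_report}: per-target
#'   accuracy, mean accuracy, stage counts, selected features and C per
#'   target, evaluation scheme label.
#' @export
validate_external <- function(ct, thresholds, cfg = validation_config()) {
  n0 <- nrow(ct$data)
  ct <- apply_exclusions(ct, cfg)
  counts <- c(input = n0, after_exclusions = nrow(ct$data))

  feature_cols <- names(ct$kinds)[ct$kinds == "analyte"]
  prune_rep <- prune_pairwise(ct$data[, feature_cols, drop = FALSE],
                              cutoff = cfg$pairwise_cutoff)
  kept <- prune_rep$kept
  counts["features_input"] <- length(feature_cols)
  counts["features_after_prune"] <- length(kept)

  labels <- apply_thresholds(ct, thresholds, cfg$targets)
  x_all <- as.matrix(ct$data[, kept, drop = FALSE])
  for (j in seq_len(ncol(x_all))) {          # median-impute residual gaps
    nas <- is.na(x_all[, j])
    if (any(nas)) x_all[nas, j] <- stats::median(x_all[, j], na.rm = TRUE)
  }
  acc <- stats::setNames(rep(NA_real_, length(cfg$targets)), cfg$targets)
  selected <- list(); Csel <- stats::setNames(rep(NA_real_, length(cfg$targets)),
                                              cfg$targets)
  for (t in cfg$targets) {
    y <- labels[[t]]
    if (attr(labels, "single_class")[t]) next
    cc <- !is.na(y)
    xt <- x_all[cc, , drop = FALSE]; yt <- y[cc]
    k_avail <- min(cfg$ig_top_k, ncol(xt))
    if (k_avail < cfg$ig_top_k)
      warning(sprintf("only %d features survive pruning (k = %d requested)",
                      ncol(xt), cfg$ig_top_k))
    top <- suppressWarnings(
      rank_by_information_gain(as.data.frame(xt), yt, k = k_avail))
    xt <- xt[, top, drop = FALSE]
    # tuning on standardized features, as in the per-fold pipeline
    xs <- scale(xt)
    xs[, attr(xs, "scaled:scale") == 0] <- 0
    C <- tune_C(xs, yt, cfg$svm_cfg, seed = child_seed(cfg$svm_cfg$seed, 1))
    acc[t] <- cv_accuracy(xt, yt, as.numeric(C), cfg$k_eval,
                          seed = child_seed(cfg$svm_cfg$seed, 2))
    selected[[t]] <- top
    Csel[t] <- as.numeric(C)
  }
  structure(list(accuracy = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 counts = counts,
                 removal_counts = attr(ct, "removal_counts"),
                 kept_features = kept,
                 selected_features = selected,
                 selected_C = Csel,
                 class_balance = attr(labels, "class_balance"),
                 scheme = sprintf("stratified %d-fold CV accuracy", cfg$k_eval)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s; mean accuracy = %.3f\n",
              x$scheme, x$mean_accuracy))
  print(round(x$accuracy, 3))
  invisible(x)
}
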