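# Correlation pruning and information-gain ranking.
#
# Two pruning rules are used at different stages: the cohort stage drops
# features with |r| > 0.7 against the continuous target (redundancy with
# the output); the external-validation stage drops features pairwise
# (greedy, first occurrence wins). |r| is compared rather than signed r:
# a strong negative correlation is equally redundant under a linear
# kernel.

#' Pearson product-moment correlation on pairwise-complete observations
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value
#'   are dropped before computing.
#' @return r in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_degenerate("fewer than 3 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_degenerate("correlation undefined for a constant vector")
  stats::cor(x, y)
}

selection_report <- function(kept, dropped, reason, stat, rule) {
  structure(list(kept = kept,
                 dropped = data.frame(feature = dropped, reason = reason,
                                      stringsAsFactors = FALSE),
                 statistics = stat, rule = rule),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> rule %s: %d kept, %d dropped\n",
              x$rule, length(x$kept), nrow(x$dropped)))
  invisible(x)
}

#' Drop features strongly correlated with the target
#'
#' Removes every feature whose |r| with the target exceeds the cutoff,
#' and the target itself if it appears as a column. Features whose
#' correlation is undefined (constant) are kept and flagged in the
#' statistics.
#'
#' @param table data frame of numeric feature columns.
#' @param target numeric (binary-capable) vector.
#' @param cutoff absolute-correlation cutoff (default 0.7).
#' @return a \code{selection_report}; \code{$kept} holds the surviving
#'   feature names.
#' @export
prune_vs_target <- function(table, target, cutoff = 0.7) {
  table <- as.data.frame(table)
  if (stats::sd(target, na.rm = TRUE) == 0)
    stop_degenerate("target is constant")
  rs <- vapply(table, function(col) {
    tryCatch(pearson_r(col, target), error = function(e) NA_real_)
  }, numeric(1))
  is_target <- vapply(table, function(col) isTRUE(all(col == target)), logical(1))
  drop <- is_target | (!is.na(rs) & abs(rs) > cutoff)
  if (all(drop)) warning("all features pruned against the target")
  selection_report(names(table)[!drop], names(table)[drop],
                   ifelse(is_target[drop], "is-target", "vs-target-r"),
                   rs, "vs-target")
}

#' Greedy pairwise correlation pruning
#'
#' Scans columns in order; a feature is dropped if its |r| with any
#' already-kept feature exceeds the cutoff (first occurrence wins).
#'
#' @param table data frame of numeric feature columns (>= 2).
#' @param cutoff absolute-correlation cutoff (default 0.7).
#' @return a \code{selection_report}.
#' @export
prune_pairwise <- function(table, cutoff = 0.7) {
  table <- as.data.frame(table)
  if (ncol(table) < 2) stop_config("need >= 2 columns")
  kept <- character(0)
  dropped <- character(0)
  maxr <- stats::setNames(rep(NA_real_, ncol(table)), names(table))
  for (nm in names(table)) {
    r_with_kept <- vapply(kept, function(k) {
      tryCatch(abs(pearson_r(table[[nm]], table[[k]])),
               error = function(e) 0)
    }, numeric(1))
    maxr[nm] <- if (length(r_with_kept)) max(r_with_kept) else NA_real_
    if (length(r_with_kept) && any(r_with_kept > cutoff)) {
      dropped <- c(dropped, nm)
    } else {
      kept <- c(kept, nm)
    }
  }
  selection_report(kept, dropped,
                   rep("pairwise-r", length(dropped)), maxr, "pairwise")
}

entropy_bits <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a feature for a binary label
#'
#' IG = H(labels) - sum_b p(bin b) H(labels | bin b), entropies base 2.
#' Continuous features are discretized into equal-frequency bins;
#' features with at most \code{n_bins} distinct values (ordinal or
#' categorical) are used as-is. Missing feature values form their own
#' bin.
#'
#' @param feature numeric vector.
#' @param labels binary 0/1 vector, both classes present.
#' @param n_bins number of equal-frequency bins (default 10).
#' @return information gain in bits, >= 0.
#' @export
information_gain <- function(feature, labels, n_bins = 10) {
  keep <- !is.na(labels)
  feature <- feature[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop_degenerate("labels contain a single class: entropy is zero")
  u <- unique(feature[!is.na(feature)])
  if (length(u) <= n_bins) {
    bins <- as.character(feature)
  } else {
    cuts <- unique(stats::quantile(feature, probs = seq_len(n_bins - 1) / n_bins,
                                   na.rm = TRUE, names = FALSE))
    bins <- as.character(findInterval(feature, cuts))
  }
  bins[is.na(feature)] <- "NA"
  h <- entropy_bits(labels)
  cond <- 0
  for (b in unique(bins)) {
    idx <- bins == b
    cond <- cond + mean(idx) * entropy_bits(labels[idx])
  }
  max(h - cond, 0)
}

#' Rank features by information gain
#'
#' @param table data frame of candidate feature columns.
#' @param labels binary 0/1 vector.
#' @param k number of top features to return (default 50); if fewer
#'   features are available, all are returned with a warning.
#' @param n_bins bins passed to \code{\link{information_gain}}.
#' @return character vector of feature names, IG descending (ties keep
#'   column order); the IG values are attached as attribute \code{"ig"}.
#' @export
rank_by_information_gain <- function(table, labels, k = 50, n_bins = 10) {
  table <- as.data.frame(table)
  ig <- vapply(table, information_gain, numeric(1),
               labels = labels, n_bins = n_bins)
  ord <- order(-ig)            # stable: ties keep column order
  if (k > length(ig)) {
    warning(sprintf("only %d features available for k = %d", length(ig), k))
    k <- length(ig)
  }
  sel <- names(table)[ord[seq_len(k)]]
  attr(sel, "ig") <- ig[ord[seq_len(k)]]
  sel
}

#' Drop subjects with too many missing variables
#'
#' Keeps rows whose fraction of non-missing feature values is at least
#' \code{min_fraction} (inclusive at the boundary).
#'
#' @param ct a \code{\link{cohort_table}} or data frame.
#' @param min_fraction minimum completeness fraction (default 0.8).
#' @param columns columns over which completeness is computed (default:
#'   all non-id columns).
#' @return the filtered object, same class as the input; the number of
#'   removed rows is attached as attribute \code{"n_removed"}.
#' @export
completeness_filter <- function(ct, min_fraction = 0.8, columns = NULL) {
  is_ct <- inherits(ct, "cohort_table")
  dat <- if (is_ct) ct$data else as.data.frame(ct)
  columns <- columns %||% setdiff(names(dat), "subject_id")
  frac <- rowMeans(!is.na(dat[, columns, drop = FALSE]))
  keep <- frac >= min_fraction
  if (!any(keep)) stop_degenerate("completeness filter removed every subject")
  out <- dat[keep, , drop = FALSE]
  rownames(out) <- NULL
  res <- if (is_ct) cohort_table(out, ct$kinds, ct$levels) else out
  attr(res, "n_removed") <- sum(!keep)
  res
}
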