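# ROC construction, AUC, Youden-index threshold selection, threshold
# metrics, and confusion matrices.
#
# Conventions: an item is predicted positive when its score is >= the
# threshold. Thresholds are the distinct observed scores in descending order
# preceded by an Inf sentinel, so the curve always starts at (0, 0) and ends
# at (1, 1). Ties in Youden's J are broken toward the smallest threshold
# (favoring sensitivity).

check_scored_batch <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("`scores` must lie in [0, 1]", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("`labels` must be 0/1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Empirical ROC curve
#'
#' Thresholds are the distinct scores in descending order plus a sentinel
#' above the maximum; TPR/FPR are computed by cumulative counting with the
#' `>=` prediction convention (score ties are grouped).
#'
#' @param scores Per-item probability of the positive class, in `[0, 1]`.
#' @param labels Per-item binary ground truth (1 = positive). Both classes
#'   must be present.
#' @return An object of class `roc_curve`: list with parallel `thresholds`
#'   (descending), `tpr`, `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  check_scored_batch(scores, labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(l == 1)[grp_last]
  fp <- cumsum(l == 0)[grp_last]
  structure(list(thresholds = c(Inf, s[grp_last]),
                 tpr = c(0, tp / npos),
                 fpr = c(0, fp / nneg)),
            class = "roc_curve")
}

#' Area under a ROC curve
#'
#' Trapezoidal area over FPR. Equals the tie-corrected Mann-Whitney pair
#' count (concordant pairs plus half credit for score ties) divided by
#' `n_pos * n_neg`.
#'
#' @param curve A [roc_curve()].
#' @return Area in `[0, 1]`.
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

#' Youden's index and the best threshold
#'
#' `J = max over thresholds of (TPR - FPR)`; the returned threshold is the
#' smallest maximizer (ties broken toward sensitivity).
#'
#' @param curve A [roc_curve()].
#' @return List with `youden_j` and `best_threshold`.
#' @export
youden_best <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$tpr - curve$fpr
  jmax <- max(j)
  # thresholds are descending, so the last maximizer is the smallest
  best <- max(which(j >= jmax - 1e-12))
  list(youden_j = jmax, best_threshold = curve$thresholds[best])
}

#' Accuracy, sensitivity, specificity at a threshold
#'
#' Predicts positive when `score >= threshold`; `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`, `ACC = (TP + TN) / n`.
#'
#' @param scores Per-item positive-class probability.
#' @param labels Binary ground truth.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return List with `acc`, `sen`, `spe`.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  check_scored_batch(scores, labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  list(acc = (tp + tn) / length(labels),
       sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Full threshold report for a scored batch
#'
#' AUC, Youden's J with its best threshold, and ACC/SEN/SPE evaluated at
#' that threshold (or at a supplied one). At the Youden-best threshold,
#' `youden_j = sen + spe - 1` exactly (same counting path).
#'
#' @param scores Positive-class probabilities.
#' @param labels Binary ground truth.
#' @param threshold Optional fixed threshold; defaults to the Youden optimum.
#' @return An object of class `threshold_report`: list with `auc`,
#'   `youden_j`, `best_threshold`, `acc`, `sen`, `spe`.
#' @export
threshold_report <- function(scores, labels, threshold = NULL) {
  curve <- roc_curve(scores, labels)
  yb <- youden_best(curve)
  thr <- threshold %||% yb$best_threshold
  m <- threshold_metrics(scores, labels, thr)
  structure(list(auc = roc_auc(curve), youden_j = yb$youden_j,
                 best_threshold = thr, acc = m$acc, sen = m$sen, spe = m$spe),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("AUC %.3f | Y index %.3f | Best T %.3f | ACC %.3f | SEN %.3f | SPE %.3f\n",
              x$auc, x$youden_j, x$best_threshold, x$acc, x$sen, x$spe))
  invisible(x)
}

#' One-vs-rest scored batches from a probability matrix
#'
#' Batch `i` scores every item by column `i` and labels it positive when its
#' true class is `i` — each class evaluated as its own positive, the way the
#' binary skin detector treats skin (class 0) and non-skin (class 1).
#'
#' @param probs `n x k` matrix of normalized class probabilities.
#' @param labels Integer true classes (1-based, in `1..k`).
#' @return A list of `k` lists, each with `scores` and `labels`.
#' @export
one_vs_rest_batches <- function(probs, labels) {
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("rows of `probs` must be normalized", call. = FALSE)
  }
  k <- ncol(probs)
  lapply(seq_len(k), function(i) {
    list(scores = probs[, i], labels = as.integer(labels == i))
  })
}

#' Confusion matrix
#'
#' `counts[actual, predicted]` over `k` classes (1-based labels).
#'
#' @param pred_labels,true_labels Integer labels in `1..k`.
#' @param k Number of classes.
#' @param class_names Optional dimnames.
#' @return An object of class `confusion_matrix`: integer `k x k` matrix,
#'   rows = actual, columns = predicted.
#' @export
confusion_matrix <- function(pred_labels, true_labels, k,
                             class_names = NULL) {
  if (length(pred_labels) != length(true_labels)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (any(c(pred_labels, true_labels) < 1 | c(pred_labels, true_labels) > k)) {
    stop("labels must lie in 1..k", call. = FALSE)
  }
  m <- matrix(0L, k, k)
  for (i in seq_along(pred_labels)) {
    m[true_labels[i], pred_labels[i]] <- m[true_labels[i], pred_labels[i]] + 1L
  }
  if (!is.null(class_names)) dimnames(m) <- list(actual = class_names,
                                                 predicted = class_names)
  structure(m, class = c("confusion_matrix", "matrix", "array"))
}

#' Row-normalize a confusion matrix
#'
#' Divides each actual-class row by its total so diagonals read as per-class
#' recall. Rows with zero count become all-zero and are flagged in the
#' `zero_rows` attribute.
#'
#' @param m A [confusion_matrix()] (or plain count matrix).
#' @return Numeric matrix of the same shape with attribute `zero_rows`.
#' @export
normalize_rows <- function(m) {
  rs <- rowSums(m)
  out <- m / ifelse(rs == 0, 1, rs)
  out <- unclass(out)
  attr(out, "zero_rows") <- which(rs == 0)
  out
}

#' Write threshold reports as a CSV table
#'
#' One row per (model, class) with columns Model, Class, AUC, Y index,
#' Best T, ACC, SEN, SPE.
#'
#' @param reports Named list of `threshold_report` objects; names are taken
#'   as "Model/Class" when they contain a slash, else the Model column.
#' @param path CSV path.
#' @return The assembled data frame, invisibly.
#' @export
write_threshold_reports <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    data.frame(Model = parts[1],
               Class = if (length(parts) > 1) parts[2] else "",
               AUC = r$auc, `Y index` = r$youden_j, `Best T` = r$best_threshold,
               ACC = r$acc, SEN = r$sen, SPE = r$spe, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a (normalized) confusion matrix as CSV with class-name headers
#' @param m A confusion matrix (counts or normalized).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(m, path) {
  write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
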