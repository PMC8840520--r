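# Confusion counts, accuracy/sensitivity/specificity, ROC/AUC, F1.

check_labels01 <- function(x, name) {
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop(sprintf("`%s` must contain only 0/1 values", name), call. = FALSE)
  }
  x
}

#' Confusion counts for binary predictions
#'
#' Class 1 ("active binding") is the positive class.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return Object of class `confusion_counts` with integer fields `TP`,
#'   `TN`, `FP`, `FN`, `N`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- check_labels01(y_true, "y_true")
  y_pred <- check_labels01(y_pred, "y_pred")
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  confusion_counts(TP = sum(y_true == 1L & y_pred == 1L),
                   TN = sum(y_true == 0L & y_pred == 0L),
                   FP = sum(y_true == 0L & y_pred == 1L),
                   FN = sum(y_true == 1L & y_pred == 0L))
}

#' Construct confusion counts directly from the four cells
#'
#' Useful for re-deriving metrics from counts printed in published tables.
#'
#' @param TP,TN,FP,FN Non-negative integers.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  for (nm in c("TP", "TN", "FP", "FN")) {
    v <- get(nm)
    check_scalar(v, nm, integer = TRUE)
    if (v < 0) stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
  }
  structure(list(TP = as.integer(TP), TN = as.integer(TN),
                 FP = as.integer(FP), FN = as.integer(FN),
                 N = as.integer(TP + TN + FP + FN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (N=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$N))
  invisible(x)
}

#' Accuracy, sensitivity, and specificity from confusion counts
#'
#' Accuracy is reported as a percentage `100 (TP+TN)/N`; sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)` as fractions. A zero
#' denominator (a test set with no positives, or no negatives) yields
#' `NA_real_` as an explicit "undefined" marker rather than a silent 0.
#' Full precision is retained; rounding is left to display code.
#'
#' @param c A `confusion_counts` object with `N > 0`.
#' @return List with `accuracy` (percent), `sensitivity`, `specificity`.
#' @export
class_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$N == 0L) stop("empty confusion counts (N = 0)", call. = FALSE)
  pos <- c$TP + c$FN
  neg <- c$TN + c$FP
  list(accuracy = 100 * (c$TP + c$TN) / c$N,
       sensitivity = if (pos > 0L) c$TP / pos else NA_real_,
       specificity = if (neg > 0L) c$TN / neg else NA_real_)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores in descending
#' order (predict 1 when score >= threshold), yielding a curve from (0, 0)
#' to (1, 1); AUC is the trapezoidal area, identical to the normalized
#' Mann-Whitney U statistic with ties counted half.
#'
#' @param y_true 0/1 vector containing both classes.
#' @param scores Numeric ranking scores, higher = more class-1.
#' @return Object of class `roc_curve` with `fpr`, `tpr`, `thresholds`
#'   (including a leading `Inf`), and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- check_labels01(y_true, "y_true")
  if (length(y_true) != length(scores)) {
    stop("`y_true` and `scores` must have equal length", call. = FALSE)
  }
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC requires both classes in `y_true`", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]
  s <- scores[ord]
  # cumulative counts at each unique score (threshold = that score)
  last <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' F1 score of the positive class
#'
#' Harmonic mean of precision and recall: `2 TP / (2 TP + FP + FN)`.
#'
#' @param TP,FP,FN Non-negative integers, not all zero.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(TP, FP, FN) {
  for (nm in c("TP", "FP", "FN")) {
    v <- get(nm)
    check_scalar(v, nm, integer = TRUE)
    if (v < 0) stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
  }
  if (TP + FP + FN == 0) {
    stop("F1 undefined: TP + FP + FN = 0", call. = FALSE)
  }
  2 * TP / (2 * TP + FP + FN)
}

#' Write ROC points as a two-column CSV
#'
#' @param roc A `roc_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_curve"))
  utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
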