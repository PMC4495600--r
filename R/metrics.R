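# Confusion-matrix metrics and ROC/AUC.

#' Confusion counts from predictions and truth
#'
#' @param predicted,actual vectors of `+1`/`-1` labels, or pass `TP`, `FN`,
#'   `TN`, `FP` directly via the count arguments.
#' @param TP,FN,TN,FP explicit non-negative counts (used when `predicted`
#'   is missing).
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(predicted = NULL, actual = NULL,
                             TP = NULL, FN = NULL, TN = NULL, FP = NULL) {
  if (!is.null(predicted)) {
    stopifnot(length(predicted) == length(actual))
    TP <- sum(predicted == 1L & actual == 1L)
    FN <- sum(predicted == -1L & actual == 1L)
    TN <- sum(predicted == -1L & actual == -1L)
    FP <- sum(predicted == 1L & actual == -1L)
  }
  stopifnot(TP >= 0, FN >= 0, TN >= 0, FP >= 0)
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param x a `confusion_counts` object.
#' @param ... unused.
#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FN=%d TN=%d FP=%d\n", x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}

pct2 <- function(x) round(100 * x, 2)

#' Accuracy, sensitivity and specificity (percent)
#'
#' `Ac = (TP+TN)/(TP+FN+TN+FP)`, `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' reported as percentages rounded to two decimals.  A zero denominator
#' yields `NA` (never a silent zero).
#'
#' @param counts a [confusion_counts()] object.
#' @return Percentage (two decimals) or `NA` if undefined.
#' @export
accuracy <- function(counts) {
  n <- counts$TP + counts$FN + counts$TN + counts$FP
  if (n == 0) return(NA_real_)
  pct2((counts$TP + counts$TN) / n)
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  n <- counts$TP + counts$FN
  if (n == 0) return(NA_real_)
  pct2(counts$TP / n)
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  n <- counts$TN + counts$FP
  if (n == 0) return(NA_real_)
  pct2(counts$TN / n)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a value in
#' `[-1, 1]`.  Any zero marginal yields `NA`.
#'
#' @param counts a [confusion_counts()] object.
#' @return MCC as a raw value (not a percentage), or `NA`.
#' @export
mcc <- function(counts) {
  m <- with(counts, c(TP + FP, TP + FN, TN + FP, TN + FN))
  if (any(m == 0)) return(NA_real_)
  with(counts, (TP * TN - FP * FN) / sqrt(prod(m)))
}

#' ROC curve points
#'
#' True/false positive rates at every distinct score cutoff (ties grouped),
#' including the (0,0) and (1,1) endpoints.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels `+1`/`-1` labels; both classes must be present.
#' @return `data.frame(cutoff, fpr, tpr)` ordered by increasing `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == -1L)
  if (np == 0L || nn == 0L) stop("both classes required", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y == 1L); fp <- cumsum(y == -1L)
  last <- cumsum(rle(s)$lengths)       # one point per distinct score
  data.frame(cutoff = c(Inf, s[last]),
             fpr = c(0, fp[last] / nn),
             tpr = c(0, tp[last] / np))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()] points; equals the Mann-Whitney
#' U statistic divided by `n+ * n-`.
#'
#' @param x a `roc_curve()` data.frame, or numeric scores (then `labels`
#'   must be given).
#' @param labels optional labels when `x` is a score vector.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(x, labels = NULL) {
  if (!is.data.frame(x)) x <- roc_curve(x, labels)
  sum(diff(x$fpr) * (utils::head(x$tpr, -1) + utils::tail(x$tpr, -1)) / 2)
}
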