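#' Threshold classification of continuous class estimates
#'
#' A sample is called positive when its estimate is greater than or equal
#' to the threshold (ties at the threshold are positive — a documented,
#' deterministic rule that is immaterial for continuous estimates). The
#' default threshold of 0.4 reflects the typical operating point of a
#' 0/1-coded PLS-DA with an imbalanced positive class.
#'
#' @param yhat numeric estimates.
#' @param threshold decision threshold (default 0.4).
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(yhat, threshold = 0.4) {
  if (any(!is.finite(yhat))) stop("non-finite estimates", call. = FALSE)
  as.integer(yhat >= threshold)
}

#' Confusion matrix for a binary classifier
#'
#' @param y_true true labels (0/1, logical, or 2-level factor with the
#'   positive class as first level).
#' @param y_pred predicted labels, same coding.
#' @return Object of class `confusion` with counts `tp`, `fn`, `fp`, `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  yt <- coerce_class01(y_true)
  yp <- coerce_class01(y_pred)
  if (length(yt) != length(yp)) stop("length mismatch", call. = FALSE)
  structure(list(tp = sum(yt == 1 & yp == 1), fn = sum(yt == 1 & yp == 0),
                 fp = sum(yt == 0 & yp == 1), tn = sum(yt == 0 & yp == 0)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("true positive", "true negative"),
                              c("pred positive", "pred negative")))
  rowpct <- sweep(m, 1, rowSums(m), `/`) * 100
  for (i in 1:2)
    cat(sprintf("%-14s %5d (%.1f%%)  %5d (%.1f%%)\n", rownames(m)[i],
                m[i, 1], rowpct[i, 1], m[i, 2], rowpct[i, 2]))
  invisible(x)
}

#' Sensitivity, specificity and error rates from a confusion matrix
#'
#' @param c a [confusion()] object.
#' @return Named numeric: `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP), and their complements `fn_rate`, `fp_rate`.
#' @export
class_metrics <- function(c) {
  stopifnot(inherits(c, "confusion"))
  if (c$tp + c$fn == 0 || c$tn + c$fp == 0)
    stop("empty class: cannot compute rates", call. = FALSE)
  sens <- c$tp / (c$tp + c$fn)
  spec <- c$tn / (c$tn + c$fp)
  c(sensitivity = sens, specificity = spec,
    fn_rate = 1 - sens, fp_rate = 1 - spec)
}

#' ROC curve over a threshold grid
#'
#' Sensitivity and specificity as a function of the positive-call
#' threshold under the [classify()] rule. Also reports the operating
#' threshold maximising `min(sensitivity, specificity)` — the point where
#' the two rates are high and comparable.
#'
#' @param y_true true labels (both classes must be present).
#' @param yhat continuous estimates.
#' @param thresholds numeric grid; defaults to the midpoints between
#'   sorted unique estimates, extended so that the curve reaches both
#'   all-positive and all-negative calls.
#' @return Object of class `roc_curve`: data.frame `curve` (threshold,
#'   sensitivity, specificity), `auc`, `operating_threshold`.
#' @export
roc_curve <- function(y_true, yhat, thresholds = NULL) {
  yt <- coerce_class01(y_true)
  if (length(unique(yt)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (is.null(thresholds)) {
    u <- sort(unique(yhat))
    thresholds <- c(u[1] - 1, u, if (length(u) > 1)
      (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    thresholds <- sort(unique(thresholds))
  }
  stats <- t(vapply(thresholds, function(th) {
    cm <- confusion(yt, classify(yhat, th))
    class_metrics(cm)[c("sensitivity", "specificity")]
  }, c(sensitivity = 0, specificity = 0)))
  curve <- data.frame(threshold = thresholds,
                      sensitivity = stats[, 1], specificity = stats[, 2])
  # trapezoidal AUC over (1-spec, sens)
  o <- order(1 - curve$specificity, curve$sensitivity)
  fpr <- (1 - curve$specificity)[o]; tpr <- curve$sensitivity[o]
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  op <- curve$threshold[which.max(pmin(curve$sensitivity, curve$specificity))]
  structure(list(curve = curve, auc = auc, operating_threshold = op),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC %.3f, operating threshold %.3f\n",
              nrow(x$curve), x$auc, x$operating_threshold))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(1 - x$curve$specificity, x$curve$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  invisible(x)
}
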