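# Evaluation over 10-s frames: confusion counts, derived metrics, ROC/AUC,
# intraclass correlation of per-recording spindle counts, count and density.

#' Confusion counts over labeled frames
#'
#' Positive class = spindle present (1). The four counts partition the
#' evaluated frames.
#'
#' @param actual,predicted binary 0/1 vectors of equal length.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  if (!is_binary(actual) || !is_binary(predicted))
    stop("labels must be binary 0/1", call. = FALSE)
  structure(list(tp = sum(actual == 1 & predicted == 1),
                 fp = sum(actual == 0 & predicted == 1),
                 tn = sum(actual == 0 & predicted == 0),
                 fn = sum(actual == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' Build confusion counts directly
#' @param tp,fp,tn,fn non-negative integer counts.
#' @rdname confusion
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (n = %d): TP %d  FP %d  TN %d  FN %d\n",
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Derived classification metrics
#'
#' Accuracy `(tp+tn)/n`, sensitivity (recall) `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, precision `tp/(tp+fp)`, F1 (harmonic mean of precision and
#' recall) and the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. A metric whose
#' denominator is zero is reported as 0 and listed in the `undefined`
#' attribute of the result.
#'
#' @param cc a `confusion_counts` object.
#' @return object of class `metrics_report`: named list of the six metrics,
#'   with an `undefined` character vector attribute.
#' @examples
#' metrics(confusion_counts(tp = 12541, fp = 1014, tn = 13972, fn = 492))
#' @export
metrics <- function(cc) {
  if (!inherits(cc, "confusion_counts"))
    stop("`cc` must be confusion counts", call. = FALSE)
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("no evaluated frames", call. = FALSE)
  undefined <- character()
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- safe(2 * prec * sens, prec + sens, "f1")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- safe(tp * tn - fp * fn, mcc_den, "mcc")
  structure(list(accuracy = (tp + tn) / n, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1, mcc = mcc,
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("accuracy %.*f  sensitivity %.*f  specificity %.*f\n",
              digits, x$accuracy, digits, x$sensitivity, digits, x$specificity))
  cat(sprintf("precision %.*f  F1 %.*f  MCC %.*f\n",
              digits, x$precision, digits, x$f1, digits, x$mcc))
  if (length(x$undefined))
    cat("undefined (0/0 -> 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and area under it
#'
#' Thresholds are the sorted unique scores in descending order with a
#' leading `Inf` sentinel; a frame is called positive when its score is at
#' or above the threshold. The area is the trapezoidal integral of TPR over
#' FPR and is invariant under strictly monotone transforms of the scores.
#'
#' @param scores finite numeric scores (larger = more spindle-like).
#' @param actual binary 0/1 labels, both classes present.
#' @return object of class `roc_curve`: list with `fpr`, `tpr`, `thresholds`.
#' @export
roc_curve <- function(scores, actual) {
  if (length(scores) != length(actual))
    stop("`scores` and `actual` must have equal length", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (!is_binary(actual)) stop("labels must be binary 0/1", call. = FALSE)
  np <- sum(actual == 1); nn <- sum(actual == 0)
  if (np == 0 || nn == 0) stop("both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & actual == 1) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & actual == 0) / nn, numeric(1))
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr), class = "roc_curve")
}

#' @param roc a `roc` object.
#' @rdname roc_curve
#' @export
auc <- function(roc) {
  n <- length(roc$fpr)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
                 ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Intraclass correlation of two raters' per-recording counts
#'
#' Two-way mixed-effects, consistency form, from the mean-squares
#' decomposition: with rows = recordings and k = 2 raters,
#' `ICC_single = (MSR - MSE) / (MSR + (k-1) MSE)` and
#' `ICC_average = (MSR - MSE) / MSR`.
#'
#' @param pairs numeric matrix or data frame with one row per recording and
#'   two columns (e.g. reference count, model count); at least 3 rows.
#' @return list with `icc_single`, `icc_average`, `msr`, `mse`, `n`.
#' @export
icc_counts <- function(pairs) {
  m <- as.matrix(pairs)
  if (ncol(m) != 2) stop("`pairs` must have exactly two columns", call. = FALSE)
  n <- nrow(m); k <- 2
  if (n < 3) stop("need at least 3 recordings", call. = FALSE)
  gm <- mean(m)
  if (all(m == gm)) stop("zero total variance: ICC undefined", call. = FALSE)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sse <- sum((m - gm)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  list(icc_single = (msr - mse) / (msr + (k - 1) * mse),
       icc_average = (msr - mse) / msr,
       msr = msr, mse = mse, n = n)
}

#' Spindle count and density from frame labels
#'
#' A frame counts once if it is positive on at least one channel (the frame
#' is the counting unit, union rule across channels). Density is the count
#' per hour of recording.
#'
#' @param labels integer 0/1 matrix, channels x frames (a [label_segments()]
#'   result), or a 0/1 vector of per-frame labels.
#' @return integer spindle count.
#' @export
spindle_count <- function(labels) {
  if (is.matrix(labels)) labels <- as.integer(colSums(labels) > 0)
  if (!is_binary(labels)) stop("labels must be binary 0/1", call. = FALSE)
  sum(labels == 1)
}

#' @param count spindle count.
#' @param recording_hours recording duration in hours (> 0).
#' @rdname spindle_count
#' @export
spindle_density <- function(count, recording_hours) {
  stopifnot_scalar_number(recording_hours, "recording_hours", positive = TRUE)
  count / recording_hours
}
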