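#' Segment-based classification metrics
#'
#' Computes accuracy, sensitivity, specificity and precision from a
#' confusion table, on the percent scale:
#' \deqn{Accuracy = (TN + TP) / (TN + FP + FN + TP)}
#' \deqn{Sensitivity = TP / (TP + FN), \quad
#'       Specificity = TN / (TN + FP), \quad
#'       Precision = TP / (FP + TP)}
#' A metric whose denominator is zero is reported as `NA` (undefined),
#' never as 0. All four metrics are invariant to scaling all counts by a
#' common factor.
#'
#' @param tp,tn,fp,fn nonnegative integer counts: true positives (ictal
#'   correctly recognised), true negatives, false positives, false
#'   negatives.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, in percent.
#' @examples
#' segment_metrics(tp = 96, tn = 97, fp = 3, fn = 4)
#' @export
segment_metrics <- function(tp, tn, fp, fn) {
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if (sum(counts) == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(accuracy = ratio(tn + tp, tn + fp + fn + tp),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, fp + tp))
}

#' Confusion counts from predictions and labels
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels.
#' @return Named integer vector `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred <- as.integer(pred); truth <- as.integer(truth)
  c(tp = sum(pred == 1L & truth == 1L),
    tn = sum(pred == 0L & truth == 0L),
    fp = sum(pred == 1L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L))
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive sample receives a
#' higher score than a randomly chosen negative one, with ties counted
#' one half -- the Mann-Whitney pairwise-comparison statistic, computed
#' via average ranks in O(n log n).
#'
#' @param scores numeric scores (higher = more seizure-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)                     # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Event-based seizure detection metrics
#'
#' Scores predicted seizure events against expert annotations. A
#' predicted event that overlaps an annotated `[onset, offset]` interval
#' counts that seizure as detected (any overlap; each annotated seizure
#' is counted at most once, and one predicted event spanning two
#' annotations credits both). Detection latency is the time from the
#' annotated onset to the start of the earliest overlapping prediction,
#' clamped at 0 when the prediction begins before the onset. Predicted
#' events overlapping no annotation are false alarms; the false-detection
#' rate (FDR) is false alarms per hour of test recording.
#'
#' @param pred data.frame of predicted events (`start_s`, `end_s`).
#' @param truth data.frame of annotated seizures (`start_s`, `end_s`),
#'   non-overlapping.
#' @param test_hours duration of the test recording in hours (> 0).
#' @return List of class `"event_score"`: counts (`n_seizures`,
#'   `n_detected`, `n_false_alarms`), `sensitivity_pct`, `fdr_per_h`,
#'   `latencies_s` (one per detected seizure) and `mean_latency_s`.
#' @examples
#' event_metrics(data.frame(start_s = 120, end_s = 180),
#'               data.frame(start_s = 100, end_s = 160), test_hours = 1)
#' @export
event_metrics <- function(pred, truth, test_hours) {
  pred <- as_events(pred); truth <- as_events(truth)
  if (test_hours <= 0) stop("test_hours must be positive")
  detected <- logical(nrow(truth))
  latencies <- rep(NA_real_, nrow(truth))
  pred_hit <- logical(nrow(pred))
  for (i in seq_len(nrow(truth))) {
    ov <- which(pred$start_s < truth$end_s[i] &
                  pred$end_s > truth$start_s[i])
    if (length(ov) > 0) {
      detected[i] <- TRUE
      pred_hit[ov] <- TRUE
      latencies[i] <- max(0, min(pred$start_s[ov]) - truth$start_s[i])
    }
  }
  n_fa <- sum(!pred_hit)
  structure(list(
    n_seizures = nrow(truth),
    n_detected = sum(detected),
    n_false_alarms = n_fa,
    test_hours = test_hours,
    sensitivity_pct = if (nrow(truth) == 0) NA_real_ else
      100 * sum(detected) / nrow(truth),
    fdr_per_h = n_fa / test_hours,
    latencies_s = latencies[detected],
    mean_latency_s = if (any(detected)) mean(latencies[detected]) else
      NA_real_), class = "event_score")
}

#' @export
print.event_score <- function(x, ...) {
  cat(sprintf(
    "Event-based score: %d/%d seizures detected (sensitivity %.2f%%)\n",
    x$n_detected, x$n_seizures, x$sensitivity_pct))
  cat(sprintf("  false alarms: %d over %.2f h (FDR %.2f/h)\n",
              x$n_false_alarms, x$test_hours, x$fdr_per_h))
  if (length(x$latencies_s) > 0) {
    cat(sprintf("  mean detection latency: %.2f s\n", x$mean_latency_s))
  }
  invisible(x)
}

as_events <- function(x) {
  if (is.null(x) || nrow(as.data.frame(x)) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  x <- as.data.frame(x)
  if (!all(c("start_s", "end_s") %in% names(x))) {
    stop("events need columns start_s, end_s")
  }
  if (any(x$end_s <= x$start_s)) stop("events must have end_s > start_s")
  x[order(x$start_s), c("start_s", "end_s"), drop = FALSE]
}
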