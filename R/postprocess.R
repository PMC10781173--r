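#' Post-processing of the per-epoch seizure-probability stream
#'
#' Long-term EEG classification produces one seizure probability per 4-s
#' epoch; isolated high scores would otherwise trigger spurious alarms.
#' Four stages convert the score stream into event decisions, applied in
#' this order: moving-average filtering ([moving_average()]),
#' thresholding ([apply_threshold()]), collar extension ([collar()]) and
#' K-of-N discrimination ([k_of_n()]). [postprocess_scores()] runs the
#' full chain and extracts events.
#'
#' @name postprocessing
NULL

#' Centered moving-average filter
#'
#' Smooths per-epoch scores with a centered mean over `w` epochs; at the
#' trace boundaries the window is truncated to the available epochs, so
#' the output has the same length and a constant trace is unchanged.
#'
#' @param scores numeric vector of per-epoch scores in `[0, 1]`.
#' @param w odd window width in epochs (>= 1); `w = 1` is the identity.
#' @return Smoothed numeric vector, same length.
#' @export
moving_average <- function(scores, w = 3L) {
  check_scores(scores)
  if (w < 1) stop("window width must be >= 1")
  if (w %% 2 == 0) stop("window width must be odd (centered window)")
  if (w == 1) return(scores)
  n <- length(scores)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, scores))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Threshold scores into binary decisions
#'
#' @param scores numeric vector of per-epoch scores.
#' @param threshold decision threshold in `(0, 1)`; a score exactly equal
#'   to the threshold is declared seizure (`>=` convention).
#' @return Integer 0/1 vector.
#' @export
apply_threshold <- function(scores, threshold = 0.5) {
  check_scores(scores)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  as.integer(scores >= threshold)
}

#' Collar extension of positive runs
#'
#' Extends every maximal run of 1s by `c_epochs` epochs on each side
#' (clipped at the trace bounds), protecting correctly detected seizure
#' segments from being clipped by later stages.
#'
#' @param decisions integer 0/1 vector.
#' @param c_epochs nonnegative collar width per side, in epochs.
#' @return Integer 0/1 vector, same length.
#' @export
collar <- function(decisions, c_epochs = 1L) {
  check_binary(decisions)
  if (c_epochs < 0) stop("collar width must be >= 0")
  if (c_epochs == 0 || !any(decisions == 1L)) return(as.integer(decisions))
  n <- length(decisions)
  out <- integer(n)
  r <- rle(as.integer(decisions))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values == 1L)) {
    lo <- max(1L, starts[k] - c_epochs)
    hi <- min(n, ends[k] + c_epochs)
    out[lo:hi] <- 1L
  }
  out
}

#' K-of-N discrimination
#'
#' Slides an `N`-epoch window one epoch at a time over the decision
#' trace; whenever at least `K` epochs inside the window are positive,
#' the entire window span is marked as seizure. The output is the union
#' of all triggered window spans (with 4-s epochs and `N = 10` each
#' triggered span is 40 s). The published operating point is `K = 5`,
#' `N = 10`.
#'
#' @param decisions integer 0/1 vector.
#' @param K minimum positive epochs to trigger (`1 <= K <= N`).
#' @param N window length in epochs (`N <= length(decisions)`).
#' @return Integer 0/1 vector, same length.
#' @export
k_of_n <- function(decisions, K = 5L, N = 10L) {
  check_binary(decisions)
  n <- length(decisions)
  if (K < 1 || K > N) stop("need 1 <= K <= N")
  if (N > n) stop("window N = ", N, " exceeds trace length ", n)
  counts <- as.integer(stats::filter(decisions, rep(1L, N), sides = 1L))
  out <- integer(n)
  for (s in seq_len(n - N + 1L)) {
    if (counts[s + N - 1L] >= K) out[s:(s + N - 1L)] <- 1L
  }
  out
}

#' Run the full post-processing chain and extract events
#'
#' Applies, in order, the moving-average filter, thresholding, the collar
#' and K-of-N discrimination, then converts contiguous positive runs of
#' the final trace into events with start/end times in seconds.
#'
#' @param scores numeric vector of per-epoch seizure probabilities.
#' @param maf_w moving-average window (epochs, odd).
#' @param threshold decision threshold.
#' @param collar_epochs collar width per side (epochs).
#' @param K,N K-of-N parameters.
#' @param epoch_len epoch length in seconds.
#' @param start_time time of the first epoch's start (s).
#' @return List with `decisions` (0/1 per epoch) and `events`
#'   (data.frame `start_s`, `end_s`; empty when nothing is detected).
#' @examples
#' s <- c(rep(0.05, 20), rep(0.95, 15), rep(0.05, 20))
#' postprocess_scores(s)$events
#' @export
postprocess_scores <- function(scores, maf_w = 3L, threshold = 0.5,
                               collar_epochs = 1L, K = 5L, N = 10L,
                               epoch_len = 4, start_time = 0) {
  sm <- moving_average(scores, maf_w)
  dec <- apply_threshold(sm, threshold)
  dec <- collar(dec, collar_epochs)
  dec <- k_of_n(dec, K, N)
  list(decisions = dec,
       events = decisions_to_events(dec, epoch_len, start_time))
}

#' Convert a binary epoch trace to an event table
#'
#' @param decisions integer 0/1 vector, one entry per epoch.
#' @param epoch_len epoch length (s).
#' @param start_time time of the first epoch's start (s).
#' @return data.frame with `start_s`, `end_s` (half-open intervals).
#' @export
decisions_to_events <- function(decisions, epoch_len = 4, start_time = 0) {
  check_binary(decisions)
  r <- rle(as.integer(decisions))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(start_s = start_time + (starts[keep] - 1L) * epoch_len,
             end_s = start_time + ends[keep] * epoch_len)
}

check_scores <- function(scores) {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop("scores must be finite numeric")
  }
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  invisible(TRUE)
}

check_binary <- function(x) {
  if (!all(x %in% c(0L, 1L))) stop("decision trace must be 0/1")
  invisible(TRUE)
}
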