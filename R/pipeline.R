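#' Detect seizure events in a continuous EEG record
#'
#' Runs the full detection chain on a (typically long) record: the
#' record is cut into contiguous 4-s epochs, each epoch is featurised
#' (S-transform + rhythm-band compression), scored by the fitted
#' Transformer, and the per-epoch probability stream is post-processed
#' (moving average, threshold, collar, K-of-N) into seizure events.
#'
#' @param rec an `"eeg_record"`.
#' @param model a fitted [seizure_transformer()].
#' @param scheme a [band_scheme()].
#' @param post post-processing parameters: list with `maf_w`,
#'   `threshold`, `collar_epochs`, `K`, `N`.
#' @param window_s epoch length (s).
#' @return List with `events` (data.frame `start_s`, `end_s`), `scores`
#'   (per-epoch seizure probability), `decisions` (post-processed 0/1),
#'   `times` (epoch starts, s) and `epoch_len`.
#' @examples
#' \donttest{
#' rec <- generate_eeg_record(600, n_channels = 4, n_seizures = 2, seed = 2)
#' ds <- segment_record(rec, seed = 2)
#' ft <- featurize_dataset(ds)
#' fit <- seizure_transformer(ft$maps, ft$labels,
#'                            encoder_config(n_layers = 2, max_epochs = 25))
#' det <- detect_seizures(rec, fit)
#' event_metrics(det$events, rec$annotations, rec$duration_s / 3600)
#' }
#' @export
detect_seizures <- function(rec, model, scheme = band_scheme(),
                            post = list(maf_w = 3L, threshold = 0.5,
                                        collar_epochs = 1L, K = 5L,
                                        N = 10L),
                            window_s = 4) {
  stopifnot(inherits(rec, "eeg_record"),
            inherits(model, "seizure_transformer"))
  fr <- featurize_record(rec, scheme, window_s)
  scores <- predict(model, fr$maps, type = "score")
  pp <- postprocess_scores(scores, maf_w = post$maf_w,
                           threshold = post$threshold,
                           collar_epochs = post$collar_epochs,
                           K = post$K, N = post$N,
                           epoch_len = window_s, start_time = fr$times[1])
  list(events = pp$events, scores = scores, decisions = pp$decisions,
       times = fr$times, epoch_len = window_s)
}
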