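#' Generate a synthetic annotated multichannel EEG record
#'
#' Produces a scalp-EEG-like record with the structure of the CHB-MIT
#' recordings: 23 bipolar 10--20 channels sampled at 256 Hz, long
#' interictal background with sparse ictal episodes. The background of
#' every channel is 1/f-weighted (pink) noise at a baseline RMS
#' amplitude; each ictal span adds rhythmic oscillatory activity
#' concentrated in the 3--30 Hz range (a fundamental drawn from 3--12 Hz
#' plus its first harmonic, capped below 30 Hz) whose RMS amplitude is
#' `amplitude_ratio` times the background, with slight per-channel phase
#' jitter and raised-cosine on/offset ramps. The record is fully
#' reproducible from `seed`.
#'
#' @param duration_s record duration (s).
#' @param n_channels number of channels (23 gives CHB-MIT-style bipolar
#'   names).
#' @param fs sampling rate (Hz).
#' @param n_seizures number of ictal episodes to place at random
#'   (ignored when `seizures` is supplied).
#' @param seizures optional data.frame (`start_s`, `end_s`) of ictal
#'   spans; must be non-overlapping, inside the record, durations
#'   6--120 s.
#' @param seizure_duration_s length-2 range from which random seizure
#'   durations are drawn (s).
#' @param gap_s minimum interictal gap between seizures and from the
#'   record edges (s).
#' @param background_rms baseline background amplitude (microvolts RMS).
#' @param amplitude_ratio ictal-to-background RMS amplitude ratio
#'   (>= 1; clinical ictal EEG is markedly higher-amplitude, default 3).
#' @param seed integer seed; same seed, same record, bit for bit.
#' @return An object of class `"eeg_record"`: list with `signal`
#'   (channels x samples matrix, microvolts), `fs`, `channel_names`,
#'   `annotations` (data.frame `start_s`, `end_s`) and `duration_s`.
#' @examples
#' rec <- generate_eeg_record(duration_s = 120, n_channels = 4,
#'                            n_seizures = 1, seed = 1)
#' rec$annotations
#' @export
generate_eeg_record <- function(duration_s, n_channels = 23L, fs = 256,
                                n_seizures = 0L, seizures = NULL,
                                seizure_duration_s = c(20, 80),
                                gap_s = 60,
                                background_rms = 30,
                                amplitude_ratio = 3,
                                seed = 1L) {
  stopifnot(duration_s > 0, n_channels >= 1, fs > 0, amplitude_ratio >= 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  if (is.null(seizures) && n_seizures > 0) {
    seizures <- place_seizures(duration_s, n_seizures,
                               seizure_duration_s, gap_s)
  }
  if (is.null(seizures)) {
    seizures <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  seizures <- validate_annotations(seizures, duration_s)

  n <- round(duration_s * fs)
  sig <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    sig[ch, ] <- pink_noise(n, fs) * background_rms
  }

  tt <- (seq_len(n) - 1) / fs
  for (k in seq_len(nrow(seizures))) {
    on_s <- seizures$start_s[k]; off_s <- seizures$end_s[k]
    i0 <- floor(on_s * fs) + 1L
    i1 <- min(n, ceiling(off_s * fs))
    idx <- i0:i1
    f0 <- stats::runif(1, 3, 12)
    f1 <- min(2 * f0, 28)
    env <- seizure_envelope(length(idx), fs)
    # split the target ictal RMS over fundamental and harmonic (2:1 power)
    rms_target <- amplitude_ratio * background_rms
    a0 <- sqrt(2) * rms_target * sqrt(2 / 3)
    a1 <- sqrt(2) * rms_target * sqrt(1 / 3)
    base_phase <- stats::runif(2, 0, 2 * pi)
    for (ch in seq_len(n_channels)) {
      jit <- stats::rnorm(2, 0, 0.3)
      gain <- exp(stats::rnorm(1, 0, 0.15))
      osc <- a0 * sin(2 * pi * f0 * tt[idx] + base_phase[1] + jit[1]) +
        a1 * sin(2 * pi * f1 * tt[idx] + base_phase[2] + jit[2])
      sig[ch, idx] <- sig[ch, idx] + gain * env * osc
    }
  }

  new_eeg_record(sig, fs, chbmit_channel_names(n_channels), seizures)
}

new_eeg_record <- function(signal, fs, channel_names, annotations) {
  rownames(signal) <- channel_names
  structure(list(signal = signal, fs = fs, channel_names = channel_names,
                 annotations = annotations,
                 duration_s = ncol(signal) / fs),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat("EEG record: ", nrow(x$signal), " channels x ",
      ncol(x$signal), " samples (", round(x$duration_s, 1), " s @ ",
      x$fs, " Hz), ", nrow(x$annotations), " annotated seizure(s)\n",
      sep = "")
  invisible(x)
}

# 1/f-amplitude-weighted Gaussian noise, unit RMS
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  wt <- 1 / sqrt(pmax(f, 1))                # flat below 1 Hz
  wt[1] <- 0                                # remove DC
  x <- Re(stats::fft(W * wt, inverse = TRUE)) / n
  x / stats::sd(x)
}

# raised-cosine on/off ramps, up to 2 s or 20% of the span per side
seizure_envelope <- function(len, fs) {
  ramp <- min(round(2 * fs), floor(len * 0.2))
  env <- rep(1, len)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[seq_len(ramp)] <- up
    env[(len - ramp + 1L):len] <- rev(up)
  }
  env
}

place_seizures <- function(duration_s, n_seizures, dur_range, gap_s) {
  durs <- stats::runif(n_seizures, dur_range[1], dur_range[2])
  free <- duration_s - sum(durs) - gap_s * (n_seizures + 1)
  if (free < 0) {
    stop("record too short for ", n_seizures, " seizures of ",
         dur_range[1], "-", dur_range[2], " s with ", gap_s, " s gaps")
  }
  cuts <- sort(stats::runif(n_seizures, 0, free))
  extra <- diff(c(0, cuts))
  onsets <- numeric(n_seizures)
  pos <- 0
  for (k in seq_len(n_seizures)) {
    pos <- pos + gap_s + extra[k]
    onsets[k] <- pos
    pos <- pos + durs[k]
  }
  data.frame(start_s = onsets, end_s = onsets + durs)
}

validate_annotations <- function(ann, duration_s) {
  ann <- as.data.frame(ann)
  if (nrow(ann) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  if (!all(c("start_s", "end_s") %in% names(ann))) {
    stop("annotations need columns start_s, end_s")
  }
  ann <- ann[order(ann$start_s), c("start_s", "end_s")]
  if (any(ann$end_s <= ann$start_s)) stop("annotation offset must follow onset")
  if (any(ann$start_s < 0) || any(ann$end_s > duration_s)) {
    stop("annotations fall outside the record")
  }
  if (nrow(ann) > 1 && any(ann$start_s[-1] < ann$end_s[-nrow(ann)])) {
    stop("annotations overlap")
  }
  rownames(ann) <- NULL
  ann
}

#' CHB-MIT-style bipolar channel names
#'
#' The 23 longitudinal-bipolar 10--20 derivations used in the CHB-MIT
#' montage; for other channel counts, names are recycled/extended with a
#' numeric suffix.
#'
#' @param n number of channels.
#' @return Character vector of length `n`.
#' @export
chbmit_channel_names <- function(n = 23L) {
  base <- c("FP1-F7", "F7-T7", "T7-P7", "P7-O1", "FP1-F3", "F3-C3",
            "C3-P3", "P3-O1", "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
            "FP2-F8", "F8-T8", "T8-P8", "P8-O2", "FZ-CZ", "CZ-PZ",
            "P7-T7", "T7-FT9", "FT9-FT10", "FT10-T8", "T8-P8-2")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("EXT", seq_len(n - length(base))))
}

#' Segment a record into labelled 4-s windows
#'
#' Implements the published segmentation protocol: ictal epochs are cut
#' with a 50%-overlapping sliding window (4-s windows, 2-s stride) fully
#' inside an annotated seizure; interictal epochs use non-overlapping
#' 4-s windows fully outside every annotation. Windows straddling an
#' annotation boundary are discarded. In `"balanced"` mode an equal
#' number of interictal windows is randomly subsampled (seeded) to match
#' the ictal count.
#'
#' @param rec an `"eeg_record"`.
#' @param mode `"balanced"` (equal class counts) or `"all"` (every
#'   eligible window).
#' @param window_s window length (s).
#' @param seed seed for the balanced subsample.
#' @return An object of class `"segment_dataset"`: list with `segments`
#'   (list of channels x samples matrices), `labels` (0/1), `times`
#'   (window start, s), `fs`.
#' @export
segment_record <- function(rec, mode = c("balanced", "all"),
                           window_s = 4, seed = 1L) {
  stopifnot(inherits(rec, "eeg_record"))
  mode <- match.arg(mode)
  if (rec$duration_s < window_s) stop("record shorter than one window")
  wlen <- round(window_s * rec$fs)
  ann <- rec$annotations

  ictal_starts <- numeric(0)
  for (k in seq_len(nrow(ann))) {
    if (ann$end_s[k] - ann$start_s[k] >= window_s) {
      ictal_starts <- c(ictal_starts,
                        seq(ann$start_s[k], ann$end_s[k] - window_s,
                            by = window_s / 2))
    }
  }
  all_starts <- seq(0, rec$duration_s - window_s, by = window_s)
  inter_starts <- all_starts[!vapply(all_starts, function(s) {
    any(s < ann$end_s & (s + window_s) > ann$start_s)
  }, logical(1))]

  if (length(ictal_starts) == 0) {
    warning("no complete ictal window available")
  }
  if (length(inter_starts) == 0) {
    warning("no complete interictal window available")
  }
  if (mode == "balanced" && length(ictal_starts) > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(seed)
    take <- min(length(inter_starts), length(ictal_starts))
    inter_starts <- sort(sample(inter_starts, take))
  }

  starts <- c(ictal_starts, inter_starts)
  labels <- c(rep(1L, length(ictal_starts)), rep(0L, length(inter_starts)))
  o <- order(starts)
  segs <- lapply(starts[o], function(s) extract_window(rec, s, wlen))
  structure(list(segments = segs, labels = labels[o], times = starts[o],
                 fs = rec$fs, window_s = window_s),
            class = "segment_dataset")
}

extract_window <- function(rec, start_s, wlen) {
  i0 <- round(start_s * rec$fs) + 1L
  rec$signal[, i0:(i0 + wlen - 1L), drop = FALSE]
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat("Segment dataset: ", length(x$segments), " windows of ",
      x$window_s, " s (", sum(x$labels == 1L), " ictal, ",
      sum(x$labels == 0L), " interictal)\n", sep = "")
  invisible(x)
}

#' Shuffle and split a segment dataset
#'
#' Seeded random shuffle followed by a proportional split (3:1 by
#' default, `ratio = 0.75` of the data for training). The union of the
#' two parts is exactly the input.
#'
#' @param ds a `"segment_dataset"`.
#' @param ratio fraction assigned to the training subset, in (0, 1).
#' @param seed shuffle seed.
#' @return List with elements `train` and `test`, both
#'   `"segment_dataset"` objects.
#' @export
split_train_test <- function(ds, ratio = 0.75, seed = 1L) {
  stopifnot(inherits(ds, "segment_dataset"))
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  n <- length(ds$segments)
  if (n < 2) stop("dataset too small to split")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- round(ratio * n)
  take <- function(ids) {
    structure(list(segments = ds$segments[ids], labels = ds$labels[ids],
                   times = ds$times[ids], fs = ds$fs,
                   window_s = ds$window_s), class = "segment_dataset")
  }
  list(train = take(idx[seq_len(n_train)]),
       test = take(idx[(n_train + 1L):n]))
}

#' Featurize a segment dataset
#'
#' Applies [build_feature_map()] to every window of a dataset, reusing a
#' single S-transform plan.
#'
#' @param ds a `"segment_dataset"`.
#' @param scheme a [band_scheme()].
#' @return List with `maps` (list of channels x 12 matrices), `labels`
#'   and `times`.
#' @export
featurize_dataset <- function(ds, scheme = band_scheme()) {
  stopifnot(inherits(ds, "segment_dataset"))
  if (length(ds$segments) == 0) {
    return(list(maps = list(), labels = integer(0), times = numeric(0)))
  }
  plan <- st_plan(ncol(ds$segments[[1]]), ds$fs,
                  min(scheme$bands$low), max(scheme$bands$high) - 1L)
  maps <- lapply(ds$segments, build_feature_map, fs = ds$fs,
                 scheme = scheme, plan = plan)
  list(maps = maps, labels = ds$labels, times = ds$times)
}

#' Featurize a record as a contiguous epoch stream
#'
#' Cuts the whole record into contiguous non-overlapping epochs (the
#' prediction-time protocol for long recordings) and computes the
#' feature map of each, memory-lightly (one epoch at a time).
#'
#' @param rec an `"eeg_record"`.
#' @param scheme a [band_scheme()].
#' @param window_s epoch length (s).
#' @return List with `maps`, `times` (epoch starts, s) and `epoch_len`.
#' @export
featurize_record <- function(rec, scheme = band_scheme(), window_s = 4) {
  stopifnot(inherits(rec, "eeg_record"))
  wlen <- round(window_s * rec$fs)
  starts <- seq(0, rec$duration_s - window_s, by = window_s)
  plan <- st_plan(wlen, rec$fs, min(scheme$bands$low),
                  max(scheme$bands$high) - 1L)
  maps <- lapply(starts, function(s) {
    build_feature_map(extract_window(rec, s, wlen), fs = rec$fs,
                      scheme = scheme, plan = plan)
  })
  list(maps = maps, times = starts, epoch_len = window_s)
}
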