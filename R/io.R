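#' Write an EEG record to an EDF file
#'
#' Writes a 16-bit European Data Format (EDF) file: one data record per
#' second, each channel stored as little-endian int16 with a per-channel
#' physical calibration spanning the channel's amplitude range.
#' Quantisation error is therefore at most half a physical unit step
#' (range / 65534). Annotations are not embedded; use
#' [write_annotations_csv()] for the sidecar.
#'
#' @param rec an `"eeg_record"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_record"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_rec <- floor(ncol(rec$signal) / fs)
  if (n_rec < 1) stop("record shorter than one EDF data record (1 s)")
  ns <- nrow(rec$signal)
  sig <- rec$signal[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ch <- apply(abs(sig), 1L, max)
  pmax_ch <- ifelse(pmax_ch == 0, 1, pmax_ch * 1.001)
  # calibration must survive the 8-char ASCII header field exactly
  pmax_ch <- vapply(pmax_ch, function(p) {
    for (d in 6:1) {
      s <- formatC(p, digits = d, format = "g")
      if (nchar(s) <= 7 && as.numeric(s) >= p / 1.001) {
        return(as.numeric(s))
      }
    }
    stop("channel amplitude not representable in an EDF header field")
  }, numeric(1))

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("synthetic EEG", 80), pad("stseize export", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8), pad(1, 8),
    pad(ns, 4)), con, eos = NULL)
  field <- function(vals, w) {
    writeChar(paste0(vapply(vals, pad, "", w = w), collapse = ""),
              con, eos = NULL)
  }
  field(substr(rec$channel_names, 1, 16), 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(-pmax_ch, digits = 6, format = "g"), 8)
  field(formatC(pmax_ch, digits = 6, format = "g"), 8)
  field(rep(-32767L, ns), 8)
  field(rep(32767L, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  scale <- 32767 / pmax_ch
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      writeBin(as.integer(round(sig[ch, cols] * scale[ch])), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into an EEG record
#'
#' Parses a 16-bit EDF file (equal sampling rate across channels).
#' When an annotation sidecar CSV exists (same path with `.csv`
#' extension, or given explicitly) its onset/offset rows are merged into
#' the record's annotations.
#'
#' @param path EDF file path.
#' @param annotations optional path of a sidecar annotations CSV
#'   (columns `onset_s`, `offset_s`); by default the reader looks for
#'   `path` with its extension replaced by `.csv`.
#' @param channels optional character vector: keep only these channels,
#'   in the requested order.
#' @param expect_fs if non-`NULL`, abort unless the file's sampling rate
#'   matches.
#' @return An `"eeg_record"`.
#' @export
read_edf <- function(path, annotations = NULL, channels = NULL,
                     expect_fs = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdn(16)
  rdn(80); rdn(8)
  pmin <- as.numeric(rdn(8)); pmax <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8))
  rdn(32)
  if (length(unique(spr)) != 1L) {
    stop("channels with unequal sampling rates are not supported")
  }
  fs <- spr[1] / rec_dur
  if (!is.null(expect_fs) && fs != expect_fs) {
    stop("sampling rate ", fs, " Hz, expected ", expect_fs, " Hz")
  }
  sig <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  off <- pmin - gain * dmin
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[1], size = 2L,
                     endian = "little")
      sig[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        raw * gain[ch] + off[ch]
    }
  }

  ann <- data.frame(start_s = numeric(0), end_s = numeric(0))
  sidecar <- annotations %||% sub("\\.[^.]+$", ".csv", path)
  if (file.exists(sidecar)) ann <- read_annotations_csv(sidecar)

  rec <- new_eeg_record(sig, fs, labels, ann)
  if (!is.null(channels)) {
    miss <- setdiff(channels, labels)
    if (length(miss) > 0) stop("channels not in file: ",
                               paste(miss, collapse = ", "))
    keep <- match(channels, labels)
    rec <- new_eeg_record(sig[keep, , drop = FALSE], fs, channels,
                          rec$annotations)
  }
  rec
}

#' Annotation, event and trace CSV I/O
#'
#' Annotations are stored as `onset_s`, `offset_s` columns (seconds from
#' record start, half-open intervals); predicted events as `start_s`,
#' `end_s`; score traces as one row per epoch with its index, start time
#' and score (plus decision when available).
#'
#' @param ann,events data.frames of intervals.
#' @param path file path.
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
write_annotations_csv <- function(ann, path) {
  ann <- as_events(ann)
  utils::write.csv(data.frame(onset_s = ann$start_s, offset_s = ann$end_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("onset_s", "offset_s") %in% names(df))) {
    stop("annotations CSV needs columns onset_s, offset_s")
  }
  as_events(data.frame(start_s = df$onset_s, end_s = df$offset_s))
}

#' @rdname annotation_io
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as_events(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname annotation_io
#' @export
read_events_csv <- function(path) {
  as_events(utils::read.csv(path))
}

#' @rdname annotation_io
#' @param scores per-epoch scores.
#' @param decisions optional per-epoch 0/1 decisions.
#' @param times epoch start times (s).
#' @export
write_trace_csv <- function(scores, path, times = NULL, decisions = NULL) {
  n <- length(scores)
  df <- data.frame(epoch = seq_len(n),
                   time_s = times %||% (seq_len(n) - 1) * 4,
                   score = scores)
  if (!is.null(decisions)) df$decision <- decisions
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline -- band scheme, encoder
#' hyperparameters, post-processing parameters, segmentation and split
#' settings, seeds -- into one serialisable list that round-trips
#' losslessly through YAML.
#'
#' @param ... overrides of the default entries (nested lists are
#'   replaced whole).
#' @return An object of class `"run_config"` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    fs = 256,
    window_s = 4,
    bands = list(names = c("delta", "theta", "alpha", "beta",
                           "gamma1", "gamma2"),
                 low = c(1, 4, 8, 12, 30, 40),
                 high = c(4, 8, 12, 30, 40, 50),
                 n_time_blocks = 2L),
    encoder = unclass(encoder_config()),
    post = list(maf_w = 3L, threshold = 0.5, collar_epochs = 1L,
                K = 5L, N = 10L),
    split = list(ratio = 0.75, seed = 1L),
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param cfg a `"run_config"`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' @rdname run_config
#' @export
band_scheme_from_config <- function(cfg) {
  band_scheme(data.frame(name = cfg$bands$names, low = cfg$bands$low,
                         high = cfg$bands$high),
              n_time_blocks = cfg$bands$n_time_blocks)
}

#' @rdname run_config
#' @export
encoder_config_from_config <- function(cfg) {
  do.call(encoder_config, cfg$encoder)
}

#' Save / load a fitted model checkpoint
#'
#' Serialises the parameters, configuration, normalisation statistics
#' and training history of a fitted [seizure_transformer()] to a single
#' file (R serialisation, version 2, portable across platforms).
#'
#' @param model a fitted `"seizure_transformer"`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "seizure_transformer"))
  saveRDS(unclass(model), path, version = 2)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "seizure_transformer")
}

#' Export channel-attention weights to CSV
#'
#' @param weights named numeric vector from [channel_attention()].
#' @param path output CSV (`channel`, `weight`).
#' @export
write_attention_csv <- function(weights, path) {
  utils::write.csv(data.frame(
    channel = names(weights) %||% seq_along(weights),
    weight = as.numeric(weights)), path, row.names = FALSE)
  invisible(path)
}
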