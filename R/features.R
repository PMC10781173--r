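#' EEG rhythm band scheme
#'
#' The canonical clinical sub-bands used to compress an S-transform
#' time-frequency matrix: delta (1--4 Hz), theta (4--8), alpha (8--12),
#' beta (12--30), gamma1 (30--40) and gamma2 (40--50). Boundaries are
#' half-open `[low, high)` on the integer-Hz row grid, so delta covers
#' rows 1--3, theta 4--7, ..., gamma2 40--49; the bands tile 1--50 Hz
#' with no overlap and no gap. Each band is further split into
#' `n_time_blocks` equal time blocks (2 for a 4-s epoch, i.e. 2-s halves),
#' giving 6 x 2 = 12 energy features per channel.
#'
#' @param bands data.frame with columns `name`, `low`, `high` (Hz).
#' @param n_time_blocks number of equal time divisions per band.
#' @return An object of class `"band_scheme"`.
#' @export
band_scheme <- function(bands = data.frame(
                          name = c("delta", "theta", "alpha", "beta",
                                   "gamma1", "gamma2"),
                          low  = c(1, 4, 8, 12, 30, 40),
                          high = c(4, 8, 12, 30, 40, 50)),
                        n_time_blocks = 2L) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low", "high") %in% names(bands)),
            n_time_blocks >= 1)
  if (any(bands$high <= bands$low)) stop("each band needs high > low")
  o <- order(bands$low)
  bands <- bands[o, , drop = FALSE]
  if (nrow(bands) > 1 &&
      any(bands$low[-1] != bands$high[-nrow(bands)])) {
    stop("bands must be contiguous and non-overlapping under [low, high)")
  }
  structure(list(bands = bands, n_time_blocks = as.integer(n_time_blocks)),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("Band scheme:", nrow(x$bands), "sub-bands x", x$n_time_blocks,
      "time blocks =", nrow(x$bands) * x$n_time_blocks, "features\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Compress an S-transform matrix into rhythm-block energies
#'
#' Sums the squared moduli \eqn{|S(\tau, f)|^2} of a time-frequency matrix
#' over each (sub-band x time-block) unit, producing one energy value per
#' unit. With the default scheme this yields 12 values per channel,
#' ordered band-major: delta/first half, delta/second half, theta/first
#' half, and so on. Summing all units equals the total energy over the
#' covered band -- no bin is dropped or double-counted.
#'
#' @param tf an `"st_tf"` object covering all integer rows `[low, high)`
#'   of every band in `scheme`.
#' @param scheme a [band_scheme()].
#' @return Named numeric vector of length
#'   `nrow(scheme$bands) * scheme$n_time_blocks`.
#' @export
compress_subbands <- function(tf, scheme = band_scheme()) {
  stopifnot(inherits(tf, "st_tf"))
  nb <- scheme$n_time_blocks
  nc <- ncol(tf$values)
  if (nc %% nb != 0) {
    stop("column count ", nc, " not divisible into ", nb, " time blocks")
  }
  need <- unlist(lapply(seq_len(nrow(scheme$bands)), function(i) {
    seq.int(scheme$bands$low[i], scheme$bands$high[i] - 1L)
  }))
  if (!all(need %in% tf$freqs)) {
    stop("time-frequency matrix does not cover rows ",
         min(need), "-", max(need), " Hz required by the band scheme")
  }
  p2 <- Re(tf$values)^2 + Im(tf$values)^2
  block <- nc %/% nb
  blocks <- split(seq_len(nc), rep(seq_len(nb), each = block))
  out <- numeric(0)
  for (i in seq_len(nrow(scheme$bands))) {
    rows <- match(seq.int(scheme$bands$low[i], scheme$bands$high[i] - 1L),
                  tf$freqs)
    for (b in seq_len(nb)) {
      out <- c(out, sum(p2[rows, blocks[[b]], drop = FALSE]))
    }
  }
  names(out) <- as.vector(t(outer(scheme$bands$name,
                                  paste0("t", seq_len(nb)), paste, sep = ".")))
  out
}

#' Build the channels x 12 feature map of one EEG epoch
#'
#' Runs the S-transform over 1--50 Hz on every channel of a multichannel
#' segment and compresses each channel's time-frequency matrix with
#' [compress_subbands()]; row `c` of the result is the 12-value rhythm
#' energy vector of channel `c`, channel order preserved.
#'
#' @param segment numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param scheme a [band_scheme()].
#' @param plan optional [st_plan()] for `ncol(segment)` samples over the
#'   scheme's frequency span; built on the fly if missing.
#' @return Numeric matrix channels x 12 with channel rownames.
#' @examples
#' seg <- matrix(rnorm(4 * 1024), nrow = 4)
#' dim(build_feature_map(seg, fs = 256))  # 4 x 12
#' @export
build_feature_map <- function(segment, fs, scheme = band_scheme(),
                              plan = NULL) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  stopifnot(is.matrix(segment), is.numeric(segment))
  if (!all(is.finite(segment))) stop("segment contains non-finite samples")
  fmin <- min(scheme$bands$low)
  fmax <- max(scheme$bands$high) - 1L
  if (is.null(plan)) plan <- st_plan(ncol(segment), fs, fmin, fmax)
  check_plan(plan, ncol(segment), fs, fmin, fmax)
  fm <- st_band_energies(segment, plan, scheme)
  rownames(fm) <- rownames(segment) %||%
    paste0("ch", seq_len(nrow(segment)))
  fm
}

#' Fit or apply per-feature normalisation
#'
#' Z-scores each of the 12 feature columns across all channel rows of all
#' maps, optionally after a `log10(1 + x)` transform (band energies span
#' several decades between interictal background and ictal activity, and
#' the compression keeps optimisation of the small encoder stable).
#' Fitting (`stats = NULL`) returns the training statistics for reuse on
#' held-out data; `method = "none"` is an inert identity mode.
#'
#' @param maps list of feature matrices (channels x 12), or a single one.
#' @param stats statistics from a previous fit, or `NULL` to fit.
#' @param method `"zscore"` or `"none"`.
#' @param log apply `log10(1 + x)` before z-scoring.
#' @return List with `maps` (normalised, same shape) and `stats`
#'   (`list(center, scale, method, log)`).
#' @export
normalize_features <- function(maps, stats = NULL, method = "zscore",
                               log = TRUE) {
  single <- is.matrix(maps)
  if (single) maps <- list(maps)
  method <- match.arg(method, c("zscore", "none"))
  if (!is.null(stats)) {
    method <- stats$method
    log <- stats$log
  }
  if (method == "none") {
    return(list(maps = if (single) maps[[1]] else maps,
                stats = list(method = "none", log = FALSE)))
  }
  tr <- function(m) if (log) log10(1 + m) else m
  if (is.null(stats)) {
    pooled <- do.call(rbind, lapply(maps, tr))
    center <- colMeans(pooled)
    scale <- apply(pooled, 2L, stats::sd)
    if (any(scale == 0)) {
      warning("zero-variance feature column(s); scale clamped to 1")
      scale[scale == 0] <- 1
    }
    stats <- list(center = center, scale = scale,
                  method = "zscore", log = log)
  } else {
    if (length(stats$center) != ncol(maps[[1]])) {
      stop("normalisation stats were fitted for ", length(stats$center),
           " features, maps have ", ncol(maps[[1]]))
    }
  }
  out <- lapply(maps, function(m) {
    sweep(sweep(tr(m), 2L, stats$center), 2L, stats$scale, "/")
  })
  list(maps = if (single) out[[1]] else out, stats = stats)
}

#' Write / read a feature-map dataset as CSV
#'
#' One row per (segment, channel) pair: `segment`, `channel`, `label`,
#' then the 12 feature columns. Round-trips losslessly up to numeric
#' printing precision.
#'
#' @param maps list of feature matrices (channels x 12).
#' @param labels integer vector (0/1), one per map.
#' @param path output file.
#' @export
write_features_csv <- function(maps, labels, path) {
  stopifnot(length(maps) == length(labels))
  rows <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    data.frame(segment = i, channel = rownames(m) %||%
                 paste0("ch", seq_len(nrow(m))),
               label = labels[i], m, row.names = NULL,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("segment", "channel", "label")
  if (!all(need %in% names(df))) {
    stop("feature CSV must have columns segment, channel, label")
  }
  fcols <- setdiff(names(df), need)
  ids <- unique(df$segment)
  maps <- lapply(ids, function(s) {
    sub <- df[df$segment == s, , drop = FALSE]
    m <- as.matrix(sub[, fcols, drop = FALSE])
    rownames(m) <- sub$channel
    m
  })
  labels <- vapply(ids, function(s) df$label[df$segment == s][1], numeric(1))
  list(maps = maps, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Batched rhythm-band energies of all channels of one epoch. Identical to
# compress_subbands(stockwell(channel)) row by row; the per-frequency
# voice transforms run in compiled code.
st_band_energies <- function(segment, plan, scheme) {
  n <- ncol(segment); nch <- nrow(segment); nf <- length(plan$freqs)
  nb <- scheme$n_time_blocks
  if (n %% nb != 0) {
    stop("column count ", n, " not divisible into ", nb, " time blocks")
  }
  # integer DFT-bin shift where the analysis frequency sits on a bin
  k <- plan$freqs * n / plan$fs
  shifts <- ifelse(abs(k - round(k)) < 1e-9, as.integer(round(k)), -1L)
  half <- st_half_energies_cpp(segment, plan$window_fft,
                               as.integer(shifts), plan$modulators, nb)
  aggregate_bands(half, plan$freqs, scheme, nch, nb)
}

# half: nch x (nf * nb), block index fastest; sum rows of each band
aggregate_bands <- function(half, freqs, scheme, nch, nb) {
  out <- matrix(0, nch, nrow(scheme$bands) * nb)
  for (i in seq_len(nrow(scheme$bands))) {
    fidx <- match(seq.int(scheme$bands$low[i], scheme$bands$high[i] - 1L),
                  freqs)
    if (any(is.na(fidx))) {
      stop("plan does not cover rows required by the band scheme")
    }
    for (b in seq_len(nb)) {
      cols <- (fidx - 1L) * nb + b
      out[, (i - 1L) * nb + b] <- rowSums(half[, cols, drop = FALSE])
    }
  }
  colnames(out) <- as.vector(t(outer(scheme$bands$name,
                                     paste0("t", seq_len(nb)),
                                     paste, sep = ".")))
  out
}
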