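#' Stockwell transform of an EEG segment
#'
#' The Stockwell transform (S-transform) is a time-frequency representation
#' that combines the absolutely-referenced phase of the short-time Fourier
#' transform with the frequency-dependent resolution of the wavelet
#' transform: each analysed frequency \eqn{f} uses a Gaussian window whose
#' standard deviation is \eqn{1/f} seconds. For a signal \eqn{x(t)} it is
#' \deqn{S_x(\tau, f) = \sum_t x(t)\,\frac{f}{\sqrt{2\pi}}
#'       e^{-(\tau - t)^2 f^2 / 2}\, e^{-i 2 \pi f t}\,\Delta t}
#' evaluated on the sample grid with periodic (circular) extension of the
#' window, one row per integer frequency in `[fmin, fmax]` and one column
#' per sample. A 4-s, 1024-point segment at 256 Hz analysed over 1--128 Hz
#' therefore yields a 128 x 1024 complex matrix.
#'
#' `stockwell()` is the production implementation: each frequency row is a
#' circular convolution of the modulated signal with the sampled periodised
#' Gaussian voice window, computed in the frequency domain with the FFT
#' (O(F n log n)). `stockwell_direct()` evaluates the defining double sum
#' (O(F n^2)) and serves as the brute-force oracle; the two agree to
#' machine precision because they share the same discretisation.
#'
#' The window carries the \eqn{\Delta t = 1/fs} factor, so it has (near)
#' unit mass and the transform inherits the collapse property: summing a
#' row over all time columns reproduces the unnormalised discrete Fourier
#' coefficient of the signal at that frequency.
#'
#' @param x numeric vector, the signal segment (microvolts); length >= 8,
#'   all values finite.
#' @param fs sampling rate in Hz.
#' @param fmin,fmax integer frequency band bounds in Hz;
#'   `1 <= fmin <= fmax <= fs/2`.
#' @param plan optional precomputed plan from [st_plan()]; supplying one
#'   amortises window/modulator setup across many segments.
#' @return An object of class `"st_tf"`: a list with `values` (complex
#'   matrix, frequency rows x time columns), `freqs` (Hz), `times` (s)
#'   and `fs`.
#' @examples
#' x <- cos(2 * pi * 10 * (0:255) / 256)
#' tf <- stockwell(x, fs = 256, fmin = 1, fmax = 50)
#' dim(tf$values)
#' tf$freqs[which.max(rowMeans(Mod(tf$values)))]  # 10 Hz
#' @seealso [st_plan()], [compress_subbands()]
#' @export
stockwell <- function(x, fs, fmin = 1, fmax = floor(fs / 2), plan = NULL) {
  x <- validate_segment(x, fs)
  if (is.null(plan)) {
    plan <- st_plan(length(x), fs, fmin, fmax)
  } else {
    check_plan(plan, length(x), fs, fmin, fmax)
  }
  n <- length(x)
  # modulate, transform, apply Gaussian voice window per row, invert
  xm <- x * plan$modulators              # n x F complex
  Xm <- stats::mvfft(xm)
  rows <- stats::mvfft(Xm * plan$window_fft, inverse = TRUE) / n
  new_st_tf(t(rows), plan$freqs, (seq_len(n) - 1) / fs, fs)
}

#' @rdname stockwell
#' @export
stockwell_direct <- function(x, fs, fmin = 1, fmax = floor(fs / 2)) {
  x <- validate_segment(x, fs)
  check_band(fmin, fmax, fs)
  n <- length(x)
  freqs <- seq.int(fmin, fmax)
  tt <- (seq_len(n) - 1) / fs
  vals <- matrix(0 + 0i, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    g <- st_window(n, fs, f)           # periodised Gaussian, lags 0..n-1
    xm <- x * exp(-2i * pi * f * tt)
    for (i in seq_len(n)) {
      lag <- ((i - seq_len(n)) %% n) + 1L
      vals[k, i] <- sum(xm * g[lag])
    }
  }
  new_st_tf(vals, freqs, tt, fs)
}

#' Precompute an S-transform plan
#'
#' Builds the per-frequency complex modulators and the DFTs of the sampled
#' periodised Gaussian voice windows for a fixed segment length, sampling
#' rate and frequency band, so that repeated [stockwell()] calls (e.g. when
#' featurising thousands of 4-s epochs) skip the setup cost.
#'
#' @inheritParams stockwell
#' @param n segment length in samples.
#' @return An object of class `"st_plan"`.
#' @export
st_plan <- function(n, fs, fmin = 1, fmax = floor(fs / 2)) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 8)
  check_band(fmin, fmax, fs)
  n <- as.integer(n)
  freqs <- seq.int(fmin, fmax)
  tt <- (seq_len(n) - 1) / fs
  modulators <- exp(-2i * pi * outer(tt, freqs))        # n x F
  window_fft <- vapply(freqs, function(f) stats::fft(st_window(n, fs, f)),
                       complex(n))
  structure(list(n = n, fs = fs, fmin = fmin, fmax = fmax,
                 freqs = freqs, modulators = modulators,
                 window_fft = matrix(window_fft, nrow = n)),
            class = "st_plan")
}

# Sampled periodised Gaussian voice window for frequency f, lags 0..n-1.
# Carries the dt factor so the window mass is 1 up to wrap-around terms
# below double precision.
st_window <- function(n, fs, f) {
  period <- n / fs
  lags <- (seq_len(n) - 1) / fs
  # wraps needed so the discarded tail is < exp(-700) ~ 1e-304
  nw <- ceiling(38 / (f * period)) + 1L
  g <- numeric(n)
  for (r in seq.int(-nw, nw)) {
    g <- g + exp(-((lags + r * period) * f)^2 / 2)
  }
  g * f / (sqrt(2 * pi) * fs)
}

new_st_tf <- function(values, freqs, times, fs) {
  structure(list(values = values, freqs = freqs, times = times, fs = fs),
            class = "st_tf")
}

check_band <- function(fmin, fmax, fs) {
  if (!(fmin >= 1 && fmin <= fmax)) {
    stop("need 1 <= fmin <= fmax, got fmin = ", fmin, ", fmax = ", fmax)
  }
  if (fmax > fs / 2) {
    stop("fmax = ", fmax, " Hz exceeds the Nyquist frequency ", fs / 2, " Hz")
  }
  invisible(TRUE)
}

validate_segment <- function(x, fs) {
  if (!is.numeric(x)) stop("signal must be numeric")
  if (length(x) < 8) stop("segment too short: need at least 8 samples")
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  as.double(x)
}

check_plan <- function(plan, n, fs, fmin, fmax) {
  if (!inherits(plan, "st_plan")) stop("plan must come from st_plan()")
  if (plan$n != n || plan$fs != fs || plan$fmin != fmin || plan$fmax != fmax) {
    stop("plan was built for n=", plan$n, ", fs=", plan$fs, ", band ",
         plan$fmin, "-", plan$fmax, " Hz; got n=", n, ", fs=", fs,
         ", band ", fmin, "-", fmax)
  }
  invisible(TRUE)
}

#' @export
print.st_tf <- function(x, ...) {
  cat("S-transform: ", nrow(x$values), " frequency rows (",
      min(x$freqs), "-", max(x$freqs), " Hz) x ", ncol(x$values),
      " time columns (", round(max(x$times) + x$times[2], 3),
      " s @ ", x$fs, " Hz)\n", sep = "")
  invisible(x)
}

#' Render an S-transform modulus spectrogram
#'
#' @param x an `"st_tf"` object.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.st_tf <- function(x, main = "S-transform spectrogram", ...) {
  graphics::image(x$times, x$freqs, t(Mod(x$values)),
                  xlab = "Time (s)", ylab = "Frequency (Hz)",
                  main = main, useRaster = TRUE, ...)
  invisible(x)
}
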