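# Rhythm-specific preprocessing: zero-phase Butterworth bandpass, resampling.

#' Bandpass specification
#'
#' Corner frequencies and per-pass order of a Butterworth bandpass. The
#' quality factor (center frequency over bandwidth) is derived as a
#' descriptor; the study band, high-gamma 85-145 Hz, has Q ~ 2.
#'
#' @param low_hz,high_hz corner frequencies in Hz, `0 < low < high`.
#' @param order Butterworth order per pass (the zero-phase forward-backward
#'   run doubles the effective order).
#' @return object of class `band_spec`.
#' @export
band_spec <- function(low_hz, high_hz, order = 4L) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 1)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 q_factor = (low_hz + high_hz) / 2 / (high_hz - low_hz)),
            class = "band_spec")
}

#' Clinical rhythm band registry
#'
#' Conventional EEG/ECoG rhythm bands. `high_gamma` (85-145 Hz) is the
#' study default for movement-related burst analysis.
#'
#' @return named list of [band_spec()]s.
#' @export
rhythm_bands <- function() {
  list(delta = band_spec(0.5, 4), theta = band_spec(4, 8),
       alpha = band_spec(8, 13), beta = band_spec(13, 30),
       gamma = band_spec(30, 85), high_gamma = band_spec(85, 145))
}

#' Zero-phase Butterworth bandpass
#'
#' Filters a trace (vector) or a trial ensemble (matrix, one trial per row)
#' with a forward-backward Butterworth bandpass. Zero-phase filtering is
#' essential here: event timings downstream are read at one-sample
#' resolution and must not be biased by group delay.
#'
#' @param trace numeric vector or matrix (rows = trials).
#' @param band a [band_spec()].
#' @param fs_hz sampling rate in Hz.
#' @return filtered object of the same shape and length.
#' @export
bandpass <- function(trace, band, fs_hz) {
  stopifnot(inherits(band, "band_spec"), fs_hz > 0)
  if (band$high_hz >= fs_hz / 2)
    stop(sprintf("band edge %.6g Hz is at or above Nyquist (%.6g Hz)",
                 band$high_hz, fs_hz / 2))
  nyq <- fs_hz / 2
  bf <- signal::butter(band$order, c(band$low_hz, band$high_hz) / nyq,
                       type = "pass")
  warmup <- 6L * (2L * band$order + 1L)
  run <- function(x) {
    n <- length(x)
    if (n <= warmup)
      stop(sprintf("trace of %d samples is shorter than the filter warm-up (%d samples)",
                   length(x), warmup))
    # odd-reflection padding confines start-up transients to the pad
    np <- min(n - 1L, 3L * warmup)
    xp <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
    y <- as.numeric(signal::filtfilt(bf, xp))
    y[(np + 1L):(np + n)]
  }
  if (is.matrix(trace)) t(apply(trace, 1L, run)) else run(as.numeric(trace))
}

#' Anti-aliased downsampling
#'
#' Polyphase resampling from `fs_in` to `fs_out` (must be lower) with the
#' resampler's built-in anti-alias filtering. The ratio is approximated by a
#' rational number to within 1e-9 relative error; output length is
#' approximately `length(trace) * fs_out / fs_in` (the polyphase convention
#' rounds down the trailing partial sample).
#'
#' @param trace numeric vector or matrix (rows = trials).
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return resampled object of the same shape.
#' @export
downsample <- function(trace, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  if (fs_out >= fs_in)
    stop("fs_out must be strictly below fs_in")
  pq <- rational_approx(fs_out / fs_in)
  run <- function(x) as.numeric(signal::resample(as.numeric(x), pq[1], pq[2]))
  if (is.matrix(trace)) {
    rows <- lapply(seq_len(nrow(trace)), function(i) run(trace[i, ]))
    do.call(rbind, rows)
  } else run(trace)
}

# Continued-fraction rational approximation p/q of x in (0, 1).
rational_approx <- function(x, tol = 1e-9, max_den = 1e6) {
  stopifnot(x > 0, x < 1)
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0; r <- x
  repeat {
    a <- floor(r)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) break
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    if (abs(h / k - x) < tol * x) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  c(as.integer(h1), as.integer(k1))
}
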