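#' Construct a unit-norm dictionary atom
#'
#' Low-level constructor for a burst atom: a unit l2-norm waveform of a given
#' duration. Learned cluster centers and parametric simulator atoms both pass
#' through here.
#'
#' @param waveform numeric vector; normalized to unit l2-norm.
#' @param fs_hz sampling rate in Hz.
#' @param atom_id integer index of the atom within its dictionary.
#' @param center_freq_hz optional descriptor, the dominant frequency in Hz.
#' @return object of class `burst_atom` with fields `waveform`,
#'   `duration_samples`, `atom_id`, `center_freq_hz`, `fs_hz`.
#' @export
burst_atom <- function(waveform, fs_hz, atom_id = 1L, center_freq_hz = NA_real_) {
  waveform <- as.numeric(waveform)
  stopifnot(length(waveform) >= 2L, fs_hz > 0)
  nrm <- norm2(waveform)
  if (nrm == 0) stop("atom waveform must be non-zero")
  structure(
    list(waveform = waveform / nrm,
         duration_samples = length(waveform),
         atom_id = as.integer(atom_id),
         center_freq_hz = center_freq_hz,
         fs_hz = fs_hz),
    class = "burst_atom")
}

#' Parametric amplitude-modulated burst atom
#'
#' Builds a unit-norm, amplitude-modulated sinusoid: a cosine carrier at
#' `center_freq_hz` under a Hann or Gaussian envelope. These play the role of
#' prototypical rhythm-specific micro-events (e.g. high-gamma bursts of
#' 50-100 ms) when ground truth is needed.
#'
#' The carrier phase is chosen so the waveform is (even-)symmetric about the
#' envelope peak, which sits at the atom's reference sample
#' (`floor(duration/2) + 1`); [synthesize()] aligns that sample with the
#' event timing tau.
#'
#' @param center_freq_hz carrier frequency in Hz; must be below Nyquist.
#' @param duration_s atom support in seconds.
#' @param fs_hz sampling rate in Hz.
#' @param envelope `"hann"` or `"gaussian"` amplitude envelope.
#' @param atom_id integer atom index.
#' @return a [burst_atom()].
#' @examples
#' a <- make_burst_atom(115, 0.08, 500)
#' a$duration_samples  # 40
#' sum(a$waveform^2)   # 1
#' @export
make_burst_atom <- function(center_freq_hz, duration_s, fs_hz,
                            envelope = c("hann", "gaussian"), atom_id = 1L) {
  envelope <- match.arg(envelope)
  stopifnot(duration_s > 0, fs_hz > 0, center_freq_hz > 0)
  if (center_freq_hz >= fs_hz / 2)
    stop(sprintf("center frequency %.6g Hz is at or above Nyquist (%.6g Hz)",
                 center_freq_hz, fs_hz / 2))
  n <- max(4L, round(duration_s * fs_hz))
  k <- seq_len(n)
  c0 <- atom_center_index(n)
  carrier <- cos(2 * pi * center_freq_hz * (k - c0) / fs_hz)
  env <- switch(envelope,
    hann = 0.5 * (1 - cos(2 * pi * (k - 1) / (n - 1))),
    gaussian = exp(-((k - c0)^2) / (2 * (n / 6)^2)))
  w <- env * carrier
  # oscillatory bursts carry no DC; remove envelope-induced offset
  w <- w - mean(w)
  burst_atom(w, fs_hz, atom_id = atom_id, center_freq_hz = center_freq_hz)
}

#' @export
print.burst_atom <- function(x, ...) {
  cat(sprintf("<burst_atom #%d: %d samples (%.0f ms at %g Hz)%s>\n",
              x$atom_id, x$duration_samples,
              1000 * x$duration_samples / x$fs_hz, x$fs_hz,
              if (is.finite(x$center_freq_hz))
                sprintf(", ~%g Hz carrier", x$center_freq_hz) else ""))
  invisible(x)
}
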