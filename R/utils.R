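# Internal numerical helpers shared across the pipeline.

norm2 <- function(x) sqrt(sum(x^2))

#' Analytic-signal amplitude envelope
#'
#' Magnitude of the analytic signal (Hilbert envelope) of a real sequence,
#' computed in the frequency domain.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length, the instantaneous amplitude.
#' @export
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# Centered moving average; edges use the available shorter window.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Reference index of an atom waveform: the sample that carries the event
# timestamp. Synthesis places this index at tau; encoding reads it back.
atom_center_index <- function(n) n %/% 2L + 1L

# 32-bit FNV-1a hash of a character scalar, as 8 hex digits. Used to stamp
# output files with their generating configuration.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor of the low 32 bits, done on doubles to avoid int overflow
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b)) +
      (if (h >= 2147483648) 2147483648 else 0)
    # h * 16777619 mod 2^32; 16777619 = 16777216 + 403, both exact in doubles
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed derived from a user seed and a stage label.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  off <- sum(utf8ToInt(label)) %% 1000L
  (as.integer(seed) %% 2000000000L) + off
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Exact count of per-channel hyperparameter configurations
#'
#' Number of joint model configurations when each of `n_channels` channels
#' independently picks one of `n_options` candidate settings (for example
#' candidate cluster counts), i.e. `n_options ^ n_channels`, computed in
#' exact integer arithmetic and returned as a decimal string. Fixed-K
#' clustering over an electrode grid faces exactly this combinatorial
#' explosion, which is why emergent model selection matters.
#'
#' @param n_options number of candidate settings per channel.
#' @param n_channels number of channels.
#' @return list with `count` (decimal string), `log10` (numeric), and
#'   `value` (numeric, possibly inexact for very large counts).
#' @export
config_count <- function(n_options, n_channels) {
  stopifnot(n_options >= 1, n_channels >= 0)
  # schoolbook big-integer power on base-10 digit vectors (least significant first)
  mul <- function(digits, k) {
    carry <- 0L
    out <- integer(0)
    for (d in digits) {
      v <- d * k + carry
      out <- c(out, v %% 10L)
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      out <- c(out, carry %% 10L)
      carry <- carry %/% 10L
    }
    out
  }
  digits <- 1L
  for (i in seq_len(n_channels)) digits <- mul(digits, as.integer(n_options))
  s <- paste(rev(digits), collapse = "")
  list(count = s, log10 = n_channels * log10(n_options),
       value = n_options^n_channels)
}
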