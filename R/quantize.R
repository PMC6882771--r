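# Quantized symbol representation underlying all description lengths.
#
# Sequences are min-max normalized per sequence and rounded to L levels
# (default 16, i.e. 4 bits per symbol: coarse enough that the empirical
# symbol entropy of a 40-100-sample window remains informative — see the
# methods vignette). Per-sequence normalization puts
# snippets of different durations and amplitudes on a common symbol grid so
# their description lengths are directly comparable; the scale and offset
# are retained for de-quantization.

#' Quantize a sequence to L levels
#'
#' @param x numeric vector.
#' @param L number of quantization levels (default 16).
#' @return object of class `quantized_seq`: integer `symbols` in
#'   `[0, L-1]`, `m` (length), `L`, and `offset`/`scale` such that
#'   `offset + scale * symbols` de-quantizes.
#' @examples
#' q <- quantize(seq(0, 1, length.out = 64), 64)
#' range(q$symbols)  # 0 63
#' @export
quantize <- function(x, L = 16L) {
  x <- as.numeric(x)
  L <- as.integer(L)
  stopifnot(length(x) >= 1L, L >= 2L)
  rng <- range(x)
  if (rng[2] > rng[1]) {
    scale <- (rng[2] - rng[1]) / (L - 1L)
    sym <- as.integer(round((x - rng[1]) / scale))
  } else {
    scale <- 0
    sym <- integer(length(x))
  }
  structure(list(symbols = sym, m = length(x), L = L,
                 offset = rng[1], scale = scale),
            class = "quantized_seq")
}

#' @rdname quantize
#' @param q a `quantized_seq`.
#' @export
dequantize <- function(q) {
  stopifnot(inherits(q, "quantized_seq"))
  q$offset + q$scale * q$symbols
}

# Empirical Shannon entropy (base 2) of an integer symbol vector.
symbol_entropy <- function(sym) {
  if (!length(sym)) return(0)
  counts <- tabulate(sym - min(sym) + 1L)
  p <- counts[counts > 0] / length(sym)
  -sum(p * log2(p))
}

#' Description length of a sequence
#'
#' Bit-level cost of a sequence: its length times the empirical Shannon
#' entropy (base 2) of its quantized symbols. A constant sequence costs 0
#' bits; a length-4 sequence with two symbols twice each costs 4 bits.
#'
#' @param x a `quantized_seq`, or a numeric vector (quantized first).
#' @param L quantization levels used when `x` is numeric.
#' @return description length in bits.
#' @export
description_length <- function(x, L = 16L) {
  q <- if (inherits(x, "quantized_seq")) x else quantize(x, L)
  q$m * symbol_entropy(q$symbols)
}
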