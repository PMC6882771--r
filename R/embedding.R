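# Discriminative embedding transform (DET): snippet extraction, the l2-norm
# embedding, background-null fit, and active-snippet selection.
#
# An M-snippet is the M-sample window centered at pi:
#   indices (pi - M/2 + 1) : (pi + M/2), valid for M/2 <= pi <= eta - M/2.
# Under a purely Gaussian (rest-state) trace the snippet norms beta_M follow
# a chi distribution with M degrees of freedom scaled by sigma; snippets that
# embed a burst inflate the right tail. Thresholding at
# gamma = mu_Z + gamma' * sigma_Z separates the two regimes.

#' Snippet center extraction
#'
#' Picks candidate snippet centers on a trace: first modulated patterns, as
#' local maxima of the smoothed instantaneous-amplitude envelope that rise
#' clearly above its bulk level; then regular tiling of the remaining
#' unmodulated stretches completes the set. All centers respect the window
#' bounds. `method = "tile"` skips peak detection and tiles the whole trace
#' with non-overlapping windows (the natural choice when characterising the
#' background null, since picking envelope maxima would bias the norms).
#'
#' @param x numeric trace, trial matrix (rows = trials), or
#'   `burst_ensemble`.
#' @param M even snippet length in samples.
#' @param method `"envelope"` (peaks + tiling) or `"tile"` (tiling only).
#' @param min_spacing minimum spacing between peak centers; default `M/2`.
#' @param smooth moving-average length for the envelope; default `M/2`.
#' @param peak_sd peak threshold in robust standard deviations
#'   (1.4826 MAD) above the envelope median; the robust scale keeps strong
#'   bursts from masking weaker ones.
#' @return object of class `snippet_index`: data.frame `centers` with
#'   columns `trial`, `center`, `kind` ("peak"/"tile"), plus `M`.
#' @export
extract_snippet_centers <- function(x, M, method = c("envelope", "tile"),
                                    min_spacing = M / 2, smooth = M / 2,
                                    peak_sd = 3) {
  method <- match.arg(method)
  M <- as.integer(M)
  if (M < 2L || M %% 2L != 0L) stop("M must be an even integer >= 2")
  traces <- as_trial_matrix(x)
  eta <- ncol(traces)
  if (eta <= M) stop(sprintf("trace length %d must exceed M = %d", eta, M))
  rows <- lapply(seq_len(nrow(traces)), function(tr) {
    ci <- centers_one_trace(traces[tr, ], M, method, min_spacing, smooth, peak_sd)
    if (nrow(ci)) ci$trial <- tr
    ci
  })
  centers <- do.call(rbind, rows)
  centers <- centers[, c("trial", "center", "kind")]
  structure(list(centers = centers, M = M), class = "snippet_index")
}

centers_one_trace <- function(y, M, method, min_spacing, smooth, peak_sd) {
  eta <- length(y)
  lo <- M %/% 2L
  hi <- eta - M %/% 2L
  peaks <- integer(0)
  if (method == "envelope") {
    e <- moving_average(analytic_envelope(y), smooth)
    # robust threshold: bursts inflate the mean/SD, not the median/MAD;
    # the relative floor guards the noiseless limit (median = MAD = 0)
    thr <- max(median(e) + peak_sd * 1.4826 * median(abs(e - median(e))),
               0.02 * max(e))
    n <- length(e)
    is_max <- c(FALSE, e[2:(n - 1)] > e[1:(n - 2)] & e[2:(n - 1)] >= e[3:n],
                FALSE) & e > thr
    cand <- which(is_max)
    # a genuine peak dominates its whole min_spacing neighbourhood (kills
    # carrier-ripple side maxima on burst skirts)
    cand <- cand[vapply(cand, function(p)
      e[p] >= max(e[max(1L, p - min_spacing):min(n, p + min_spacing)]),
      logical(1))]
    if (length(cand)) {
      cand <- cand[order(e[cand], decreasing = TRUE)]
      for (p in cand) {
        if (!length(peaks) || all(abs(peaks - p) >= min_spacing))
          peaks <- c(peaks, p)
      }
      peaks <- sort(pmin(pmax(peaks, lo), hi))
      peaks <- unique(peaks)
    }
  }
  tiles <- seq.int(lo, hi, by = M)
  if (length(peaks))
    tiles <- tiles[vapply(tiles, function(t) all(abs(t - peaks) >= M), logical(1))]
  data.frame(center = as.integer(c(peaks, tiles)),
             kind = rep(c("peak", "tile"), c(length(peaks), length(tiles))),
             stringsAsFactors = FALSE)
}

as_trial_matrix <- function(x) {
  if (inherits(x, "burst_ensemble")) x$traces
  else if (is.matrix(x)) x
  else matrix(as.numeric(x), nrow = 1L)
}

snippet_window <- function(center, M) (center - M %/% 2L + 1L):(center + M %/% 2L)

#' l2-norm embedding of M-snippets
#'
#' Maps every indexed snippet to its l2-norm, producing the surrogate
#' variable beta_M in which rest and active regimes separate.
#'
#' @param x trace, trial matrix, or `burst_ensemble` matching the index.
#' @param index a [extract_snippet_centers()] result.
#' @return object of class `beta_sample`: numeric `values` (one norm per
#'   snippet, all non-negative), `M`, and the center table as `provenance`.
#' @export
embed_snippets <- function(x, index) {
  stopifnot(inherits(index, "snippet_index"))
  traces <- as_trial_matrix(x)
  M <- index$M
  cen <- index$centers
  stopifnot(all(cen$trial >= 1), all(cen$trial <= nrow(traces)),
            all(cen$center >= M %/% 2L), all(cen$center <= ncol(traces) - M %/% 2L))
  vals <- vapply(seq_len(nrow(cen)), function(i) {
    norm2(traces[cen$trial[i], snippet_window(cen$center[i], M)])
  }, numeric(1))
  structure(list(values = vals, M = M, provenance = cen),
            class = "beta_sample")
}

#' Manually specified background null
#'
#' Builds a `null_fit` from known background parameters instead of fitting
#' them — useful for noiseless ground-truth ensembles (where the background
#' norm distribution is degenerate) and for replaying a stored fit.
#'
#' @param mu_zm background norm mean.
#' @param sigma_zm background norm standard deviation (> 0).
#' @param gamma_prime threshold multiplier.
#' @return object of class `null_fit`.
#' @export
null_fit <- function(mu_zm, sigma_zm, gamma_prime = 1) {
  stopifnot(sigma_zm > 0)
  structure(list(mu_zm = mu_zm, sigma_zm = sigma_zm,
                 gamma_prime = gamma_prime,
                 gamma = mu_zm + gamma_prime * sigma_zm,
                 method = "manual", n = NA_integer_),
            class = "null_fit")
}

#' Fit the background mode of the norm distribution
#'
#' Estimates the mean and standard deviation of the Gaussian describing the
#' background (rest-state) mode of beta_M, and derives the selection
#' threshold `gamma = mu + gamma_prime * sigma`. The default `"mode"`
#' method locates the dominant mode as the argmax of a kernel density
#' estimate and measures spread from the left tail only (mirrored about the
#' mode) via the median absolute deviation, since
#' active-state snippets contaminate only the right tail. `"moments"` uses
#' the plain mean and standard deviation of all norms.
#'
#' @param beta a [embed_snippets()] result, or a numeric vector of norms.
#' @param gamma_prime threshold multiplier gamma'; default 1.
#' @param method `"mode"` (tail-robust) or `"moments"`.
#' @return object of class `null_fit` with `mu_zm`, `sigma_zm`,
#'   `gamma_prime`, `gamma`.
#' @export
fit_background <- function(beta, gamma_prime = 1,
                           method = c("mode", "moments")) {
  method <- match.arg(method)
  vals <- if (inherits(beta, "beta_sample")) beta$values else as.numeric(beta)
  if (length(vals) < 50L)
    stop("need at least 50 norm values to fit the background mode")
  if (sd(vals) == 0) stop("degenerate (constant) norm sample")
  if (method == "moments") {
    mu <- mean(vals); sig <- sd(vals)
  } else {
    # KDE restricted to the bulk (heavy active-state tails would stretch
    # the grid); location = centroid of the flat top, steadier than argmax
    d <- stats::density(vals, n = 1024,
                        from = quantile(vals, 0.001),
                        to = quantile(vals, 0.95))
    top <- d$y >= 0.95 * max(d$y)
    mu <- sum(d$x[top] * d$y[top]) / sum(d$y[top])
    left <- vals[vals <= mu]
    # half-Gaussian deviations: median(|x - mu|) = 0.6745 sigma
    sig <- median(mu - left) / 0.6744898
    if (!is.finite(sig) || sig == 0) stop("left tail of the norm sample is degenerate")
  }
  structure(list(mu_zm = mu, sigma_zm = sig, gamma_prime = gamma_prime,
                 gamma = mu + gamma_prime * sig, method = method,
                 n = length(vals)),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("<null_fit (%s, n=%d): mu=%.4g sigma=%.4g gamma'=%g -> gamma=%.4g>\n",
              x$method, x$n, x$mu_zm, x$sigma_zm, x$gamma_prime, x$gamma))
  invisible(x)
}

#' Select active-state snippets
#'
#' Collects into the matrix X (one column per snippet) every M-snippet whose
#' l2-norm is at least gamma, concatenating across trials. Ties at the
#' threshold are included.
#'
#' @param x trace, trial matrix, or `burst_ensemble`.
#' @param index a [extract_snippet_centers()] result.
#' @param fit a [fit_background()] result from the same ensemble and band.
#' @return object of class `snippet_matrix`: `X` (M x Psi), `provenance`
#'   (trial, center, kind, beta per column), `M`, `gamma`.
#' @export
select_snippets <- function(x, index, fit) {
  stopifnot(inherits(index, "snippet_index"), inherits(fit, "null_fit"))
  traces <- as_trial_matrix(x)
  beta <- embed_snippets(traces, index)
  keep <- which(beta$values >= fit$gamma)
  if (!length(keep))
    warning("no snippet norm reaches gamma; returning an empty selection")
  M <- index$M
  X <- matrix(0, nrow = M, ncol = length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    X[, j] <- traces[beta$provenance$trial[i],
                     snippet_window(beta$provenance$center[i], M)]
  }
  prov <- beta$provenance[keep, , drop = FALSE]
  prov$beta <- beta$values[keep]
  rownames(prov) <- NULL
  structure(list(X = X, provenance = prov, M = M, gamma = fit$gamma, fit = fit),
            class = "snippet_matrix")
}

#' @export
print.snippet_matrix <- function(x, ...) {
  cat(sprintf("<snippet_matrix: M=%d, Psi=%d selected at gamma=%.4g>\n",
              x$M, ncol(x$X), x$gamma))
  invisible(x)
}

#' One-call discriminative embedding transform
#'
#' Convenience wrapper running center extraction, the norm embedding, the
#' background fit and snippet selection on an ensemble.
#'
#' @param x trial matrix or `burst_ensemble` (already bandpassed).
#' @param M snippet length in samples.
#' @param gamma_prime threshold multiplier.
#' @param fit_method background fit method, see [fit_background()].
#' @param ... passed to [extract_snippet_centers()].
#' @return list with `index`, `beta`, `fit`, `snippets`.
#' @export
det_transform <- function(x, M = 50L, gamma_prime = 1,
                          fit_method = "mode", ...) {
  index <- extract_snippet_centers(x, M, ...)
  beta <- embed_snippets(x, index)
  fit <- fit_background(beta, gamma_prime, method = fit_method)
  list(index = index, beta = beta, fit = fit,
       snippets = select_snippets(x, index, fit))
}
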