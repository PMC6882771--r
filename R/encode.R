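# TMPP inference: assign each selected snippet its best atom, timing and
# weight, and derive the per-trial features used downstream.

#' Encode selected snippets as a temporal marked point process
#'
#' For every selected snippet, the dictionary atom with maximal normalized
#' cross-correlation over admissible lags is chosen (one atom per
#' micro-event); the event timing tau is the trace sample onto which the
#' atom's reference sample falls at the best lag, and the weight alpha is
#' the raw inner product between the snippet segment and the unit-norm atom
#' (signed when polarity matching is on). Timing resolution is one sample
#' period; there is no sub-sample interpolation.
#'
#' @param snippets a [select_snippets()] result.
#' @param dictionary a `burst_dictionary` or list of [burst_atom()]s.
#' @param fs_hz sampling rate in Hz.
#' @param t0_s time of trace sample 1 relative to the alignment cue, in
#'   seconds.
#' @param n_trials total trials in the ensemble (zero-event trials still
#'   count for rates); defaults to the largest trial index seen.
#' @param polarity signed (sign-invariant) matching flag.
#' @return object of class `tmpp_train`: `events` data.frame (`trial`,
#'   `tau_sample`, `tau_s`, `alpha`, `atom_id`, `score`), `n_omega` counts
#'   per atom, `fs_hz`, `t0_s`, `n_trials`.
#' @export
encode <- function(snippets, dictionary, fs_hz, t0_s = 0, n_trials = NULL,
                   polarity = TRUE) {
  atoms <- dictionary_atoms(dictionary)
  if (!length(atoms)) stop("cannot encode with an empty dictionary")
  stopifnot(inherits(snippets, "snippet_matrix"), fs_hz > 0)
  X <- snippets$X
  M <- snippets$M
  prov <- snippets$provenance
  if (is.null(n_trials)) n_trials <- if (nrow(prov)) max(prov$trial) else 0L
  if (ncol(X) == 0L)
    return(new_tmpp_train(empty_events(), atoms, fs_hz, t0_s, n_trials))
  rows <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    best <- NULL
    for (a in atoms) {
      al <- align_template(X[, j], a$waveform, polarity)
      if (is.null(best) || al$score > best$al$score) best <- list(a = a, al = al)
    }
    a <- best$a; al <- best$al
    d <- a$duration_samples
    seg <- X[(al$lag + 1L):(al$lag + d), j]
    alpha <- sum(seg * a$waveform)
    tau_sample <- prov$center[j] - M %/% 2L + al$lag + atom_center_index(d)
    rows[[j]] <- data.frame(trial = prov$trial[j],
                            tau_sample = as.integer(tau_sample),
                            tau_s = t0_s + (tau_sample - 1) / fs_hz,
                            alpha = alpha, atom_id = a$atom_id,
                            score = al$score)
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$trial, ev$tau_sample), , drop = FALSE]
  rownames(ev) <- NULL
  new_tmpp_train(ev, atoms, fs_hz, t0_s, n_trials)
}

dictionary_atoms <- function(dictionary) {
  if (inherits(dictionary, "burst_dictionary")) dictionary$atoms
  else if (inherits(dictionary, "burst_atom")) list(dictionary)
  else dictionary
}

empty_events <- function() {
  data.frame(trial = integer(), tau_sample = integer(), tau_s = numeric(),
             alpha = numeric(), atom_id = integer(), score = numeric())
}

new_tmpp_train <- function(events, atoms, fs_hz, t0_s, n_trials) {
  ids <- vapply(atoms, function(a) a$atom_id, integer(1))
  n_omega <- setNames(vapply(ids, function(i) sum(events$atom_id == i),
                             integer(1)), as.character(ids))
  structure(list(events = events, n_omega = n_omega, fs_hz = fs_hz,
                 t0_s = t0_s, n_trials = as.integer(n_trials)),
            class = "tmpp_train")
}

#' @export
print.tmpp_train <- function(x, ...) {
  cat(sprintf("<tmpp_train: %d events over %d trials at %g Hz (%s)>\n",
              nrow(x$events), x$n_trials, x$fs_hz,
              paste(sprintf("atom %s: %d", names(x$n_omega), x$n_omega),
                    collapse = ", ")))
  invisible(x)
}

window_events <- function(train, window) {
  ev <- train$events
  if (is.null(window)) return(ev)
  ev[ev$tau_s >= window[1] & ev$tau_s <= window[2], , drop = FALSE]
}

#' Per-trial event rate
#'
#' Number of events whose timing falls inside the analysis window, per
#' trial. Trials without events count zero; the raster a plot would show
#' and this rate come from the same event table.
#'
#' @param train a [encode()] result.
#' @param window analysis window in seconds relative to the cue, default
#'   -0.5 to 2 s.
#' @return integer vector of length `n_trials`.
#' @export
event_rate <- function(train, window = c(-0.5, 2)) {
  stopifnot(inherits(train, "tmpp_train"))
  ev <- window_events(train, window)
  counts <- integer(train$n_trials)
  if (nrow(ev)) {
    tab <- table(factor(ev$trial, levels = seq_len(train$n_trials)))
    counts <- as.integer(tab)
  }
  counts
}

#' Per-trial mean log inter-burst interval
#'
#' Natural log of the intervals (in seconds) between consecutive events in
#' the window, averaged per trial; the log transform encourages normality.
#' Trials with fewer than two events yield `NA`.
#'
#' @inheritParams event_rate
#' @return numeric vector of length `n_trials`.
#' @export
mean_log_ibi <- function(train, window = c(-0.5, 2)) {
  stopifnot(inherits(train, "tmpp_train"))
  ev <- window_events(train, window)
  out <- rep(NA_real_, train$n_trials)
  for (tr in unique(ev$trial)) {
    taus <- sort(ev$tau_s[ev$trial == tr])
    if (length(taus) >= 2L) out[tr] <- mean(log(diff(taus)))
  }
  out
}

#' Per-trial bivariate timing/weight features
#'
#' Trial means of the event timings tau and of `log(alpha^2)` (the squared
#' weight on a log scale, sign-invariant and closer to normal). Trials
#' without events yield `NA`.
#'
#' @inheritParams event_rate
#' @return data.frame with columns `trial`, `mean_tau`,
#'   `mean_log_alpha_sq`.
#' @export
bivariate_features <- function(train, window = c(-0.5, 2)) {
  stopifnot(inherits(train, "tmpp_train"))
  ev <- window_events(train, window)
  out <- data.frame(trial = seq_len(train$n_trials),
                    mean_tau = NA_real_, mean_log_alpha_sq = NA_real_)
  for (tr in unique(ev$trial)) {
    sel <- ev$trial == tr
    out$mean_tau[tr] <- mean(ev$tau_s[sel])
    out$mean_log_alpha_sq[tr] <- mean(log(ev$alpha[sel]^2))
  }
  out
}

#' All per-trial TMPP features
#'
#' @inheritParams event_rate
#' @return data.frame with `trial`, `rate`, `mean_log_ibi`, `mean_tau`,
#'   `mean_log_alpha_sq`.
#' @export
tmpp_features <- function(train, window = c(-0.5, 2)) {
  bi <- bivariate_features(train, window)
  data.frame(trial = bi$trial,
             rate = event_rate(train, window),
             mean_log_ibi = mean_log_ibi(train, window),
             mean_tau = bi$mean_tau,
             mean_log_alpha_sq = bi$mean_log_alpha_sq)
}

#' Short-time power baseline
#'
#' Band power of an (already bandpassed) trace on 250 ms windows with 50%
#' overlap — the conventional time-frequency comparison feature.
#'
#' @param trace numeric bandpassed trace.
#' @param fs_hz sampling rate in Hz.
#' @param window_s window length in seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @param t0_s time of sample 1 relative to the cue.
#' @return data.frame with `t_s` (window centers) and `power` (mean squared
#'   amplitude per window).
#' @export
stft_power_baseline <- function(trace, fs_hz, window_s = 0.25, overlap = 0.5,
                                t0_s = 0) {
  trace <- as.numeric(trace)
  w <- max(2L, round(window_s * fs_hz))
  hop <- max(1L, round(w * (1 - overlap)))
  starts <- seq.int(1L, length(trace) - w + 1L, by = hop)
  power <- vapply(starts, function(s) mean(trace[s:(s + w - 1L)]^2), numeric(1))
  data.frame(t_s = t0_s + (starts + (w - 1) / 2 - 1) / fs_hz, power = power)
}

#' Log band power over the analysis window
#'
#' Log of the mean squared amplitude of an (already bandpassed) trace,
#' optionally restricted to the analysis window. A zero trace has no
#' defined log power and yields `NA`.
#'
#' @param trace numeric vector or trial matrix (rows = trials).
#' @param fs_hz sampling rate in Hz (needed when `window` is given).
#' @param window analysis window in seconds, or `NULL` for the whole trace.
#' @param t0_s time of sample 1 relative to the cue.
#' @return numeric scalar (vector input) or per-trial vector.
#' @export
log_band_power <- function(trace, fs_hz = NULL, window = NULL, t0_s = 0) {
  run <- function(x) {
    if (!is.null(window)) {
      stopifnot(!is.null(fs_hz))
      idx <- which(t0_s + (seq_along(x) - 1) / fs_hz >= window[1] &
                     t0_s + (seq_along(x) - 1) / fs_hz <= window[2])
      x <- x[idx]
    }
    p <- mean(x^2)
    if (p <= 0) NA_real_ else log(p)
  }
  if (is.matrix(trace)) apply(trace, 1L, run) else run(as.numeric(trace))
}
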