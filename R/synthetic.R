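# Ground-truth simulator: event plans, Gaussian background, trace synthesis.

#' Amplitude law for simulated events
#'
#' Distribution from which event amplitudes (the TMPP weights alpha) are
#' drawn. The default is lognormal: burst amplitudes are positive and
#' right-skewed, with a configurable median.
#'
#' @param dist `"lognormal"` or `"fixed"`.
#' @param median median amplitude (lognormal) or the constant value (fixed).
#' @param sdlog log-scale standard deviation for the lognormal law.
#' @return object of class `amp_law`.
#' @export
amp_law <- function(dist = c("lognormal", "fixed"), median = 1, sdlog = 0.25) {
  dist <- match.arg(dist)
  stopifnot(median > 0, sdlog >= 0)
  structure(list(dist = dist, median = median, sdlog = sdlog),
            class = "amp_law")
}

draw_amplitudes <- function(law, n) {
  switch(law$dist,
    lognormal = rlnorm(n, meanlog = log(law$median), sdlog = law$sdlog),
    fixed = rep(law$median, n))
}

#' Gaussian background model
#'
#' Parameters of the rest-state (background) component of a filtered trace:
#' i.i.d. Gaussian with mean `mu_z` and standard deviation `sigma_z`, plus an
#' independent additive sensor-noise term with standard deviation
#' `epsilon_sigma` applied after event placement.
#'
#' @param mu_z background mean.
#' @param sigma_z background standard deviation; must be positive unless the
#'   trace is explicitly noiseless (`sigma_z = 0` is allowed for ground-truth
#'   checks).
#' @param epsilon_sigma additive noise standard deviation.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(mu_z = 0, sigma_z = 1, epsilon_sigma = 0) {
  stopifnot(sigma_z >= 0, epsilon_sigma >= 0)
  structure(list(mu_z = mu_z, sigma_z = sigma_z, epsilon_sigma = epsilon_sigma),
            class = "noise_model")
}

#' Event plan container
#'
#' A table of planned events (trial, timing in samples, amplitude, atom id)
#' plus the minimum within-trial separation the plan respects. Timings are
#' 1-based sample indices of the atom's reference sample.
#'
#' @param events data.frame with columns `trial`, `tau_samples`, `alpha`,
#'   `atom_id`.
#' @param min_separation_samples minimum gap between consecutive timings
#'   within a trial.
#' @return object of class `event_plan`.
#' @export
event_plan <- function(events, min_separation_samples = 1L) {
  stopifnot(is.data.frame(events),
            all(c("trial", "tau_samples", "alpha", "atom_id") %in% names(events)),
            min_separation_samples >= 1)
  events <- events[order(events$trial, events$tau_samples), , drop = FALSE]
  rownames(events) <- NULL
  if (nrow(events) > 0) {
    gaps <- unlist(lapply(split(events$tau_samples, events$trial),
                          function(t) diff(t)), use.names = FALSE)
    if (length(gaps) && any(gaps < min_separation_samples))
      stop("event plan violates the minimum within-trial separation")
  }
  structure(list(events = events,
                 min_separation_samples = as.integer(min_separation_samples)),
            class = "event_plan")
}

#' Sample a homogeneous-rate event plan
#'
#' Draws event timings per trial from a homogeneous Poisson process of rate
#' `rate_per_s`, thinned so consecutive timings are at least
#' `min_sep_samples` apart (a burst occupies its support exclusively: one
#' atom per micro-event). Amplitudes come from `amp_law`; atom ids are drawn
#' uniformly from `atom_ids`.
#'
#' @param n_trials number of trials.
#' @param trial_len_samples samples per trial.
#' @param rate_per_s event rate per second (before thinning).
#' @param fs_hz sampling rate in Hz.
#' @param amp_law an [amp_law()].
#' @param min_sep_samples minimum separation between consecutive timings.
#' @param atom_ids candidate atom ids, sampled uniformly per event.
#' @param margin_samples keep timings in
#'   `[1 + margin, trial_len - margin]` so every atom fits inside the trial.
#' @param seed integer seed; the plan is reproducible given the seed.
#' @return an [event_plan()].
#' @export
sample_event_plan <- function(n_trials, trial_len_samples, rate_per_s, fs_hz,
                              amp_law = burstmdl::amp_law(),
                              min_sep_samples = 1L, atom_ids = 1L,
                              margin_samples = 0L, seed = NULL) {
  stopifnot(n_trials >= 1, trial_len_samples >= 1, rate_per_s >= 0,
            fs_hz > 0, min_sep_samples >= 1)
  lo <- 1L + margin_samples
  hi <- trial_len_samples - margin_samples
  if (hi < lo) stop("margin leaves no admissible timing range")
  with_seed(seed, {
    rows <- vector("list", n_trials)
    dropped <- 0L; planned <- 0L
    for (tr in seq_len(n_trials)) {
      n_ev <- rpois(1L, rate_per_s * trial_len_samples / fs_hz)
      planned <- planned + n_ev
      if (n_ev == 0L) next
      taus <- sort(round(runif(n_ev, lo, hi)))
      keep <- logical(length(taus))
      last <- -Inf
      for (i in seq_along(taus)) {
        if (taus[i] - last >= min_sep_samples) {
          keep[i] <- TRUE
          last <- taus[i]
        }
      }
      dropped <- dropped + sum(!keep)
      taus <- taus[keep]
      if (!length(taus)) next
      rows[[tr]] <- data.frame(
        trial = tr, tau_samples = as.integer(taus),
        alpha = draw_amplitudes(amp_law, length(taus)),
        atom_id = as.integer(sample(rep(atom_ids, 2L), length(taus),
                                    replace = TRUE)))
    }
    if (planned > 0 && dropped / planned > 0.25)
      warning(sprintf(
        "rate %.3g/s is hard to honour at min separation %d samples: %d of %d events thinned",
        rate_per_s, min_sep_samples, dropped, planned))
    ev <- do.call(rbind, rows)
    if (is.null(ev))
      ev <- data.frame(trial = integer(), tau_samples = integer(),
                       alpha = numeric(), atom_id = integer())
    event_plan(ev, min_sep_samples)
  })
}

#' Synthesize a ground-truth ensemble
#'
#' Renders a multi-trial, single-channel ensemble from the generative model:
#' each trial is a Gaussian background plus the sum of amplitude-weighted,
#' time-shifted unit-norm atoms named in the plan, plus independent additive
#' noise. The atom's reference sample (`floor(duration/2) + 1`) lands on the
#' planned timing. Events whose support would overhang a trial edge are
#' rejected at validation, keeping the model exact.
#'
#' @param plan an [event_plan()].
#' @param dictionary list of [burst_atom()]s indexed by their `atom_id`.
#' @param noise a [noise_model()].
#' @param n_trials,trial_len_samples,fs_hz ensemble geometry.
#' @param labels optional per-trial class labels (factor or character).
#' @param t0_s time of the first sample relative to the trial-alignment cue,
#'   in seconds (e.g. -0.5 when recording starts 0.5 s before the cue).
#' @param seed integer seed; the ensemble is bit-reproducible given the seed.
#' @return object of class `burst_ensemble` with fields `traces`
#'   (`n_trials` x `trial_len_samples` matrix), `fs_hz`, `labels`, `plan`,
#'   `dictionary`, `noise`, `t0_s`.
#' @export
synthesize <- function(plan, dictionary, noise, n_trials, trial_len_samples,
                       fs_hz, labels = NULL, t0_s = 0, seed = NULL) {
  stopifnot(inherits(plan, "event_plan"), inherits(noise, "noise_model"),
            n_trials >= 1, trial_len_samples >= 2, fs_hz > 0)
  ids <- vapply(dictionary, function(a) a$atom_id, integer(1))
  ev <- plan$events
  if (nrow(ev) > 0) {
    if (!all(ev$atom_id %in% ids))
      stop("plan references atom ids absent from the dictionary")
    if (any(ev$trial < 1 | ev$trial > n_trials))
      stop("plan references trials outside the ensemble")
    for (r in seq_len(nrow(ev))) {
      a <- dictionary[[match(ev$atom_id[r], ids)]]
      d <- a$duration_samples
      start <- ev$tau_samples[r] - (atom_center_index(d) - 1L)
      if (start < 1L || start + d - 1L > trial_len_samples)
        stop(sprintf("event %d (trial %d, tau %d) overhangs the trial edge",
                     r, ev$trial[r], ev$tau_samples[r]))
    }
  }
  traces <- with_seed(seed, {
    tr <- matrix(rnorm(n_trials * trial_len_samples, noise$mu_z, noise$sigma_z),
                 nrow = n_trials)
    if (nrow(ev) > 0) {
      for (r in seq_len(nrow(ev))) {
        a <- dictionary[[match(ev$atom_id[r], ids)]]
        d <- a$duration_samples
        start <- ev$tau_samples[r] - (atom_center_index(d) - 1L)
        idx <- start:(start + d - 1L)
        tr[ev$trial[r], idx] <- tr[ev$trial[r], idx] + ev$alpha[r] * a$waveform
      }
    }
    if (noise$epsilon_sigma > 0)
      tr <- tr + matrix(rnorm(n_trials * trial_len_samples, 0, noise$epsilon_sigma),
                        nrow = n_trials)
    tr
  })
  if (!is.null(labels)) stopifnot(length(labels) == n_trials)
  structure(list(traces = traces, fs_hz = fs_hz, labels = labels, plan = plan,
                 dictionary = dictionary, noise = noise, t0_s = t0_s),
            class = "burst_ensemble")
}

#' @export
print.burst_ensemble <- function(x, ...) {
  cat(sprintf("<burst_ensemble: %d trials x %d samples at %g Hz (%d planted events, %d atoms)>\n",
              nrow(x$traces), ncol(x$traces), x$fs_hz,
              nrow(x$plan$events), length(x$dictionary)))
  invisible(x)
}
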