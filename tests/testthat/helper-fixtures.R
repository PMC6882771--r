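# Shared fixture builders. Everything is generated in code at test time.

fs_default <- 500

# Two-atom ground-truth ensemble: one 80 ms and one 120 ms high-gamma burst
# per trial, amplitudes lognormal around the 10 dB within-burst SNR level.
two_atom_plan <- function(n_trials = 100, seed = 11) {
  set.seed(seed)
  ev <- do.call(rbind, lapply(seq_len(n_trials), function(tr) data.frame(
    trial = tr,
    tau_samples = c(250, 750) + sample(-50:50, 2),
    alpha = sqrt(10 * 40) * rlnorm(2, 0, 0.25),
    atom_id = c(1L, 2L))))
  event_plan(ev, 150)
}

two_atom_dictionary <- function(fs = fs_default) {
  list(make_burst_atom(115, 0.08, fs, atom_id = 1L),
       make_burst_atom(100, 0.12, fs, atom_id = 2L))
}

two_atom_ensemble <- function(n_trials = 100, sigma = 1, seed = 11,
                              synth_seed = 8, fs = fs_default) {
  plan <- two_atom_plan(n_trials, seed)
  synthesize(plan, two_atom_dictionary(fs), noise_model(0, sigma, 0),
             n_trials, 1000L, fs, seed = synth_seed)
}

# Independent entropy-based description length (the test-side oracle).
oracle_dl <- function(symbols) {
  p <- as.numeric(table(symbols)) / length(symbols)
  -length(symbols) * sum(p * log2(p))
}

# Independently coded textbook Wilks computation: determinant ratio with
# Bartlett's chi-squared approximation (dimension-0 test).
wilks_oracle <- function(x, labels) {
  labels <- factor(labels)
  grand <- colMeans(x)
  W <- matrix(0, ncol(x), ncol(x)); Tm <- crossprod(sweep(x, 2, grand))
  for (lv in levels(labels)) {
    xi <- x[labels == lv, , drop = FALSE]
    W <- W + crossprod(sweep(xi, 2, colMeans(xi)))
  }
  n <- nrow(x); p <- ncol(x); g <- nlevels(labels)
  wl <- det(W) / det(Tm)
  chi <- -(n - 1 - (p + g) / 2) * log(wl)
  df <- p * (g - 1)
  list(wilks = wl, chisq = chi, df = df,
       p = pchisq(chi, df, lower.tail = FALSE))
}

# Fixed 4-group, 3-feature design fixture.
fixture_design <- function() {
  set.seed(51)
  mus <- rbind(c(0, 0, 0), c(1, 0, 0.5), c(0, 1, -0.5), c(1, 1, 0.2))
  x <- do.call(rbind, lapply(1:4, function(g)
    sweep(matrix(rnorm(30 * 3), ncol = 3), 2, mus[g, ], "+")))
  list(x = x, labels = rep(letters[1:4], each = 30))
}

# Maximum |normalized cross-correlation| of a template anywhere inside a
# padded copy of a reference waveform (atom-recovery score).
atom_recovery_score <- function(learned, truth) {
  pad <- length(learned)
  burstmdl:::align_template(c(numeric(pad), truth, numeric(pad)),
                            learned, polarity = TRUE)$score
}
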