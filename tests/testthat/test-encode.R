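# TMPP inference and feature extraction.

make_noiseless_train <- function() {
  fs <- 500
  dict <- two_atom_dictionary(fs)
  plan <- two_atom_plan(20, seed = 41)
  ens <- synthesize(plan, dict, noise_model(0, 0, 0), 20, 1000, fs, seed = 42)
  idx <- extract_snippet_centers(ens$traces, 80)
  sn <- select_snippets(ens$traces, idx, null_fit(0, 0.5, 1))
  list(train = encode(sn, dict, fs_hz = fs), plan = plan, snippets = sn,
       dict = dict, fs = fs)
}

test_that("noiseless encoding recovers the plan exactly", {
  fx <- make_noiseless_train()
  tru <- fx$plan$events
  got <- fx$train$events
  expect_equal(nrow(got), nrow(tru))
  m <- merge(got, tru, by.x = c("trial", "atom_id"),
             by.y = c("trial", "atom_id"))
  expect_equal(nrow(m), nrow(tru))            # every atom label correct
  expect_true(all(m$tau_sample == m$tau_samples))
  expect_lt(max(abs(abs(m$alpha.x) - m$alpha.y)), 1e-6)
  expect_equal(sum(fx$train$n_omega), nrow(got))
})

test_that("encoding is idempotent on a noiseless reconstruction", {
  fx <- make_noiseless_train()
  ev <- fx$train$events
  plan2 <- event_plan(data.frame(trial = ev$trial, tau_samples = ev$tau_sample,
                                 alpha = abs(ev$alpha), atom_id = ev$atom_id),
                      min_separation_samples = 100)
  ens2 <- synthesize(plan2, fx$dict, noise_model(0, 0, 0), 20, 1000, fx$fs)
  idx2 <- extract_snippet_centers(ens2$traces, 80)
  sn2 <- select_snippets(ens2$traces, idx2, null_fit(0, 0.5, 1))
  tr2 <- encode(sn2, fx$dict, fs_hz = fx$fs)
  expect_equal(tr2$events$tau_sample, ev$tau_sample)
  expect_equal(tr2$events$atom_id, ev$atom_id)
  expect_equal(abs(tr2$events$alpha), abs(ev$alpha), tolerance = 1e-9)
})

test_that("alpha is the unit-norm inner product and tau sits on the sample grid", {
  fs <- 500
  a <- make_burst_atom(115, 0.08, fs, atom_id = 1L)
  x <- numeric(200)
  x[81:120] <- 3 * a$waveform
  idx <- extract_snippet_centers(x, 80)
  sn <- select_snippets(x, idx, null_fit(0, 0.1, 1))
  train <- encode(sn, list(a), fs_hz = fs)
  expect_equal(abs(train$events$alpha[1]), 3, tolerance = 1e-9)
  # timing resolution is exactly one sample period
  expect_equal(train$events$tau_s,
               (train$events$tau_sample - 1) / fs, tolerance = 1e-12)

  expect_error(encode(sn, list(), fs_hz = fs), "empty dictionary")
  empty_sn <- suppressWarnings(select_snippets(x, idx, null_fit(100, 1, 1)))
  expect_equal(nrow(encode(empty_sn, list(a), fs_hz = fs)$events), 0L)
})

fake_train <- function(taus_s, alphas = NULL, trials = NULL, n_trials = 1L,
                       fs = 500) {
  n <- length(taus_s)
  if (is.null(alphas)) alphas <- rep(1, n)
  if (is.null(trials)) trials <- rep(1L, n)
  ev <- data.frame(trial = trials,
                   tau_sample = as.integer(round(taus_s * fs) + 1L),
                   tau_s = taus_s, alpha = alphas,
                   atom_id = rep(1L, n), score = rep(1, n))
  burstmdl:::new_tmpp_train(ev, list(make_burst_atom(100, .05, fs)),
                            fs, 0, n_trials)
}

test_that("event rate counts only events inside the analysis window", {
  tr <- fake_train(c(0.1, 0.5, 1.0, 1.9, 2.5), n_trials = 2L)
  expect_equal(event_rate(tr, c(0, 2)), c(4L, 0L))
  empty <- fake_train(numeric(0), trials = integer(0), n_trials = 3L)
  expect_equal(event_rate(empty, c(0, 2)), c(0L, 0L, 0L))
  # boundary: an event just outside is excluded
  tr2 <- fake_train(c(0.5, 2.002), n_trials = 1L)
  expect_equal(event_rate(tr2, c(0, 2)), 1L)
})

test_that("mean log-IBI matches hand arithmetic and handles sparse trials", {
  tr <- fake_train(c(0.1, 0.3, 0.7))
  expect_equal(mean_log_ibi(tr, c(0, 2)), mean(log(c(0.2, 0.4))),
               tolerance = 1e-9)
  expect_equal(mean_log_ibi(tr, c(0, 2)), -1.2628643, tolerance = 1e-6)

  single <- fake_train(0.5)
  expect_true(is.na(mean_log_ibi(single, c(0, 2))))

  equal <- fake_train(seq(0.2, 1.8, by = 0.2))
  expect_equal(mean_log_ibi(equal, c(0, 2)), log(0.2), tolerance = 1e-9)
})

test_that("bivariate features are trial means with sign-invariant weights", {
  tr <- fake_train(1, alphas = 2)
  bi <- bivariate_features(tr, c(0, 2))
  expect_equal(bi$mean_tau, 1, tolerance = 1e-9)
  expect_equal(bi$mean_log_alpha_sq, log(4), tolerance = 1e-9)

  trn <- fake_train(1, alphas = -2)
  expect_equal(bivariate_features(trn, c(0, 2))$mean_log_alpha_sq, log(4),
               tolerance = 1e-9)

  # lognormal alpha: mean log alpha^2 = 2 meanlog (Monte-Carlo, 3 SE)
  set.seed(43)
  n <- 2e4
  alphas <- rlnorm(n, meanlog = 1.3, sdlog = 0.5)
  trl <- fake_train(rep(1, n), alphas = alphas)
  got <- bivariate_features(trl, c(0, 2))$mean_log_alpha_sq
  expect_lt(abs(got - 2 * 1.3), 3 * (2 * 0.5) / sqrt(n))
})

test_that("STFT power baseline localizes bursts and is flat for tones", {
  fs <- 500
  z <- stft_power_baseline(numeric(2000), fs)
  expect_true(all(z$power == 0))
  expect_lt(abs(diff(z$t_s[1:2]) - 0.125), 1 / fs)         # 50% overlap

  tone <- sin(2 * pi * 115 * (0:1999) / fs)
  p <- stft_power_baseline(tone, fs)
  expect_lt(diff(range(p$power)), 0.02 * mean(p$power) + 1e-9)
  expect_equal(mean(p$power), 0.5, tolerance = 0.01)       # tone power A^2/2

  a <- make_burst_atom(115, 0.08, fs)
  x <- numeric(2000); x[961:1000] <- 10 * a$waveform       # burst at ~1.96 s
  pb <- stft_power_baseline(x, fs)
  t_burst <- (980 - 1) / fs
  expect_lt(abs(pb$t_s[which.max(pb$power)] - t_burst), 0.25)
})

test_that("log band power scales as 2 log c and guards the zero trace", {
  set.seed(44)
  x <- rnorm(5e4)
  expect_lt(abs(log_band_power(x) - 0), 3 * sqrt(2 / length(x)))
  expect_equal(log_band_power(3 * x) - log_band_power(x), 2 * log(3),
               tolerance = 1e-9)
  expect_true(is.na(log_band_power(numeric(100))))
})
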