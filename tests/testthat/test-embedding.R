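# Discriminative embedding transform: centers, norms, background fit,
# selection.

test_that("a noiseless burst yields one envelope-peak center at the burst", {
  fs <- 500
  a <- make_burst_atom(115, 0.08, fs)
  plan <- event_plan(data.frame(trial = 1L, tau_samples = 500L, alpha = 3,
                                atom_id = 1L))
  ens <- synthesize(plan, list(a), noise_model(0, 0, 0), 1, 2000, fs)
  idx <- extract_snippet_centers(ens$traces[1, ], 50)
  peaks <- idx$centers$center[idx$centers$kind == "peak"]
  # argmax of the analytic envelope as independent oracle
  oracle <- which.max(analytic_envelope(ens$traces[1, ]))
  expect_equal(length(peaks), 1L)
  expect_lte(abs(peaks - oracle), 2)
  expect_lte(abs(peaks - 500), 2)
})

test_that("pure Gaussian traces are tiled: count ~ eta/M, centers in bounds", {
  set.seed(21)
  y <- rnorm(2000)
  idx <- extract_snippet_centers(y, 50)
  expect_lte(abs(nrow(idx$centers) - 2000 / 50), 1)
  expect_true(all(idx$centers$center >= 25 & idx$centers$center <= 1975))
  expect_error(extract_snippet_centers(rnorm(40), 50), "exceed")
  expect_error(extract_snippet_centers(rnorm(100), 49), "even")
})

test_that("the norm embedding matches the chi closed form", {
  idx0 <- structure(list(centers = data.frame(trial = 1L, center = 100L,
                                              kind = "tile"), M = 50L),
                    class = "snippet_index")
  expect_equal(embed_snippets(numeric(500), idx0)$values, 0)

  a <- make_burst_atom(115, 0.1, 500)
  x <- numeric(500)
  x[76:125] <- 2 * a$waveform
  expect_equal(embed_snippets(x, idx0)$values, 2, tolerance = 1e-12)

  # chi-M mean: sigma * sqrt(2) * Gamma((M+1)/2) / Gamma(M/2), M = 50
  set.seed(22)
  sigma <- 1.7
  n <- 1e5
  M <- 50
  X <- matrix(rnorm(n * M, 0, sigma), ncol = M)
  beta <- sqrt(rowSums(X^2))
  chi_mean <- sigma * sqrt(2) * exp(lgamma(25.5) - lgamma(25))
  chi_sd <- sigma * sqrt(M - chi_mean^2 / sigma^2)
  expect_lt(abs(mean(beta) - chi_mean), 3 * chi_sd / sqrt(n))
})

test_that("background fit recovers Gaussian parameters and resists a heavy tail", {
  set.seed(23)
  clean <- rnorm(5000, 7, 1)
  # self-consistency on a pure Gaussian: plain moments at 3 SE
  fmo <- fit_background(clean, gamma_prime = 1, method = "moments")
  expect_lt(abs(fmo$mu_zm - 7), 3 / sqrt(5000))
  expect_lt(abs(fmo$sigma_zm - 1), 3 * sqrt(1 / (2 * 5000)))
  expect_equal(fmo$gamma, fmo$mu_zm + fmo$sigma_zm)

  # tail-robust mode fit survives 10% heavy right-tail contamination
  mixed <- c(rnorm(4500, 7, 1), 7 + abs(rcauchy(500, 3, 2)))
  fm <- fit_background(mixed, gamma_prime = 1)
  expect_lt(abs(fm$mu_zm - 7) / 7, 0.10)
  expect_lt(abs(fm$sigma_zm - 1), 0.10)
  # ... where the plain fit is destroyed by the same contamination
  fbad <- fit_background(mixed, gamma_prime = 1, method = "moments")
  expect_gt(fbad$sigma_zm, 2)

  f0 <- fit_background(clean, gamma_prime = 0)
  expect_equal(f0$gamma, f0$mu_zm)

  expect_error(fit_background(rnorm(10)), "50")
  expect_error(fit_background(rep(3, 100)), "degenerate")
})

test_that("selection keeps exactly the snippets at or above gamma", {
  set.seed(24)
  ens <- two_atom_ensemble(20, seed = 31, synth_seed = 32)
  filt <- bandpass(ens$traces, band_spec(85, 145), 500)
  idx <- extract_snippet_centers(filt, 80)
  beta <- embed_snippets(filt, idx)
  fit <- fit_background(beta, gamma_prime = 1)
  sel <- select_snippets(filt, idx, fit)
  expect_true(all(sel$provenance$beta >= fit$gamma))
  expect_equal(ncol(sel$X), sum(beta$values >= fit$gamma))
  expect_equal(nrow(sel$X), 80)

  # planted bursts (alpha >> gamma) are all captured by selected snippets
  tru <- ens$plan$events
  covered <- vapply(seq_len(nrow(tru)), function(r) {
    any(sel$provenance$trial == tru$trial[r] &
          abs(sel$provenance$center - tru$tau_samples[r]) <= 40)
  }, logical(1))
  expect_true(all(covered))
})

test_that("excluded fraction rises with gamma-prime and ignores trial order", {
  set.seed(25)
  y <- matrix(rnorm(20 * 2000), nrow = 20)
  idx <- extract_snippet_centers(y, 50, method = "tile")
  beta <- embed_snippets(y, idx)
  fits <- lapply(c(0, 0.5, 1, 1.5, 2), function(g)
    fit_background(beta, gamma_prime = g, method = "moments"))
  excl <- vapply(fits, function(f) mean(beta$values < f$gamma), numeric(1))
  expect_true(all(diff(excl) >= 0))

  perm <- sample(20)
  beta_p <- embed_snippets(y[perm, ], extract_snippet_centers(y[perm, ], 50,
                                                              method = "tile"))
  expect_equal(sort(beta_p$values), sort(beta$values), tolerance = 1e-12)

  f_hi <- null_fit(max(beta$values) + 10, 1)
  expect_warning(select_snippets(y, idx, f_hi), "empty")
})

test_that("pure-background norms follow the scaled chi distribution", {
  set.seed(26)
  M <- 50
  y <- matrix(rnorm(100 * 5000, 0, 1), nrow = 100)
  idx <- extract_snippet_centers(y, M, method = "tile")
  beta <- embed_snippets(y, idx)
  expect_gte(length(beta$values), 9000)
  ks <- suppressWarnings(ks.test(beta$values^2, "pchisq", df = M))
  expect_gt(ks$p.value, 0.01)
})
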