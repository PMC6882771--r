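# Discrimination statistics: MANOVA dimension tests, silhouettes,
# timing-power correlation, randomization, detection scoring.

test_that("MANOVA dimension-0 test matches the textbook Wilks computation", {
  fx <- fixture_design()
  mv <- one_way_manova(fx$x, fx$labels)
  or <- wilks_oracle(fx$x, fx$labels)
  expect_equal(mv$dims$wilks[1], or$wilks, tolerance = 1e-8)
  expect_equal(mv$dims$chisq[1], or$chisq, tolerance = 1e-8)
  expect_equal(mv$dims$df[1], or$df)
  expect_equal(mv$dims$p_value[1], or$p, tolerance = 1e-8)
  expect_equal(nrow(mv$dims), 3L)           # dims 0, 1, 2 for 4 groups
  expect_true(all(mv$dims$p_value >= 0 & mv$dims$p_value <= 1))
  expect_lte(ncol(mv$canonical), 3L)
})

test_that("MANOVA retains the null for equal means and rejects strong signal", {
  set.seed(52)
  retained <- vapply(1:60, function(i) {
    x <- matrix(rnorm(200 * 3), ncol = 3)
    one_way_manova(x, rep(1:4, each = 50))$dims$p_value[1] > 0.05
  }, logical(1))
  expect_gte(mean(retained), 0.9)

  mus <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  x <- do.call(rbind, lapply(1:4, function(g)
    sweep(matrix(rnorm(50 * 3, 0, 0.1), ncol = 3), 2, mus[g, ], "+")))
  mv <- one_way_manova(x, rep(1:4, each = 50))
  expect_lt(tail(mv$dims$p_value, 1), 1e-4)  # highest-dimension null rejected
})

test_that("MANOVA p-values are uniform under the global null", {
  set.seed(53)
  ps <- vapply(1:500, function(i) {
    x <- matrix(rnorm(60 * 2), ncol = 2)
    one_way_manova(x, rep(1:3, each = 20))$dims$p_value[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("singular within-class covariance is ridged with a warning", {
  set.seed(54)
  x <- matrix(rnorm(20 * 30), ncol = 30)   # p >> n/class
  expect_warning(mv <- one_way_manova(x, rep(1:2, each = 10)), "ridge")
  expect_true(all(is.finite(mv$dims$p_value)))
})

test_that("silhouettes match hand arithmetic and stay within [-1, 1]", {
  pts <- c(0, 1, 10, 11)
  lab <- c("a", "a", "b", "b")
  s <- silhouette_score(pts, lab)
  expect_equal(s$a[1], 1)
  expect_equal(s$b[1], 10.5)
  expect_equal(s$s[1], 9.5 / 10.5, tolerance = 1e-9)
  expect_true(all(s$s >= -1 & s$s <= 1))

  # coincident clusters: no separability
  set.seed(55)
  x <- rnorm(40)
  sc <- silhouette_score(x, rep(c("a", "b"), 20))
  expect_lt(abs(sc$mean_silhouette), 0.15)

  ssing <- silhouette_score(c(0, 1, 5), c("a", "a", "b"))
  expect_equal(ssing$s[3], 0)               # singleton convention

  expect_error(silhouette_score(1:5, rep("a", 5)), "two classes")
})

test_that("timing-power correlation tracks planted bursts and not chance", {
  # dense bursting: ~8 events per 4 s trial, planted at known times
  fs <- 500
  a <- make_burst_atom(115, 0.08, fs, atom_id = 1L)
  plan <- suppressWarnings(
    sample_event_plan(20, 2000, 2.2, fs,
                      amp_law = amp_law("fixed", median = 20),
                      min_sep_samples = 130, margin_samples = 50,
                      seed = 56))
  ens <- synthesize(plan, list(a), noise_model(0, 1, 0), 20, 2000, fs,
                    seed = 57)
  filt <- bandpass(ens$traces, band_spec(85, 145), fs)
  ev <- plan$events
  train <- burstmdl:::new_tmpp_train(
    data.frame(trial = ev$trial, tau_sample = ev$tau_samples,
               tau_s = (ev$tau_samples - 1) / fs, alpha = ev$alpha,
               atom_id = 1L, score = 1),
    list(a), fs, 0, 20L)
  tp <- timing_power_correlation(train, filt, fs)
  expect_gt(tp$r, 0.8)

  # independence null: events shuffled away from the traces
  set.seed(58)
  rs <- replicate(30, {
    ev <- train$events
    ev$tau_sample <- sample(100:1900, nrow(ev), replace = TRUE)
    ev$trial <- sample(ev$trial)
    sh <- burstmdl:::new_tmpp_train(ev, list(a), fs, 0, train$n_trials)
    timing_power_correlation(sh, filt, fs)$r
  })
  expect_lt(abs(mean(rs)), 0.1)

  empty <- burstmdl:::new_tmpp_train(burstmdl:::empty_events(),
                                     list(a), fs, 0, 20L)
  expect_true(is.na(timing_power_correlation(empty, filt, fs)$r))
})

test_that("randomization test separates structure from exchangeable noise", {
  set.seed(59)
  x <- rbind(matrix(rnorm(60, 0, 0.5), ncol = 2),
             matrix(rnorm(60, 4, 0.5), ncol = 2))
  lab <- rep(c("a", "b"), each = 30)
  rt <- randomization_test(x, lab, "mean_silhouette", n_perm = 200, seed = 60)
  expect_gt(rt$observed, quantile(rt$null, 0.95))
  expect_length(rt$null, 200)

  # permuted-label silhouettes concentrate at or below zero
  expect_lte(median(rt$null), 0.05)

  expect_error(randomization_test(x, lab, n_perm = 0), "at least 1")
})

test_that("sample-wise detection scores match hand counts", {
  s <- sample_wise_detection(cbind(0, 10), cbind(0, 10), 20)
  expect_equal(s$TPR, 1)
  expect_equal(s$FPR, 0)

  s2 <- sample_wise_detection(NULL, cbind(0, 10), 20)
  expect_equal(s2$TPR, 0)
  expect_equal(s2$FPR, 0)

  s3 <- sample_wise_detection(cbind(5, 15), cbind(0, 10), 20)
  expect_equal(c(s3$TP, s3$FP, s3$FN, s3$TN), c(5, 5, 5, 5))
  expect_equal(s3$TPR, 0.5)
  expect_equal(s3$FPR, 0.5)
  expect_equal(s3$TP + s3$FP + s3$TN + s3$FN, 20)
})
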