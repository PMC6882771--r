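# MDL machinery: quantization, description lengths, bitsave operators,
# motif discovery, greedy learning.

test_that("quantization maps to the symbol grid and de-quantizes within bound", {
  qc <- quantize(rep(2.5, 10), 64)
  expect_true(all(qc$symbols == 0L))
  expect_equal(description_length(qc), 0)

  ramp <- seq(0, 1, length.out = 64)
  qr <- quantize(ramp, 64)
  expect_equal(sort(qr$symbols), 0:63)

  set.seed(31)
  x <- rnorm(200)
  q <- quantize(x, 64)
  expect_lte(max(abs(dequantize(q) - x)), diff(range(x)) / (2 * 63) + 1e-12)
  expect_true(all(q$symbols >= 0 & q$symbols <= 63))
})

test_that("description length equals length times empirical entropy", {
  # hand cases: 0, 4, 16 bits
  expect_equal(description_length(quantize(rep(1, 7), 64)), 0)
  q4 <- structure(list(symbols = c(0L, 1L, 0L, 1L), m = 4L, L = 64L,
                       offset = 0, scale = 1), class = "quantized_seq")
  expect_equal(description_length(q4), 4)
  q16 <- structure(list(symbols = rep(0:3, 2), m = 8L, L = 64L,
                        offset = 0, scale = 1), class = "quantized_seq")
  expect_equal(description_length(q16), 16)

  # independent entropy oracle on random sequences
  set.seed(32)
  for (i in 1:100) {
    q <- quantize(rnorm(sample(10:80, 1)), sample(c(4L, 16L, 64L), 1))
    expect_equal(description_length(q), oracle_dl(q$symbols), tolerance = 1e-9)
  }
})

test_that("conditional description length is zero for copies and shifts", {
  set.seed(33)
  h <- make_burst_atom(115, 0.08, 500)$waveform
  expect_equal(conditional_dl(h, h)$bits, 0)
  expect_equal(conditional_dl(3 * h, h)$bits, 0)   # scale-invariant symbols

  A <- c(numeric(17), h, numeric(23))
  cd <- conditional_dl(A, h)
  expect_equal(cd$bits, 0)
  expect_equal(cd$lag, 17L)

  cdn <- conditional_dl(-A, h)
  expect_equal(cdn$bits, 0)
  expect_equal(cdn$sign, -1)

  expect_error(conditional_dl(h[1:10], h), "admissible")
})

test_that("unrelated noise is not compressible: DL(A|H) ~ DL(A)", {
  set.seed(34)
  ratios <- replicate(300, {
    A <- rnorm(50); H <- rnorm(50)
    conditional_dl(A, H)$bits / description_length(A)
  })
  expect_gt(mean(ratios), 0.95)
})

test_that("cluster description length follows the discounted-sum formula", {
  h <- make_burst_atom(100, 0.1, 500)$waveform
  C2 <- mdl_cluster(h, list(h, h))
  expect_equal(cluster_dl(C2), description_length(h))

  C1 <- mdl_cluster(h, list(2 * h))
  expect_equal(cluster_dl(C1), description_length(h))

  expect_error(cluster_dl(mdl_cluster(h, list())), "no members")

  # small hand instance: every term enumerated independently
  A1 <- c(0, 1, 2, 3, 3, 2, 1, 0)
  A2 <- c(0, 1, 2, 3, 3, 2, 1, 1)
  A3 <- c(3, 2, 1, 0, 0, 1, 2, 3)
  H <- c(0, 1, 2, 3, 3, 2, 1, 0)
  C <- mdl_cluster(H, list(A1, A2, A3))
  L <- 4L
  bits_of <- function(A) {
    al <- burstmdl:::align_template(A, C$center, TRUE)
    qa <- quantize(A, L)$symbols
    qh <- quantize(C$center, L)$symbols
    if (al$sign < 0) qh <- (L - 1L) - qh
    oracle_dl(qa - qh) # same length: lag 0
  }
  bits <- vapply(list(A1, A2, A3), bits_of, numeric(1))
  expected <- oracle_dl(quantize(C$center, L)$symbols) + sum(bits)
  expect_equal(cluster_dl(C, L = L), expected, tolerance = 1e-9)
})

test_that("bitsave operators obey their identities", {
  set.seed(35)
  h <- make_burst_atom(115, 0.08, 500)$waveform
  A <- 2 * h + 0  # non-constant structured sequence

  cr <- bitsave_create(A, A)
  expect_equal(cr$bs, description_length(A))
  expect_gt(cr$bs, 0)
  expect_equal(sum(cr$cluster$center^2), 1, tolerance = 1e-9)

  # polarity symmetry: A and -A create the same savings
  cr_neg <- bitsave_create(A, -A)
  expect_equal(cr_neg$bs, cr$bs)

  # adding a copy of the center of a two-identical-member cluster
  C <- mdl_cluster(h, list(h, h))
  ad <- bitsave_add(h, C)
  expect_equal(ad$bs, description_length(h))

  # merging identical clusters compresses duplicate structure
  C1 <- mdl_cluster(h, list(h, h))
  C2 <- mdl_cluster(h, list(h, h))
  mg <- bitsave_merge(C1, C2)
  expect_gt(mg$bs, 0)
  expect_equal(sum(mg$cluster$center^2), 1, tolerance = 1e-9)
})

test_that("independent noise resists creation and structured clusters reject it", {
  set.seed(36)
  bs_noise <- replicate(400, bitsave_create(rnorm(50), rnorm(50))$bs)
  expect_lte(mean(bs_noise > 0), 0.05)

  h <- make_burst_atom(100, 0.12, 500)$waveform
  C <- mdl_cluster(h, list(h + rnorm(60, 0, 0.02), h + rnorm(60, 0, 0.02)))
  bs_add <- replicate(1000, bitsave_add(rnorm(60), C)$bs)
  expect_gt(mean(bs_add < 0), 0.95)
})

test_that("merging clusters of different ground-truth atoms is rejected", {
  set.seed(37)
  a1 <- make_burst_atom(115, 0.08, 500)$waveform
  a2 <- make_burst_atom(100, 0.12, 500)$waveform[11:50]
  neg <- 0L
  for (i in 1:50) {
    m1 <- lapply(1:4, function(i) a1 * 3 + rnorm(40, 0, 0.05))
    m2 <- lapply(1:4, function(i) a2 * 3 + rnorm(40, 0, 0.05))
    C1 <- burstmdl:::refresh_center(mdl_cluster(a1, m1))
    C2 <- burstmdl:::refresh_center(mdl_cluster(a2, m2))
    if (bitsave_merge(C1, C2)$bs < 0) neg <- neg + 1L
  }
  expect_gt(neg / 50, 0.9)
})

test_that("motif search finds planted pairs and agrees with brute force", {
  set.seed(38)
  h <- make_burst_atom(115, 0.08, 500)$waveform
  X <- matrix(rnorm(60 * 6, 0, 0.05), nrow = 60)
  X[6:45, 2] <- X[6:45, 2] + 3 * h
  X[11:50, 5] <- X[11:50, 5] + 3 * h
  mot <- find_motifs(X, 40, top_k = 1)
  expect_equal(c(mot$i, mot$j), c(2L, 5L))
  expect_gt(mot$score, 0.95)

  # brute-force over all pairs on 3 snippets
  X3 <- matrix(rnorm(30 * 3), nrow = 30)
  got <- find_motifs(X3, 12, top_k = 1)
  brute <- expand.grid(i = 1:3, j = 1:3)
  brute <- brute[brute$i < brute$j, ]
  brute$score <- vapply(seq_len(nrow(brute)), function(r) {
    c0 <- (30 - 12) %/% 2 + 1
    max(vapply(c(
      list(c(brute$i[r], brute$j[r])), list(c(brute$j[r], brute$i[r]))),
      function(pr) {
        v <- X3[c0:(c0 + 11), pr[1]]
        max(vapply(1:(30 - 12 + 1), function(s) {
          w <- X3[s:(s + 11), pr[2]]
          abs(sum(v * w) / sqrt(sum(v^2) * sum(w^2)))
        }, numeric(1)))
      }, numeric(1)))
  }, numeric(1))
  best <- brute[which.max(brute$score), ]
  expect_equal(c(got$i, got$j), c(best$i, best$j))
  expect_equal(got$score, best$score, tolerance = 1e-9)

  expect_error(find_motifs(matrix(0, 30, 1), 10), "two snippets")
})

test_that("a single generator yields one cluster matching the true atom", {
  set.seed(39)
  h <- make_burst_atom(110, 0.12, 500)$waveform  # 60 samples
  X <- vapply(1:40, function(i) {
    lag <- sample(0:20, 1)
    x <- numeric(80)
    x[(lag + 1):(lag + 60)] <- h * runif(1, 2, 4)
    x
  }, numeric(80))
  cfg <- learn_config(delta_grid = c(50, 60, 70), M = 80, seed = 1)
  fit <- learn_dictionary(X, cfg, fs_hz = 500)
  expect_equal(fit$K, 1L)
  expect_gt(atom_recovery_score(fit$atoms[[1]]$waveform, h), 0.99)
  # all applied operators saved bits; encoded DL strictly decreasing
  expect_true(all(fit$learn_log$bitsave > 0))
  expect_true(all(vapply(fit$atoms, function(a) a$duration_samples,
                         integer(1)) <= 80))

  # deterministic rerun: identical operator log
  fit2 <- learn_dictionary(X, cfg, fs_hz = 500)
  expect_identical(fit$learn_log, fit2$learn_log)
})

test_that("pure-noise snippets do not produce spurious structure", {
  set.seed(40)
  X <- matrix(rnorm(50 * 30), nrow = 50)
  cfg <- learn_config(delta_grid = c(30, 40), M = 50, motif_top_k = 2)
  fit <- learn_dictionary(X, cfg)
  # no cluster encodes more than a token fraction of the noise snippets
  expect_lte(nrow(fit$assignments), 8)

  expect_warning(learn_dictionary(matrix(0, 50, 0), cfg), "empty")
})
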