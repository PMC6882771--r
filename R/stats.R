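# Evaluation battery: one-way MANOVA dimension tests with canonical
# projections, silhouettes, timing-power correlation, label-shuffle
# randomization, and sample-wise detection scoring.

#' Assemble a labelled design matrix
#'
#' Binds per-trial feature columns with class labels and imputes missing
#' values (e.g. the inter-burst interval of a trial with fewer than two
#' events) with the class-wise mean, falling back to the overall mean when
#' a whole class is missing.
#'
#' @param features data.frame or matrix of per-trial features (a `trial`
#'   column, if present, is dropped).
#' @param labels per-trial class labels; at least two classes.
#' @param impute impute missing values with class-wise means.
#' @return object of class `design_matrix` with `x` (numeric matrix) and
#'   `labels` (factor).
#' @export
build_design <- function(features, labels, impute = TRUE) {
  x <- as.data.frame(features)
  x$trial <- NULL
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- factor(labels)
  stopifnot(nrow(x) == length(labels), nlevels(labels) >= 2L)
  if (impute && anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      if (!anyNA(x[, j])) next
      for (lv in levels(labels)) {
        sel <- labels == lv
        miss <- sel & is.na(x[, j])
        if (any(miss)) {
          fill <- mean(x[sel, j], na.rm = TRUE)
          if (!is.finite(fill)) fill <- mean(x[, j], na.rm = TRUE)
          x[miss, j] <- fill
        }
      }
    }
  }
  structure(list(x = x, labels = labels), class = "design_matrix")
}

as_design <- function(x, labels = NULL) {
  if (inherits(x, "design_matrix")) x else build_design(x, labels)
}

#' One-way MANOVA with sequential dimension tests
#'
#' Tests, for each dimension d = 0, 1, ..., the null hypothesis that the
#' class multivariate means lie in a d-dimensional affine subspace (d = 0:
#' all means equal; with four classes the largest testable null is the
#' 3-dimensional hyperplane). Wilks' lambda for each d is formed from the
#' eigenvalues of `W^-1 B` (within- and between-class SSCP matrices) and
#' referred to Bartlett's chi-squared approximation. Canonical variates —
#' the linear projections maximizing between-class Mahalanobis separation,
#' scaled to unit within-class variance — and the projected coordinates are
#' returned for plotting.
#'
#' A singular within-class covariance (more feature dimensions than trials
#' per class) is regularized by a small ridge, with a warning.
#'
#' @param x `design_matrix`, or feature matrix/data.frame.
#' @param labels class labels when `x` is not a `design_matrix`.
#' @param ridge relative ridge applied to `W` only when it is singular.
#' @return object of class `manova_result`: `dims` data.frame (`dim`,
#'   `wilks`, `chisq`, `df`, `p_value`), `eigenvalues`, `canonical`
#'   (p x s projection matrix), `coords` (n x s projected data).
#' @export
one_way_manova <- function(x, labels = NULL, ridge = 1e-8) {
  des <- as_design(x, labels)
  x <- des$x; labels <- des$labels
  n <- nrow(x); p <- ncol(x); g <- nlevels(labels)
  stopifnot(n > g)
  grand <- colMeans(x)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lv in levels(labels)) {
    xi <- x[labels == lv, , drop = FALSE]
    ni <- nrow(xi)
    mi <- colMeans(xi)
    xc <- sweep(xi, 2L, mi)
    W <- W + crossprod(xc)
    B <- B + ni * tcrossprod(mi - grand)
  }
  if (rcond_sym(W) < 1e-12) {
    warning("within-class covariance is singular; applying a small ridge")
    W <- W + diag(ridge * sum(diag(W)) / p, p)
  }
  s <- min(p, g - 1L)
  eg <- eigen(solve(W, B), only.values = FALSE)
  ord <- order(-Re(eg$values))
  lambda <- pmax(Re(eg$values)[ord], 0)[seq_len(s)]
  A <- Re(eg$vectors)[, ord[seq_len(s)], drop = FALSE]
  # scale canonical vectors to unit pooled within-class variance
  for (k in seq_len(s)) {
    v <- sqrt(drop(crossprod(A[, k], W %*% A[, k])) / (n - g))
    if (v > 0) A[, k] <- A[, k] / v
  }
  dims <- data.frame(dim = 0:(s - 1L), wilks = NA_real_, chisq = NA_real_,
                     df = NA_real_, p_value = NA_real_)
  for (d in 0:(s - 1L)) {
    lam <- lambda[(d + 1L):s]
    wl <- prod(1 / (1 + lam))
    chi <- -(n - 1 - (p + g) / 2) * log(wl)
    df <- (p - d) * (g - 1L - d)
    dims[d + 1L, c("wilks", "chisq", "df", "p_value")] <-
      c(wl, chi, df, pchisq(chi, df, lower.tail = FALSE))
  }
  coords <- sweep(x, 2L, grand) %*% A
  structure(list(dims = dims, eigenvalues = lambda, canonical = A,
                 coords = coords, labels = labels, n = n, p = p, g = g),
            class = "manova_result")
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("<one-way MANOVA: n=%d, p=%d, %d classes>\n", x$n, x$p, x$g))
  print(x$dims, row.names = FALSE)
  invisible(x)
}

#' Silhouette separability
#'
#' Per-point silhouette `S_i = (b_i - a_i) / max(a_i, b_i)` where `a_i` is
#' the mean Euclidean distance from point i to the other members of its own
#' class and `b_i` the smallest mean distance to the points of any other
#' class. Values lie in `[-1, 1]`; singleton-class points score 0 by
#' convention.
#'
#' @param x numeric matrix (rows = points) or vector.
#' @param labels class labels, at least two classes.
#' @return object of class `silhouette_result`: `s`, `a`, `b`,
#'   `mean_silhouette`.
#' @export
silhouette_score <- function(x, labels) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("silhouette needs at least two classes")
  n <- nrow(x)
  stopifnot(length(labels) == n)
  D <- as.matrix(dist(x))
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { a[i] <- NA; b[i] <- NA; s[i] <- 0; next }
    a[i] <- sum(D[i, own]) / n_own
    b[i] <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                       function(lv) mean(D[i, labels == lv]), numeric(1)))
    mx <- max(a[i], b[i])
    s[i] <- if (mx > 0) (b[i] - a[i]) / mx else 0
  }
  structure(list(s = s, a = a, b = b, mean_silhouette = mean(s),
                 labels = labels),
            class = "silhouette_result")
}

#' @export
print.silhouette_result <- function(x, ...) {
  cat(sprintf("<silhouette: n=%d, mean S=%.4f>\n", length(x$s),
              x$mean_silhouette))
  invisible(x)
}

#' Correlation between event timing density and modulated power
#'
#' Pearson correlation between the running event count (sliding windows
#' over the timings tau) and the running variance of the bandpassed trace,
#' pooled over trials. Window length defaults to 250 ms with 50% hop,
#' mirroring the spectrogram convention.
#'
#' @param train a [encode()] result.
#' @param traces bandpassed trial matrix (rows = trials) the train was
#'   encoded from.
#' @param fs_hz sampling rate in Hz.
#' @param window_s sliding window length in seconds.
#' @return list with `r` (Pearson coefficient, `NA` when undefined),
#'   and `table` (trial, window center, count, variance).
#' @export
timing_power_correlation <- function(train, traces, fs_hz, window_s = 0.25) {
  stopifnot(inherits(train, "tmpp_train"))
  traces <- as_trial_matrix(traces)
  if (!nrow(train$events))
    return(list(r = NA_real_, table = NULL))
  w <- max(2L, round(window_s * fs_hz))
  hop <- max(1L, w %/% 2L)
  starts <- seq.int(1L, ncol(traces) - w + 1L, by = hop)
  rows <- vector("list", nrow(traces))
  for (tr in seq_len(nrow(traces))) {
    taus <- train$events$tau_sample[train$events$trial == tr]
    cnt <- vapply(starts, function(s) sum(taus >= s & taus < s + w), numeric(1))
    v <- vapply(starts, function(s) var(traces[tr, s:(s + w - 1L)]), numeric(1))
    rows[[tr]] <- data.frame(trial = tr, t_sample = starts + w %/% 2L,
                             count = cnt, variance = v)
  }
  tab <- do.call(rbind, rows)
  r <- if (sd(tab$count) == 0 || sd(tab$variance) == 0) NA_real_ else
    cor(tab$count, tab$variance)
  list(r = r, table = tab)
}

#' Label-shuffle randomization test
#'
#' Permutes the class labels `n_perm` times, recomputes the chosen
#' statistic (mean silhouette, or the MANOVA p-value of the
#' highest-dimension null) for each shuffle, and locates the observed value
#' on the resulting null distribution. Guards against overfitting: genuine
#' structure should exceed the null's upper percentiles.
#'
#' @param x `design_matrix`, or feature matrix with `labels`.
#' @param labels class labels when `x` is not a `design_matrix`.
#' @param statistic `"mean_silhouette"` or `"manova_p"`.
#' @param n_perm number of shuffles (1,000 in the reference protocol).
#' @param seed integer seed governing the full shuffle stream.
#' @return object of class `randomization_result`: `observed`, `null`
#'   (length `n_perm`), `percentile` of the observed value on the null.
#' @export
randomization_test <- function(x, labels = NULL,
                               statistic = c("mean_silhouette", "manova_p"),
                               n_perm = 1000L, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  des <- as_design(x, labels)
  stat_fun <- switch(statistic,
    mean_silhouette = function(lab) silhouette_score(des$x, lab)$mean_silhouette,
    manova_p = function(lab) {
      r <- one_way_manova(build_design(des$x, lab, impute = FALSE))
      tail(r$dims$p_value, 1L)
    })
  observed <- stat_fun(des$labels)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_fun(sample(des$labels)), numeric(1))
  })
  structure(list(observed = observed, null = null,
                 percentile = 100 * mean(null < observed) +
                   50 * mean(null == observed),
                 statistic = statistic, n_perm = n_perm),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization test (%s, %d shuffles): observed %.4g at percentile %.1f>\n",
              x$statistic, x$n_perm, x$observed, x$percentile))
  invisible(x)
}

#' Sample-wise detection scoring
#'
#' Confusion counts over `[0, n_samples)`: a sample is a true positive when
#' both the reference scoring and the detector mark it as part of a
#' micro-event. Spans are half-open `[start, end)` sample intervals
#' (0-based). `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`.
#'
#' @param pred,truth two-column matrices or data.frames of spans
#'   (`start`, `end`); `NULL` or zero rows mean no detections.
#' @param n_samples total number of samples scored.
#' @return object of class `detection_score` with `TP`, `FP`, `TN`, `FN`,
#'   `TPR`, `FPR`.
#' @export
sample_wise_detection <- function(pred, truth, n_samples) {
  stopifnot(n_samples >= 1)
  p <- spans_to_logical(pred, n_samples)
  t <- spans_to_logical(truth, n_samples)
  TP <- sum(p & t); FP <- sum(p & !t); FN <- sum(!p & t); TN <- sum(!p & !t)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_),
            class = "detection_score")
}

spans_to_logical <- function(spans, n_samples) {
  out <- logical(n_samples)
  if (is.null(spans)) return(out)
  spans <- as.matrix(as.data.frame(spans))
  if (!nrow(spans)) return(out)
  stopifnot(ncol(spans) >= 2L)
  for (r in seq_len(nrow(spans))) {
    s <- max(0, spans[r, 1]); e <- min(n_samples, spans[r, 2])
    if (e > s) out[(s + 1):e] <- TRUE
  }
  out
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf("<detection: TP=%d FP=%d TN=%d FN=%d | TPR=%.3f FPR=%.3f>\n",
              x$TP, x$FP, x$TN, x$FN, x$TPR, x$FPR))
  invisible(x)
}
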