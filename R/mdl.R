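# MDL (bitsave) hierarchical clustering of selected snippets into a
# dictionary of variable-duration, unit-norm atoms.
#
# The cost currency is the description length (DL) of quantized sequences.
# A cluster holds a center hypothesis H (unit-norm, length delta <= M) and
# member snippets; encoding a member given H costs the DL of its residual
# after shift-invariant alignment. Clustering proceeds greedily: at each
# step the operator (create / add / merge) with the largest positive
# bitsave is applied; the number of atoms K is an emergent property.

# ---- alignment -------------------------------------------------------------

# Best placement of template h (length delta) inside sequence a (length
# m >= delta) by normalized cross-correlation. With polarity = TRUE the
# match is sign-invariant and the sign is reported. Returns 0-based lag.
# Sliding dot products are computed in one convolution.
align_template <- function(a, h, polarity = TRUE) {
  m <- length(a); d <- length(h)
  if (d > m) stop("template longer than the sequence: no admissible lag")
  nh <- norm2(h)
  dots <- sliding_dots(a, h)
  cs <- cumsum(c(0, a^2))
  seg2 <- cs[(d + 1L):(m + 1L)] - cs[1L:(m - d + 1L)]
  den <- sqrt(pmax(seg2, 0)) * nh
  cc <- ifelse(den > 0, dots / den, 0)
  sc <- if (polarity) abs(cc) else cc
  k <- which.max(sc)
  list(score = sc[k], lag = k - 1L,
       sign = if (polarity && cc[k] < 0) -1 else 1)
}

# dots[k] = sum(a[k:(k+d-1)] * h), k = 1..m-d+1
sliding_dots <- function(a, h) {
  m <- length(a); d <- length(h)
  if (m - d + 1L <= 0L) stop("no admissible lag")
  if (m < 200L) {
    vapply(seq_len(m - d + 1L),
           function(k) sum(a[k:(k + d - 1L)] * h), numeric(1))
  } else {
    as.numeric(stats::convolve(a, rev(h), type = "filter"))
  }
}

# Best pair of delta-windows, one from each sequence, by normalized
# cross-correlation over all window placements (exhaustive).
best_window_pair <- function(a, b, delta, polarity = TRUE) {
  m <- length(a)
  stopifnot(length(b) == m, delta <= m, delta >= 2)
  WA <- window_stack(matrix(a, ncol = 1L), delta)
  WB <- window_stack(matrix(b, ncol = 1L), delta)
  S <- crossprod(WA, WB)
  idx <- if (polarity) which.max(abs(S)) else which.max(S)
  nw <- m - delta + 1L
  sa <- (idx - 1L) %% nw + 1L
  sb <- (idx - 1L) %/% nw + 1L
  sc <- S[sa, sb]
  list(score = if (polarity) abs(sc) else sc,
       start_a = sa, start_b = sb,
       sign = if (polarity && sc < 0) -1 else 1)
}

# All normalized delta-windows of every column of X, stacked column-blocks
# per snippet: result is delta x (nw * ncol(X)), block j holding the nw
# windows of snippet j. Zero-norm windows stay zero.
window_stack <- function(X, delta) {
  M <- nrow(X); nw <- M - delta + 1L
  I <- outer(0L:(delta - 1L), seq_len(nw), "+")   # delta x nw index matrix
  W <- matrix(X[as.vector(I), , drop = FALSE], nrow = delta)
  nrms <- sqrt(colSums(W^2))
  nrms[nrms == 0] <- 1
  sweep(W, 2L, nrms, "/")
}

# ---- conditional and cluster description lengths ---------------------------

#' Conditional description length of a snippet given a hypothesis
#'
#' Cost in bits of encoding sequence `A` given cluster center `H`: `H` is
#' aligned to `A` at the lag maximizing normalized cross-correlation
#' (sign-invariant when `polarity` is on), the quantized symbols of the
#' matched window of `A` are subtracted from those of `H`, and the
#' description length of the residual symbols over the aligned support is
#' returned (`DL(A|H) = DL(A - H)`). The remainder of `A` outside the
#' support is unexplained background and is not charged to the hypothesis;
#' all cluster economics live on the support scale. Identical or shifted
#' copies cost 0 bits; an unrelated same-length sequence costs about its
#' own description length (no compression).
#'
#' @param A numeric snippet.
#' @param H numeric center hypothesis, `length(H) <= length(A)`.
#' @param L quantization levels.
#' @param polarity allow sign-flipped matches (bandpassed bursts are
#'   sign-ambiguous).
#' @return list with `bits`, `lag` (0-based placement of `H` in `A`), and
#'   `sign`.
#' @export
conditional_dl <- function(A, H, L = 16L, polarity = TRUE) {
  A <- as.numeric(A); H <- as.numeric(H)
  al <- align_template(A, H, polarity)
  d <- length(H)
  supp <- (al$lag + 1L):(al$lag + d)
  qa <- quantize(A[supp], L)$symbols
  qh <- quantize(H, L)$symbols
  if (al$sign < 0) qh <- (L - 1L) - qh
  res <- qa - qh
  list(bits = d * symbol_entropy(res), lag = al$lag, sign = al$sign)
}

#' Cluster constructor and description length
#'
#' A cluster pairs a unit-norm center hypothesis with its member snippets.
#' `cluster_dl` is the bit cost of representing all members through the
#' center: `DL(H) + sum(DL(A|H))` — the hypothesis plus every member's
#' residual. In the formulation where the hypothesis is itself one of the
#' members, the member acting as hypothesis has a vanishing conditional
#' term, which is what a "discount one member" rule emulates; with averaged
#' centers an explicit max-member discount would make the most expensive
#' member free and reward absorbing noise, so the undiscounted coding cost
#' is used (see the methods vignette).
#'
#' @param center numeric center waveform (normalized internally).
#' @param member_seqs list of numeric member snippets.
#' @param member_ids optional integer identities (e.g. column indexes of the
#'   snippet matrix); `NA` allowed.
#' @return `mdl_cluster` object.
#' @export
mdl_cluster <- function(center, member_seqs, member_ids = NULL) {
  center <- as.numeric(center)
  nrm <- norm2(center)
  if (nrm == 0) stop("cluster center must be non-zero")
  if (is.null(member_ids)) member_ids <- rep(NA_integer_, length(member_seqs))
  stopifnot(length(member_ids) == length(member_seqs))
  structure(list(center = center / nrm, member_seqs = member_seqs,
                 member_ids = as.integer(member_ids)),
            class = "mdl_cluster")
}

#' @rdname mdl_cluster
#' @param C an `mdl_cluster`.
#' @param L quantization levels.
#' @param polarity sign-invariant alignment flag.
#' @export
cluster_dl <- function(C, L = 16L, polarity = TRUE) {
  stopifnot(inherits(C, "mdl_cluster"))
  if (!length(C$member_seqs)) stop("cluster has no members")
  bits <- vapply(C$member_seqs,
                 function(a) conditional_dl(a, C$center, L, polarity)$bits,
                 numeric(1))
  description_length(C$center, L) + sum(bits)
}

#' @export
print.mdl_cluster <- function(x, ...) {
  cat(sprintf("<mdl_cluster: %d members, center of %d samples>\n",
              length(x$member_seqs), length(x$center)))
  invisible(x)
}

# Re-estimate the center as the aligned, sign-corrected average of the
# normalized member windows; support length is preserved.
refresh_center <- function(C, polarity = TRUE) {
  d <- length(C$center)
  acc <- numeric(d)
  for (a in C$member_seqs) {
    al <- align_template(a, C$center, polarity)
    seg <- a[(al$lag + 1L):(al$lag + d)]
    ns <- norm2(seg)
    if (ns > 0) acc <- acc + al$sign * seg / ns
  }
  nrm <- norm2(acc)
  if (nrm > 0) C$center <- acc / nrm
  C
}

# ---- bitsave operators -----------------------------------------------------

#' Bitsave of creating a cluster from two snippets
#'
#' Bits saved by encoding snippets `A` and `B` through a common center
#' rather than individually: `DL(A) + DL(B) - DLC(C)`, with every
#' description length taken at the scale of the matched `delta`-window
#' (for same-length operands this is the plain formula). The center is the
#' aligned, normalized average of the best-matching pair of `delta`-windows
#' (full length when `delta` is `NULL`), re-normalized to unit norm.
#'
#' @param A,B numeric snippets of equal length.
#' @param delta center duration to explore; `NULL` for full length.
#' @param L quantization levels.
#' @param polarity sign-invariant matching flag.
#' @param ids optional pair of member identities.
#' @return list with `bs` (bits saved) and `cluster`.
#' @export
bitsave_create <- function(A, B, delta = NULL, L = 16L, polarity = TRUE,
                           ids = c(NA_integer_, NA_integer_)) {
  A <- as.numeric(A); B <- as.numeric(B)
  stopifnot(length(A) == length(B))
  if (is.null(delta)) delta <- length(A)
  bp <- best_window_pair(A, B, delta, polarity)
  wa <- A[bp$start_a:(bp$start_a + delta - 1L)]
  wb <- B[bp$start_b:(bp$start_b + delta - 1L)]
  na <- norm2(wa); nb <- norm2(wb)
  center <- (if (na > 0) wa / na else wa) +
    bp$sign * (if (nb > 0) wb / nb else wb)
  if (norm2(center) == 0) center <- wa + 1e-12
  C <- mdl_cluster(center, list(A, B), ids)
  bs <- description_length(wa, L) + description_length(wb, L) -
    cluster_dl(C, L, polarity)
  list(bs = bs, cluster = C)
}

#' Bitsave of adding a snippet to a cluster
#'
#' `DL(A) + DLC(C) - DLC(C')` where `C'` includes `A` and `DL(A)` is taken
#' at the scale of `A`'s aligned window. The bitsave is evaluated against
#' the current center (so the cost of the candidate is exactly the
#' conditional description length of `A`, adjusted for the discounted
#' most-expensive member); with `refresh = TRUE` (the default)
#' the returned cluster carries the refreshed center — the aligned average
#' of all members, re-normalized — which takes effect once the operator is
#' applied.
#'
#' @param A numeric snippet.
#' @param C an [mdl_cluster()].
#' @param L,polarity see [cluster_dl()].
#' @param refresh re-average the center of the returned cluster.
#' @param id optional member identity.
#' @param dlc precomputed `cluster_dl(C)`, if available.
#' @return list with `bs` and `cluster` (the candidate `C'`).
#' @export
bitsave_add <- function(A, C, L = 16L, polarity = TRUE, refresh = TRUE,
                        id = NA_integer_, dlc = NULL) {
  stopifnot(inherits(C, "mdl_cluster"))
  A <- as.numeric(A)
  if (is.null(dlc)) dlc <- cluster_dl(C, L, polarity)
  C2 <- mdl_cluster(C$center, c(C$member_seqs, list(A)),
                    c(C$member_ids, as.integer(id)))
  al <- align_template(A, C$center, polarity)
  wA <- A[(al$lag + 1L):(al$lag + length(C$center))]
  bs <- description_length(wA, L) + dlc - cluster_dl(C2, L, polarity)
  if (refresh) C2 <- refresh_center(C2, polarity)
  list(bs = bs, cluster = C2)
}

#' Bitsave of merging two clusters
#'
#' `DLC(C1) + DLC(C2) - DLC(C')`. The merged center is the member-count
#' weighted average of the two centers after shift-invariant alignment
#' (overhanging alignments may lengthen the support beyond either parent);
#' edge samples are then trimmed while the retained support keeps at least
#' `trim_energy` of the center energy, and the support never exceeds
#' `max_len` (the snippet length) when given.
#'
#' @param C1,C2 [mdl_cluster()]s built from snippets of a common length.
#' @param L,polarity see [cluster_dl()].
#' @param trim_energy retained energy fraction for edge trimming.
#' @param max_len optional hard cap on the merged support.
#' @param dlc1,dlc2 precomputed parent description lengths, if available.
#' @return list with `bs` and `cluster`.
#' @export
bitsave_merge <- function(C1, C2, L = 16L, polarity = TRUE,
                          trim_energy = 0.99, max_len = NULL,
                          dlc1 = NULL, dlc2 = NULL) {
  stopifnot(inherits(C1, "mdl_cluster"), inherits(C2, "mdl_cluster"))
  # merged support must still fit inside every member for alignment
  member_cap <- min(lengths(c(C1$member_seqs, C2$member_seqs)))
  max_len <- if (is.null(max_len)) member_cap else min(max_len, member_cap)
  if (is.null(dlc1)) dlc1 <- cluster_dl(C1, L, polarity)
  if (is.null(dlc2)) dlc2 <- cluster_dl(C2, L, polarity)
  # longer center hosts the alignment
  if (length(C2$center) > length(C1$center)) {
    tmp <- C1; C1 <- C2; C2 <- tmp
    tmp <- dlc1; dlc1 <- dlc2; dlc2 <- tmp
  }
  c1 <- C1$center; c2 <- C2$center
  d1 <- length(c1); d2 <- length(c2)
  n1 <- length(C1$member_seqs); n2 <- length(C2$member_seqs)
  min_ov <- max(2L, as.integer(ceiling(d2 / 2)))
  best <- list(score = -Inf, lag = 0L, sign = 1)
  for (lag in (min_ov - d2):(d1 - min_ov)) {
    i1 <- max(1L, 1L + lag):min(d1, lag + d2)
    i2 <- i1 - lag
    s1 <- c1[i1]; s2 <- c2[i2]
    nn <- norm2(s1) * norm2(s2)
    if (nn == 0) next
    cc <- sum(s1 * s2) / nn
    sg <- if (polarity && cc < 0) -1 else 1
    sc <- if (polarity) abs(cc) else cc
    if (sc > best$score) best <- list(score = sc, lag = lag, sign = sg)
  }
  lag <- best$lag
  start <- min(1L, 1L + lag)
  end <- max(d1, lag + d2)
  idx <- start:end
  m1 <- numeric(length(idx)); m2 <- numeric(length(idx))
  m1[(1L - start + 1L):(1L - start + d1)] <- c1
  m2[(lag + 2L - start):(lag + d2 - start + 1L)] <- best$sign * c2
  center <- (n1 * m1 + n2 * m2) / (n1 + n2)
  center <- trim_center(center, trim_energy, max_len)
  C <- mdl_cluster(center, c(C1$member_seqs, C2$member_seqs),
                   c(C1$member_ids, C2$member_ids))
  bs <- dlc1 + dlc2 - cluster_dl(C, L, polarity)
  list(bs = bs, cluster = C)
}

# Drop edge samples (smaller-energy edge first) while the retained span
# keeps at least `keep` of the total energy; then enforce max_len.
trim_center <- function(center, keep = 0.99, max_len = NULL) {
  e <- center^2
  tot <- sum(e)
  i <- 1L; j <- length(center)
  if (tot > 0) {
    cur <- tot
    while (j - i + 1L > 4L) {
      drop_left <- e[i] <= e[j]
      nxt <- cur - if (drop_left) e[i] else e[j]
      if (nxt < keep * tot) break
      if (drop_left) i <- i + 1L else j <- j - 1L
      cur <- nxt
    }
    if (!is.null(max_len)) {
      while (j - i + 1L > max_len) {
        if (e[i] <= e[j]) i <- i + 1L else j <- j - 1L
      }
    }
  }
  center[i:j]
}

# ---- motif discovery -------------------------------------------------------

# Pairwise motif scores at duration delta: for snippets i, j the maximum
# normalized cross-correlation between the central delta-window of one and
# all delta-windows of the other (both directions). Returns Psi x Psi
# matrices of scores, matched window starts and signs.
motif_score_matrix <- function(X, delta, polarity = TRUE) {
  M <- nrow(X); Psi <- ncol(X)
  nw <- M - delta + 1L
  c0 <- (M - delta) %/% 2L + 1L
  V <- X[c0:(c0 + delta - 1L), , drop = FALSE]
  vn <- sqrt(colSums(V^2)); vn[vn == 0] <- 1
  V <- sweep(V, 2L, vn, "/")
  Wall <- window_stack(X, delta)
  S <- crossprod(V, Wall)                      # Psi x (Psi*nw)
  Ssc <- if (polarity) abs(S) else S
  # best window of j for central i: Psi x Psi
  Bmax <- matrix(0, Psi, Psi); Barg <- matrix(1L, Psi, Psi)
  Bsgn <- matrix(1, Psi, Psi)
  for (j in seq_len(Psi)) {
    blk <- Ssc[, ((j - 1L) * nw + 1L):(j * nw), drop = FALSE]
    wm <- max.col(blk, ties.method = "first")
    Bmax[, j] <- blk[cbind(seq_len(Psi), wm)]
    Barg[, j] <- wm
    raw <- S[cbind(seq_len(Psi), (j - 1L) * nw + wm)]
    Bsgn[, j] <- ifelse(polarity & raw < 0, -1, 1)
  }
  list(Bmax = Bmax, Barg = Barg, Bsgn = Bsgn, c0 = c0, delta = delta)
}

#' Motif pairs at a candidate duration
#'
#' For every snippet pair, the maximal normalized cross-correlation between
#' the central `delta`-window of one snippet and all `delta`-windows of the
#' other (both directions, sign-invariant when `polarity` is on). Returns
#' the `top_k` best-scoring pairs with disjoint snippet membership, with the
#' matched window starts.
#'
#' @param X snippet matrix (M x Psi) or [select_snippets()] result.
#' @param delta window duration in samples, `delta <= M`.
#' @param top_k number of disjoint pairs to return.
#' @param polarity sign-invariant matching flag.
#' @return data.frame with columns `i`, `j`, `start_i`, `start_j`, `sign`,
#'   `score`, ordered by decreasing score.
#' @export
find_motifs <- function(X, delta, top_k = 1L, polarity = TRUE) {
  X <- as_snippet_mat(X)
  if (ncol(X) < 2L) stop("need at least two snippets to search for motifs")
  stopifnot(delta >= 2, delta <= nrow(X))
  ms <- motif_score_matrix(X, delta, polarity)
  motif_pairs(ms, seq_len(ncol(X)), top_k)
}

# Extract the top_k disjoint pairs restricted to the `pool` of snippet
# indexes, from a precomputed motif_score_matrix. With disjoint = FALSE the
# full score-sorted pair table is returned.
motif_pairs <- function(ms, pool, top_k, disjoint = TRUE) {
  if (length(pool) < 2L)
    return(data.frame(i = integer(), j = integer(), start_i = integer(),
                      start_j = integer(), sign = numeric(), score = numeric()))
  n <- length(pool)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  gi <- pool[ij[, 1L]]; gj <- pool[ij[, 2L]]
  s_ij <- ms$Bmax[cbind(gi, gj)]   # central i vs windows of j
  s_ji <- ms$Bmax[cbind(gj, gi)]   # central j vs windows of i
  use_ij <- s_ij >= s_ji
  score <- pmax(s_ij, s_ji)
  start_i <- ifelse(use_ij, ms$c0, ms$Barg[cbind(gj, gi)])
  start_j <- ifelse(use_ij, ms$Barg[cbind(gi, gj)], ms$c0)
  sign <- ifelse(use_ij, ms$Bsgn[cbind(gi, gj)], ms$Bsgn[cbind(gj, gi)])
  out <- data.frame(i = gi, j = gj, start_i = as.integer(start_i),
                    start_j = as.integer(start_j), sign = sign, score = score)
  out <- out[order(-out$score, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  if (!disjoint) return(out)
  used <- integer(0); keep <- logical(nrow(out))
  for (r in seq_len(nrow(out))) {
    if (!(out$i[r] %in% used) && !(out$j[r] %in% used)) {
      keep[r] <- TRUE
      used <- c(used, out$i[r], out$j[r])
      if (sum(keep) >= top_k) break
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_snippet_mat <- function(X) {
  if (inherits(X, "snippet_matrix")) X$X else as.matrix(X)
}

# ---- greedy dictionary learning -------------------------------------------

#' Learning configuration
#'
#' @param delta_grid candidate center durations (samples); suggestions only
#'   — merges may drift durations off the grid, bounded above by `M`.
#' @param M snippet length in samples.
#' @param L quantization levels; the default 16 (4 bits/symbol) keeps
#'   the empirical symbol entropy of 40-100-sample windows informative
#'   (see the methods vignette).
#' @param max_iterations cap on greedy steps.
#' @param motif_top_k motif pairs evaluated per duration per step; `Inf`
#'   evaluates every admissible pair (exhaustive).
#' @param add_candidates `"nearest"` evaluates only the unassigned snippet
#'   closest (by cross-correlation) to each center; `"all"` evaluates every
#'   unassigned snippet against every cluster (exhaustive).
#' @param polarity sign-invariant matching flag.
#' @param trim_energy merge-center edge-trimming energy fraction.
#' @param seed integer seed (the procedure is deterministic given inputs;
#'   the seed is recorded for provenance).
#' @return `learn_config` object.
#' @export
learn_config <- function(delta_grid, M, L = 16L, max_iterations = 500L,
                         motif_top_k = 3L, add_candidates = c("nearest", "all"),
                         polarity = TRUE, trim_energy = 0.99, seed = NULL) {
  delta_grid <- sort(unique(as.integer(delta_grid)))
  add_candidates <- match.arg(add_candidates)
  stopifnot(all(delta_grid >= 2L), all(delta_grid <= M), M >= 2L, L >= 2L)
  structure(list(delta_grid = delta_grid, M = as.integer(M), L = as.integer(L),
                 max_iterations = as.integer(max_iterations),
                 motif_top_k = motif_top_k, add_candidates = add_candidates,
                 polarity = polarity, trim_energy = trim_energy, seed = seed),
            class = "learn_config")
}

#' Greedy MDL dictionary learning
#'
#' Hierarchically clusters the selected snippets by repeatedly applying the
#' single clustering operator with the largest positive bitsave:
#' * create — a new cluster from the best-matching unassigned motif pairs,
#'   over every duration in `delta_grid`;
#' * add — the nearest unassigned snippet (by normalized cross-correlation)
#'   to each existing center;
#' * merge — any pair of clusters, possibly changing the center duration.
#'
#' Learning stops when no operator saves bits (encoding background noise is
#' never worthwhile), when snippets are exhausted, or at `max_iterations`.
#' The number of atoms K is an emergent byproduct, never fixed a priori.
#' Equal bitsaves are broken deterministically: add over merge over create,
#' then lowest operand index. The total description length of the encoded
#' portion of X is strictly decreasing across applied steps.
#'
#' @param X snippet matrix (M x Psi) or [select_snippets()] result.
#' @param config a [learn_config()].
#' @param fs_hz sampling rate stored on the learned atoms.
#' @return object of class `burst_dictionary`: `atoms` (list of
#'   [burst_atom()]), `K`, `learn_log` (one row per applied operator),
#'   `assignments` (snippet, cluster, lag, sign), and the final `clusters`.
#' @export
learn_dictionary <- function(X, config, fs_hz = NA_real_) {
  stopifnot(inherits(config, "learn_config"))
  Xm <- as_snippet_mat(X)
  Psi <- ncol(Xm)
  L <- config$L; pol <- config$polarity
  if (Psi == 0L) {
    warning("empty snippet matrix: returning an empty dictionary")
    return(empty_dictionary(config, fs_hz, Psi))
  }
  if (Psi < 2L) return(empty_dictionary(config, fs_hz, Psi))
  # precomputed, sorted motif pair lists per candidate duration
  pairs_by_delta <- lapply(config$delta_grid, function(d) {
    ms <- motif_score_matrix(Xm, d, pol)
    motif_pairs(ms, seq_len(Psi), top_k = Inf, disjoint = FALSE)
  })
  unassigned <- rep(TRUE, Psi)
  clusters <- list()
  cache <- list()      # per cluster: member bits, DL(center), DLC
  log_rows <- list()
  iter <- 0L
  tie_eps <- 1e-9
  repeat {
    iter <- iter + 1L
    if (iter > config$max_iterations) break
    cands <- list()
    un_idx <- which(unassigned)
    # -- create candidates: top motif pairs per duration among unassigned
    if (length(un_idx) >= 2L) {
      for (di in seq_along(config$delta_grid)) {
        mot <- top_disjoint_pairs(pairs_by_delta[[di]], unassigned,
                                  config$motif_top_k)
        for (r in seq_len(nrow(mot))) {
          cr <- bitsave_create(Xm[, mot$i[r]], Xm[, mot$j[r]],
                               delta = config$delta_grid[di],
                               L = L, polarity = pol,
                               ids = c(mot$i[r], mot$j[r]))
          cands[[length(cands) + 1L]] <-
            list(op = "create", bs = cr$bs, cluster = cr$cluster,
                 members = c(mot$i[r], mot$j[r]), priority = 3L,
                 key = mot$i[r])
        }
      }
    }
    # -- add candidates: nearest unassigned snippet to each center
    if (length(clusters) && length(un_idx)) {
      for (k in seq_along(clusters)) {
        d <- length(clusters[[k]]$center)
        if (config$add_candidates == "nearest") {
          W <- window_stack(Xm[, un_idx, drop = FALSE], d)
          sc <- crossprod(clusters[[k]]$center, W)
          if (pol) sc <- abs(sc)
          nw <- nrow(Xm) - d + 1L
          per <- vapply(seq_along(un_idx), function(u)
            max(sc[((u - 1L) * nw + 1L):(u * nw)]), numeric(1))
          js <- un_idx[which.max(per)]
        } else {
          js <- un_idx
        }
        for (j in js) {
          # incremental bitsave: the candidate's own bits minus its
          # conditional (residual) bits given the current center
          cd <- conditional_dl(Xm[, j], clusters[[k]]$center, L, pol)
          wj <- Xm[(cd$lag + 1L):(cd$lag + d), j]
          bs <- description_length(wj, L) - cd$bits
          cands[[length(cands) + 1L]] <-
            list(op = "add", bs = bs, members = j, target = k,
                 priority = 1L, key = k)
        }
      }
    }
    # -- merge candidates: all cluster pairs
    if (length(clusters) >= 2L) {
      for (k1 in seq_len(length(clusters) - 1L)) {
        for (k2 in (k1 + 1L):length(clusters)) {
          mg <- bitsave_merge(clusters[[k1]], clusters[[k2]], L = L,
                              polarity = pol, trim_energy = config$trim_energy,
                              max_len = config$M,
                              dlc1 = cache[[k1]]$dlc, dlc2 = cache[[k2]]$dlc)
          cands[[length(cands) + 1L]] <-
            list(op = "merge", bs = mg$bs, cluster = mg$cluster,
                 target = c(k1, k2), priority = 2L, key = k1)
        }
      }
    }
    if (!length(cands)) break
    bs_all <- vapply(cands, `[[`, numeric(1), "bs")
    if (max(bs_all) <= 0) break
    top <- which(bs_all > max(bs_all) - tie_eps)
    if (length(top) > 1L) {
      pri <- vapply(cands[top], `[[`, integer(1), "priority")
      top <- top[pri == min(pri)]
      if (length(top) > 1L) {
        keys <- vapply(cands[top], `[[`, numeric(1), "key")
        top <- top[which.min(keys)]
      }
    }
    ch <- cands[[top[1L]]]
    if (ch$op == "create") {
      C <- ch$cluster
      clusters[[length(clusters) + 1L]] <- C
      cache[[length(clusters)]] <- cluster_cache(C, L, pol)
      unassigned[ch$members] <- FALSE
      detail <- sprintf("snippets %d+%d (delta %d)", ch$members[1],
                        ch$members[2], length(C$center))
    } else if (ch$op == "add") {
      k <- ch$target
      C <- mdl_cluster(clusters[[k]]$center,
                       c(clusters[[k]]$member_seqs, list(Xm[, ch$members])),
                       c(clusters[[k]]$member_ids, ch$members))
      C <- refresh_center(C, pol)
      clusters[[k]] <- C
      cache[[k]] <- cluster_cache(C, L, pol)
      unassigned[ch$members] <- FALSE
      detail <- sprintf("snippet %d -> cluster %d", ch$members, k)
    } else {
      keep <- setdiff(seq_along(clusters), ch$target)
      clusters <- c(clusters[keep], list(ch$cluster))
      cache <- c(cache[keep], list(cluster_cache(ch$cluster, L, pol)))
      detail <- sprintf("clusters %d+%d", ch$target[1], ch$target[2])
    }
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(step = length(log_rows) + 1L, op = ch$op, bitsave = ch$bs,
                 detail = detail, stringsAsFactors = FALSE)
    if (!any(unassigned) && length(clusters) < 2L) break
  }
  finalize_dictionary(clusters, log_rows, config, fs_hz, Psi)
}

cluster_cache <- function(C, L, polarity) {
  bits <- vapply(C$member_seqs,
                 function(a) conditional_dl(a, C$center, L, polarity)$bits,
                 numeric(1))
  dlH <- description_length(C$center, L)
  list(bits = bits, dlH = dlH, dlc = dlH + sum(bits))
}

# Top_k disjoint pairs restricted to currently unassigned snippets, from a
# precomputed, score-sorted pair table. top_k = Inf returns every admissible
# pair (exhaustive candidate generation).
top_disjoint_pairs <- function(pairs, unassigned, top_k) {
  ok <- unassigned[pairs$i] & unassigned[pairs$j]
  sub <- pairs[ok, , drop = FALSE]
  if (is.infinite(top_k)) return(sub)
  used <- integer(0); keep <- logical(nrow(sub))
  for (r in seq_len(nrow(sub))) {
    if (!(sub$i[r] %in% used) && !(sub$j[r] %in% used)) {
      keep[r] <- TRUE
      used <- c(used, sub$i[r], sub$j[r])
      if (sum(keep) >= top_k) break
    }
  }
  sub[keep, , drop = FALSE]
}

empty_dictionary <- function(config, fs_hz, Psi = 0L) {
  finalize_dictionary(list(), list(), config, fs_hz, Psi)
}

finalize_dictionary <- function(clusters, log_rows, config, fs_hz, Psi) {
  atoms <- vector("list", length(clusters))
  assign_rows <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    C <- clusters[[k]]
    atoms[[k]] <- burst_atom(C$center,
                             fs_hz = if (is.na(fs_hz)) 1 else fs_hz,
                             atom_id = k)
    if (is.na(fs_hz)) atoms[[k]]$fs_hz <- NA_real_
    als <- lapply(C$member_seqs, align_template, h = C$center,
                  polarity = config$polarity)
    assign_rows[[k]] <- data.frame(
      snippet = C$member_ids, cluster = k,
      lag = vapply(als, `[[`, integer(1), "lag"),
      sign = vapply(als, `[[`, numeric(1), "sign"))
  }
  learn_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(), op = character(), bitsave = numeric(),
               detail = character(), stringsAsFactors = FALSE)
  assignments <- if (length(assign_rows)) do.call(rbind, assign_rows) else
    data.frame(snippet = integer(), cluster = integer(), lag = integer(),
               sign = numeric())
  rownames(assignments) <- NULL
  structure(list(atoms = atoms, K = length(atoms), learn_log = learn_log,
                 assignments = assignments, clusters = clusters,
                 config = config, fs_hz = fs_hz, n_snippets = Psi),
            class = "burst_dictionary")
}

#' @export
print.burst_dictionary <- function(x, ...) {
  durs <- vapply(x$atoms, function(a) a$duration_samples, integer(1))
  cat(sprintf("<burst_dictionary: K=%d atom(s)%s; %d greedy steps>\n",
              x$K,
              if (x$K) sprintf(" of %s samples", paste(durs, collapse = "/")) else "",
              nrow(x$learn_log)))
  invisible(x)
}
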