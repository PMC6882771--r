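---
title: "Modelling oscillatory bursts as a marked point process: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oscillatory bursts as a marked point process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstmdl)
```

## The model

A bandpassed, single-channel, single-trial trace $\tilde y(t)$ is treated as
switching between two physiological regimes. At rest the network produces a
featureless background $z(t)$ that is Gaussian after linear filtering,
$z \sim \mathcal N(\mu_Z, \sigma_Z)$. In the active regime the trace carries
transient, rhythm-specific bursts (micro-events). The active component is a
shot-noise-style sum over a dictionary of $K$ unit-norm waveforms
$\{d_\omega\}$ of heterogeneous durations $\delta_\omega$:

$$
y(t) \;=\; \sum_{\omega=1}^{K} \sum_{i=1}^{n_\omega}
  \alpha_i^{\omega}\, d_\omega(t - \tau_i^{\omega}) \;+\; \epsilon(t),
$$

so each burst is an amplitude-weighted ($\alpha$), time-shifted ($\tau$)
instance of one atom ($\omega$). The triples $(\tau, \alpha, \omega)$ form a
temporal marked point process (TMPP); timing resolution is one sample period
(2 ms at 500 Hz) and no windowing is involved. Inference (assigning
$\tau, \alpha, \omega$ to observed bursts) and learning (estimating the
dictionary itself, including $K$) are both unsupervised.

Because real multi-electrode recordings of this kind are not publicly
deposited, the package carries a first-class simulator (`make_burst_atom()`,
`sample_event_plan()`, `synthesize()`) that renders exactly this generative
model with retained ground truth, so every downstream stage is testable.

## Stage 1 — preprocessing

`bandpass()` applies a forward–backward (zero-phase) Butterworth bandpass,
order 4 per pass by default. Zero-phase filtering matters: the encoder reads
timings at one-sample resolution, and a causal filter's group delay would
bias every $\tau$. The band registry ships the clinical rhythm bands with
high-gamma (85–145 Hz, quality factor $\approx 2$) as the study default.
`downsample()` performs polyphase anti-aliased resampling (e.g. a 2034.5 Hz
acquisition rate to the 500 Hz analysis rate). The pipeline downsamples
first, then filters; the alternative order is equivalent for bands below the
new Nyquist, and this order is cheaper.

## Stage 2 — the discriminative embedding transform (DET)

An *M-snippet* is the $M$-sample window centred at $\pi_i$. Centers are
chosen by `extract_snippet_centers()`: modulated patterns first (local
maxima of the analytic-signal envelope smoothed by an $M/2$ moving average),
then regular tiling of the unmodulated remainder. Each snippet maps to its
$\ell_2$-norm (`embed_snippets()`), giving the surrogate variable
$\beta_M$. Under a Gaussian background, $\beta_M$ is a chi distribution with
$M$ degrees of freedom scaled by $\sigma$ — approximately Gaussian for
$M = 50$ — while embedded bursts inflate the right tail. `fit_background()`
estimates $(\mu_{Z_M}, \sigma_{Z_M})$ of the background mode and
`select_snippets()` keeps every snippet with norm
$\ge \gamma = \mu_{Z_M} + \gamma' \sigma_{Z_M}$ (ties included) in the
matrix $\mathbf X \in \mathbb R^{M\times\Psi}$.

Design choices the literature leaves open, fixed here:

* **Peak picking.** Threshold = envelope median $+\,3 \times 1.4826\,$MAD,
  with a 2 %-of-maximum floor, and a peak must dominate its
  $\pm M/2$ neighbourhood. A mean/SD threshold fails in practice: a single
  strong burst inflates the scale estimate and masks weaker bursts in the
  same trial (we observed exactly this on simulated ensembles); the
  median/MAD pair is insensitive to the bursts themselves. The floor covers
  the noiseless limit where median and MAD are both zero, and the
  neighbourhood-dominance rule removes carrier-ripple side maxima on burst
  skirts. Peak spacing is $\ge M/2$; tiles are placed $\ge M$ from any peak.
* **Background fit.** Default is the kernel-density mode (location) plus a
  left-tail median-absolute-deviation scale, mirrored about the mode:
  active-state snippets contaminate only the right tail, so a plain
  mean/SD fit (available as `method = "moments"`) is biased upward when
  bursts are dense. For symmetric nulls the two agree. (A half-sample mode
  was tried first; its sampling error at a few thousand norms is several
  times that of the density argmax.)
* **$\gamma' = 1$, $M = 50$ samples (100 ms)** are the defaults for the
  high-gamma protocol. With a Gaussian null, $\gamma' = 1$ excludes
  $\Phi(1) \approx 84\%$ of background snippets; the conventional quote of
  "at least 66 %" is a lower bound, and the package's checks treat it as
  such. Excluded fraction is monotone in $\gamma'$.
* For recovery studies with a 120 ms atom we set $M = 80$ (160 ms): the
  snippet must contain the longest expected burst. $M$ is a rhythm-scale
  choice, not a tuning knob.

## Stage 3 — MDL dictionary learning

Clustering the columns of $\mathbf X$ must be shift-invariant (bursts sit at
arbitrary offsets inside their snippets) and duration-agnostic (prototypes
of different lengths coexist). Both rule out k-means. The package follows a
minimum-description-length formulation: sequences are min–max normalized and
quantized to $L$ discrete levels, the description length of a sequence is
$DL(T) = m \cdot H(T)$ (length times empirical Shannon entropy of its
symbols), and the conditional cost of a snippet given a center
hypothesis $H$ is the DL of the quantized residual after aligning $H$ at
the lag with maximal normalized cross-correlation, $DL(A|H) = DL(A-H)$. A
cluster costs

$$
DLC(C) = DL(H) + \sum_{A \in C} DL(A|H),
$$

the center plus every member's residual. A common variant discounts one
member's conditional term, reflecting a formulation in which the hypothesis
*is* one of the members (whose conditional then vanishes). With averaged
centers that discount misbehaves: the most expensive member becomes free,
so adding arbitrary noise to a cluster always "saves" bits and the greedy
loop absorbs junk — we verified this failure mode empirically before
settling on the undiscounted coding cost, which agrees with the
member-as-hypothesis reading on all the small worked identities
(identical pairs, singletons).

**Choosing the level count $L$.** The empirical entropy of an $m$-sample
window saturates at $\log_2 m$ as soon as most symbols are distinct. At
the window lengths this pipeline works with ($\delta \approx 40$–$100$
samples), 64 levels (the "6 bits/symbol" convention one might lift from a
coarse reading of a 64-level code) leaves nearly every symbol unique:
$DL$s of noise, structure and residuals all collapse to
$\approx m \log_2 m$ and the bitsave contrast that drives clustering
degenerates — measured directly, the probability that adding pure noise to
a structured cluster is (correctly) rejected fell to $\approx 0.76$, and
two distinct planted atoms were merged into one. The default is therefore
$L = 16$ (4 bits/symbol), which resolves the relevant distributions at
these window lengths; the level count is configurable, and larger windows
tolerate larger $L$ (keep roughly $L \lesssim \delta/2$). Three
operators are scored by their *bitsave* (bits before minus bits after):
creating a cluster from two snippets, adding a snippet to a cluster, and
merging two clusters. `learn_dictionary()` greedily applies the single
operator with the largest positive bitsave until none saves bits; the
number of atoms $K$ is an emergent byproduct, never fixed a priori.

Numerical and design decisions:

* **Window-scale description lengths.** All DL terms in the bitsave
  formulas are taken at the scale of the matched $\delta$-window of each
  snippet (the conditional DL charges only the aligned support; the
  unexplained remainder of a snippet stays background). With full-snippet
  DLs and centers shorter than snippets, the max-member discount would make
  *every* create operator profitable — the discounted member "saves" its
  full $M$-scale cost while the cluster pays only the $\delta$-scale
  $DL(H)$ — and $K$ diverges (we observed $K \approx 60$ on a one-atom
  simulation). For same-length operands the window form reduces exactly to
  the formulas above, so all small worked identities (e.g.
  $BS_{\text{create}}(A, A) = DL(A)$) are unchanged.
* **Initialization.** For each duration $\delta$ in the suggestion grid
  $\Delta$ (50–100 ms in 10 ms steps by default), a motif routine ranks
  snippet pairs by the maximal normalized cross-correlation between one
  snippet's central $\delta$-window and all windows of the other; the top
  pairs seed create candidates. Initial centers are the aligned, normalized
  average of the motif windows. $\Delta$ is only a suggestion: merges may
  lengthen supports (overhanging alignments) or shorten them (edge
  trimming at 99 % retained energy), bounded above by $M$.
* **Polarity.** Bandpassed bursts are sign-ambiguous, so alignment uses
  $|{\rm xcorr}|$ and stores a $\pm 1$ per member (disable with
  `polarity = FALSE`).
* **Add evaluation and center refresh.** The bitsave of an add is evaluated
  against the current center — its cost is exactly the candidate's
  conditional DL plus the change in the max discount — and the center is
  re-averaged (all members, aligned, sign-corrected, re-normalized) when
  the operator is applied. Evaluating against a hypothetically refreshed
  center would cost a full member sweep per candidate for no change in the
  greedy trajectory we could detect.
* **Tie-breaking.** Equal bitsaves prefer add over merge over create, then
  the lowest operand index — growing existing structure before spawning
  new clusters. The procedure is fully deterministic given its inputs;
  reruns yield identical operator logs.
* **Stopping.** Strictly positive bitsave required; "until X is exhausted"
  is an upper bound, not a mandate to encode noise. On pure-noise input the
  motif scores carry no structure and the learner returns an empty (or
  near-empty, immediately starved) dictionary.
* `motif_top_k = Inf` together with `add_candidates = "all"` switches the
  candidate generation to exhaustive enumeration; on tiny instances the
  greedy trajectory then provably matches brute-force evaluation of every
  operator, which the test suite exercises.

## Stage 4 — TMPP encoding and features

`encode()` assigns each selected snippet the atom with maximal normalized
cross-correlation over admissible lags (one atom per micro-event — no
iterative reconstruction pursuit, since the background is not worth
encoding). $\tau$ is the sample the atom's reference point falls on
(resolution $1/f_s$, no sub-sample interpolation); $\alpha$ is the raw
inner product between the snippet segment and the unit-norm atom, signed
when polarity matching is on. On noiseless simulations the plan is
recovered exactly; at 10 dB within-burst SNR the median timing error is at
most one sample.

Per-trial features (`tmpp_features()`): the event **rate** in the analysis
window (default $-0.5$ to $2$ s relative to the cue); the mean **log
inter-burst interval** (natural log; the base only rescales features);
bivariate means $(\bar\tau, \overline{\log \alpha^2})$ (the log of the
squared weight is sign-invariant and closer to normal); plus the
conventional baselines `log_band_power()` and `stft_power_baseline()`
(250 ms windows, 50 % overlap). Trials with fewer than two events have no
IBI; missing values are imputed with the class-wise mean in
`build_design()` (configurable) — a documented choice where the protocol
is silent.

## Stage 5 — discrimination statistics

`one_way_manova()` tests, for each dimension $d$, whether the class mean
vectors lie in a $d$-dimensional affine subspace, via Wilks' lambda formed
from the eigenvalues of $W^{-1}B$ and Bartlett's $\chi^2$ approximation;
canonical variates scaled to unit pooled within-class variance provide the
projections that maximize between-class Mahalanobis separation. All
sequential dimension tests are always reported (different questions use
different nulls: four classes admit $d = 0, 1, 2$). When the within-class
covariance is singular (feature dimension approaching trials per class) a
ridge of $10^{-8}\,\mathrm{tr}(W)/p$ is added with a warning.
`silhouette_score()` implements the per-point silhouette
$S_i = (b_i - a_i)/\max(a_i, b_i) \in [-1, 1]$, singletons scoring 0 by
convention. `timing_power_correlation()` correlates running event counts
with running variances of the bandpassed trace (250 ms windows, 50 % hop,
mirroring the spectrogram convention). `randomization_test()` shuffles
labels (1,000 times by default, one seed governing the full stream) and
locates the observed statistic on the null — the package's overfitting
guard. `sample_wise_detection()` scores detections against reference spans
sample by sample (half-open intervals), yielding TPR and FPR.

## What the simulator does and does not emulate

The generator reproduces the study conditions the model assumes:
multi-trial ensembles at 500 Hz, roughly 4 s trials, 50–100 ms bursts in
the 85–145 Hz band sparsely superimposed on a white Gaussian background
(the rest-state premise after bandpassing; an additive noise term
$\epsilon$ is available separately), with class-dependent rates or
amplitudes and lognormal amplitude marks (median set by the target SNR,
log-scale SD 0.25 — the amplitude law of real gamma bursts is not
documented, so this is a stand-in, not a claim). It does **not** emulate
1/f background structure (an optional extension), multi-channel spatial
correlation, artifacts (EMG/EOG), or nonstationary background regimes.
Passing tests therefore demonstrate correctness of the algorithms under
the model's own assumptions, not robustness to everything real recordings
contain.

Problem sizes used in the shipped checks were chosen to estimate each
quantity comfortably on a laptop-class machine: $10^5$ snippets for the
background-exclusion and chi-null checks; 100 trials of 2 s with 100
events per atom at 10 dB SNR for the two-atom recovery study; tiny
($\Psi \le 6$, $\delta \le 8$, $L = 4$) instances for the
greedy-vs-exhaustive equivalence.

## Known limitations

* Learned atom supports shrink toward the high-energy burst core
  (repeated merge trimming compounds); recovered waveform shape and
  timings are unaffected, but reported durations under-estimate the full
  envelope extent.
* The DET is built for oscillatory, envelope-modulated events;
  non-oscillatory transients and desynchronization phenomena need a
  different front end.
* Learning is rhythm-specific: one band per run.
* The MANOVA dimension tests use Bartlett's large-sample $\chi^2$; with
  very few trials per class the p-values are approximate.
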