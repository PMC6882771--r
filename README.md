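# burstmdl

Unsupervised modelling of rhythm-specific oscillatory bursts in
single-channel electrophysiology (ECoG, EEG, LFP), for researchers who want
burst *events* — when they occur, how strong they are, and which waveform
they instantiate — rather than windowed power.

## The model

A bandpassed trace switches between a Gaussian rest state and an active
state in which transient micro-events ride on the background. The active
component is a sparse sum of amplitude-weighted, time-shifted, unit-norm
prototype waveforms (a *dictionary* of atoms with heterogeneous durations):

    y(t) = sum_w sum_i alpha_i^w * d_w(t - tau_i^w) + eps(t)

The triples (tau, alpha, omega) — timing, weight, atom index — form a
temporal marked point process (TMPP) with one-sample timing resolution
(2 ms at 500 Hz). The package provides the full unsupervised pipeline:

1. **Simulation** with retained ground truth (`make_burst_atom`,
   `sample_event_plan`, `synthesize`) — the recordings this method targets
   are not publicly deposited, so every stage is testable against
   synthetic truth;
2. **Preprocessing**: zero-phase Butterworth bandpass (`bandpass`; high
   gamma 85–145 Hz is the study default) and anti-aliased resampling
   (`downsample`);
3. **Discriminative embedding transform (DET)**: M-sample snippets are
   mapped to their l2-norms, where the Gaussian background forms a
   chi-distributed bulk and bursts inflate the right tail; snippets with
   norm above `gamma = mu + gamma' * sigma` are selected
   (`extract_snippet_centers`, `embed_snippets`, `fit_background`,
   `select_snippets`);
4. **MDL dictionary learning** (`learn_dictionary`): greedy hierarchical
   clustering of the selected snippets driven by bitsave scores of three
   operators (create / add / merge) over quantized-sequence description
   lengths; shift-invariant, duration-flexible, and the number of atoms K
   is an emergent byproduct — never a hyperparameter;
5. **TMPP encoding and statistics**: `encode` assigns each snippet its
   best atom, timing and weight; per-trial features (event rate, log
   inter-burst intervals, mean timing, log squared weight) feed one-way
   MANOVA dimension tests with canonical projections, silhouettes,
   timing–power correlation, label-shuffle randomization tests, and
   sample-wise TPR/FPR detection scoring.

See `vignettes/burst-dictionary-learning.Rmd` for the methods account and
the design decisions.

## Worked example

Two planted burst prototypes (80 ms at 115 Hz, 120 ms at 100 Hz), 100
trials, one event per atom per trial at 10 dB within-burst SNR:

```r
library(burstmdl)
fs <- 500
dict_true <- list(make_burst_atom(115, 0.08, fs, atom_id = 1L),
                  make_burst_atom(100, 0.12, fs, atom_id = 2L))
set.seed(11)
ev <- do.call(rbind, lapply(1:100, function(tr) data.frame(
  trial = tr, tau_samples = c(250, 750) + sample(-50:50, 2),
  alpha = sqrt(10 * 40) * rlnorm(2, 0, 0.25), atom_id = c(1L, 2L))))
ens <- synthesize(event_plan(ev, 150), dict_true, noise_model(0, 1, 0),
                  100, 1000, fs, seed = 8)

filt <- bandpass(ens$traces, rhythm_bands()$high_gamma, fs)
det  <- det_transform(filt, M = 80, gamma_prime = 1)
det$fit
#> <null_fit (mode, n=999): mu=4.062 sigma=0.6445 gamma'=1 -> gamma=4.706>
det$snippets
#> <snippet_matrix: M=80, Psi=331 selected at gamma=4.706>

dict <- learn_dictionary(det$snippets,
                         learn_config(delta_grid = c(30, 40, 50, 60),
                                      M = 80, seed = 1), fs_hz = fs)
dict
#> <burst_dictionary: K=2 atom(s) of 31/21 samples; 329 greedy steps>

train <- encode(det$snippets, dict, fs_hz = fs)
train
#> <tmpp_train: 331 events over 100 trials at 500 Hz (atom 1: 118, atom 2: 213)>
```

What the numbers mean: the DET fitted the background norm bulk at
mu = 4.06, sigma = 0.64 and kept the 331 snippets above gamma = 4.71; the
MDL learner decided on K = 2 atoms on its own (their supports concentrate
on the high-energy burst cores); encoding produced one event per selected
snippet. Matching the events back to the plan: all 200 planted events are
recovered with a median timing error of 1 sample (2 ms) and
`cor(alpha_hat, alpha) = 0.982`; each learned atom matches a different
ground-truth waveform with normalized cross-correlation above 0.99.

Per-trial features and discrimination statistics then follow:

```r
feats <- tmpp_features(train, window = c(0, 2))
mv    <- one_way_manova(build_design(feats, labels))   # given trial labels
sil   <- silhouette_score(mv$coords, labels)
rnd   <- randomization_test(build_design(feats, labels), n_perm = 1000, seed = 1)
```

A command-line surface wrapping the same functions ships as
`exec/burstmdl` (subcommands `simulate`, `learn`, `encode`, `features`,
`discriminate`; JSON config, seeded, artifacts stamped with the config
hash).

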