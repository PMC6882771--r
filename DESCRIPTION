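Package: burstmdl
Title: MDL Dictionary Learning and Marked Point Process Encoding of
    Oscillatory Bursts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative modelling of single-channel electrophysiological
    recordings (ECoG, EEG, LFP) as sparse, weighted activations of
    prototypical burst waveforms over a Gaussian background. Provides a
    ground-truth simulator, rhythm-specific preprocessing, a discriminative
    embedding transform that separates active-state snippets from
    background by their l2-norms, minimum-description-length (bitsave)
    hierarchical clustering that learns a dictionary of variable-duration,
    unit-norm atoms, temporal marked point process (TMPP) encoding of
    event timings, amplitudes and atom indexes, and the downstream
    discriminability statistics (one-way MANOVA dimension tests with
    canonical projections, silhouettes, timing-power correlation,
    label-shuffle randomization tests, and sample-wise detection scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
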