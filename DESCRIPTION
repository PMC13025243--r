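Package: eegti
Title: Spectral Transcendence Index Pipeline for Low-Density EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end spectral analysis of eyes-closed scalp EEG from
    portable low-density recorders: EDF and delimited-text ingest, zero-phase
    band-pass and mains-notch filtering, non-overlapping 2 s epoching with
    amplitude and EMG artifact screening, Hann-windowed periodogram power
    spectral density estimation, canonical band and sub-band power extraction
    with relative-power normalization, and computation of the Transcendence
    Index, a log-ratio composite of theta-plus-alpha over combined beta power,
    together with its delta-augmented variant. Includes the within-subject
    condition contrast (paired t, Cohen's d with confidence interval),
    descriptive statistics, pairwise-deletion Pearson correlation families
    with Benjamini-Hochberg false discovery rate control, and a fully seeded
    synthetic EEG generator with known band structure, planted condition
    effects, and labeled artifacts for ground-truth validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'bands.R'
    'io.R'
    'preprocess.R'
    'spectral.R'
    'ti.R'
    'stats.R'
    'simulate.R'
    'pipeline.R'
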