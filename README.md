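# eegti

Spectral analysis of eyes-closed, low-density portable EEG and computation
of the **Transcendence Index (TI)** — a log-ratio composite contrasting
internally oriented theta–alpha activity with externally oriented beta
activity — together with the within-subject condition contrast and the
correlation/FDR analyses built on it.

The package is aimed at researchers working with portable 8-channel
recorders (10–20 montage, e.g. Fz, C3, Cz, C4, Pz, PO7, Oz, PO8 at 250 Hz)
who need a reproducible, fully scripted version of the classic
resting-state band-power pipeline: deterministic artifact screening in
place of visual inspection, variance-calibrated PSD estimation, canonical
band extraction, and ratio indices that are invariant to the amplitude
scaling that plagues between-subject comparisons of raw power.

## The index

Band powers are integrals of the power spectral density over canonical
half-open bands (delta 1–4, theta 4–7, low/high alpha 8–10/10–12, low/high
beta 13–20/20–30, low/high gamma 30–45/45–70 Hz). The index and its
delta-augmented variant are

    TI      = ln[ (P_theta + P_alpha_low + P_alpha_high) / (P_beta_low + P_beta_high) ]
    TI_D    = ln[ (P_delta + P_theta + P_alpha_low + P_alpha_high) / (P_beta_low + P_beta_high) ]

Being ratios, both are invariant to global amplitude rescaling and
identical whether absolute or relative (normalized) band powers are
supplied. The processing chain is: 0.5–70 Hz zero-phase band-pass → 50 Hz
notch → non-overlapping 2 s epochs → amplitude/EMG artifact screening →
Hann-windowed periodogram averaging → band integration → channel
aggregation → TI. Inference: paired t with Cohen's d = t/√n and a
normal-approximation CI; pairwise-deletion Pearson correlation families
with Benjamini–Hochberg FDR at q = 0.05.

See `vignettes/transcendence-index.Rmd` for the full methods account,
including every numerical design choice.

## Worked example

Plugging published group-mean band powers into the index as a single
pseudo-subject:

```r
library(eegti)
tab <- data.frame(subject = "group_mean", condition = "pooled",
                  channel = "mean:all",
                  band  = c("delta", "theta", "alpha_low", "alpha_high",
                            "beta_low", "beta_high"),
                  power = c(9327.87, 3849.94, 5469.42, 4729.73,
                            2109.69, 1415.47))
computeTI(tab)
#>      subject condition       ti                     variant
#> 1 group_mean    pooled 1.382632 standard|log=e|agg=mean:all
computeTI(tab, variant = "delta_augmented")$ti
#> [1] 1.891825
```

`ti = 1.38` says that theta–alpha power is about e^1.38 ≈ 4 times combined
beta power at these group means; adding delta raises the ratio to ≈ 6.6.

A complete synthetic study — simulate recordings with a planted 1.25×
theta–alpha effect in the "prayer" condition and typical artifact rates,
extract features, and analyze:

```r
dir <- tempfile()
spec <- studySimSpec(nSubjects = 8, blockS = 120, seed = 1,
                     spikeRate = 0.055, emgRate = 0.035)
st  <- simulateStudy(spec, dir)
cfg <- runConfig(manifest = st$manifest, outDir = file.path(dir, "out"))
feat <- runExtract(cfg)
#> extract S01/prayer: 5/60 epochs rejected (8.3%)
#> extract S01/relaxation: 6/60 epochs rejected (10.0%)
#> ...
res <- runAnalyze(cfg, feat)
head(res$ti, 2)
#>   subject  condition        ti                     variant
#> 1     S01     prayer 1.0549638 standard|log=e|agg=mean:all
#> 2     S01 relaxation 0.8431721 standard|log=e|agg=mean:all
res$contrast
#>   n    t df        p    d d_lo d_hi mean_diff
#> 1 8 39.8  7 1.64e-09 14.1 7.15   21     0.215
```

The rejection fractions land in the 8–12% range the screening is calibrated
to, and the mean paired TI difference (0.215 here) recovers the planted
ln 1.25 = 0.223 up to the window-smearing bias discussed in the vignette.
(The huge d is expected: these synthetic subjects share an identical
condition effect, so the difference variance is estimation noise only.)

A command-line wrapper with `simulate` / `extract` / `analyze` subcommands
lives at `inst/cli/ti.R`:

```sh
Rscript inst/cli/ti.R simulate --subjects 10 --seed 1 --out study --artifacts
Rscript inst/cli/ti.R extract  --manifest study/manifest.tsv --out feats
Rscript inst/cli/ti.R analyze  --features feats/features.tsv --out results \
                               --covariates study/covariates.tsv
```

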