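---
title: "Methods: spectral pipeline and the Transcendence Index"
author: "eegti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral pipeline and the Transcendence Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegti)
```

## The measurement problem

Eyes-closed scalp EEG from portable low-density recorders is dominated by a
handful of oscillatory bands whose *relative* balance — not their absolute
amplitude — carries the signal of interest. Absolute power varies between
people for non-neural reasons (skull conductivity, electrode impedance,
anatomy), so composite indices are built as ratios. The Transcendence Index
(TI) implemented here summarizes the balance between internally oriented
slow activity and externally oriented fast activity:

$$\mathrm{TI} = \ln\frac{P_\theta + P_{\alpha_{low}} + P_{\alpha_{high}}}
                        {P_{\beta_{low}} + P_{\beta_{high}}},$$

with a delta-augmented variant that adds $P_\delta$ to the numerator. Band
powers $P_i$ are integrals of the power spectral density (PSD, in
µV²/Hz) over canonical intervals: delta 1–4, theta 4–7, low alpha 8–10, high
alpha 10–12, low beta 13–20, high beta 20–30, low gamma 30–45, high gamma
45–70 Hz, all half-open $[f_{low}, f_{high})$.

Because the index is a log-ratio it inherits three exact identities that the
test suite exercises: it is invariant to any global amplitude rescaling of
the recording; it is identical whether absolute or relative (normalized)
band powers are supplied, since the normalizer cancels; and multiplying
every numerator band by $1+\varepsilon$ shifts it by exactly
$\ln(1+\varepsilon)$. The last identity is what makes a synthetic-data
validation of the full pipeline possible.

### Why the log sits on the composite ratio

Descriptive statistics of the published index constrain where the logarithm
is applied. Plugging the group-mean sub-band powers into
$\ln[(\theta+\alpha_{low}+\alpha_{high})/(\beta_{low}+\beta_{high})]$ gives
1.3827 against a printed participant mean of 1.36, and the delta-augmented
plug-in gives 1.8918 against 1.87 — both within 0.05, with the residual on
the side predicted by averaging a concave transform (a composite of means
exceeds a mean of composites). Raw ratios (≈4.0 and ≈6.6), a log of
broad-band ratios (≈1.60), and a ratio of logs (≈2.24) are all inconsistent
with the printed scale. The package therefore computes the natural log of
the composite ratio; exact equality with printed participant means is not
expected and not asserted.

The numerator uses the two alpha *sub-bands* rather than a broad alpha band,
for the same plug-in consistency reason. Broad-band descriptives in the
source tables are in fact inconsistent with the sums of their sub-bands and
sit close to sub-band means; since the broad-band computation is not
defined anywhere, the package keeps sub-bands canonical and offers both
direct integration and sub-band aggregation for broad-band reporting,
labelling which mode produced a value instead of asserting either as
authoritative.

## The processing chain

`runExtract()` applies, per recording:

1. **Band-pass 0.5–70 Hz**, fourth-order Butterworth (second-order
   high-pass cascaded with second-order low-pass), applied forward and
   backward so band power is not distorted by group delay. A zero-phase
   double pass squares the magnitude response, so the low-pass digital
   corner is widened by the factor $0.9^{-1}(10^{0.05}-1)^{-1/4} \approx
   1.52$ that keeps the double-pass response within 1 dB of unity at
   $0.9\,f_{high}$; the high-pass corner needs no compensation at these
   ratios. Attenuation at Nyquist is structural (the bilinear transform
   places low-pass zeros there).
2. **Mains notch**, second-order IIR with quality factor 30 (default 50 Hz;
   60 Hz via `mains = 60`), also zero-phase.
3. **Epoching** into non-overlapping, contiguous 2.0 s segments (500
   samples at 250 Hz, hence 0.5 Hz resolution — every canonical band edge
   falls on a bin boundary). "Approximately 2 s" is fixed at exactly 2.0 s
   for reproducibility; trailing partial segments are discarded.
4. **Artifact screening** replacing visual inspection with deterministic
   rules: absolute amplitude > 100 µV or peak-to-peak > 200 µV on any
   channel flags an epoch "amplitude"; a robust z-score > 3 of the epoch's
   30–110 Hz power — median/MAD across the block's epochs, per channel,
   computed on the log scale where power is variance-stabilized — flags it
   "emg". The thresholds are conventional portable-EEG values, configurable
   via `artifactOptions()`; an override list of manually rejected epoch
   indices is accepted for parity with human screening. Rejection fractions
   are reported per recording block.
5. **PSD estimation**: per retained epoch, demean, periodic Hann window,
   FFT, one-sided periodogram compensated by the mean squared window value;
   densities averaged over epochs (a Welch estimate with zero overlap,
   matching the segmentation exactly rather than a generic 50%-overlap
   default). The compensation makes the estimate variance-calibrated:
   integrating the density over frequency recovers the time-domain variance
   (Parseval, verified to 1% on stationary input), a 15 Hz sinusoid of
   amplitude $A$ integrates to $A^2/2$, and white noise of variance
   $\sigma^2$ integrates to $\sigma^2$.
6. **Band integration** over bins whose *centre* satisfies
   $f_{low} \le f < f_{high}$; DC and Nyquist bins never contribute. The
   half-open convention makes band integration exactly additive and puts a
   bin at, say, 4.0 Hz into theta, not delta. The canonical band set leaves
   gaps at [7,8) and [12,13) Hz; they are preserved by default
   (`defaultBands(bridgeGaps = TRUE)` closes them for sensitivity
   analyses). High-gamma rows are flagged low-confidence whenever the
   low-pass corner or the notch lies inside the band.

`runAnalyze()` then aggregates channels (default: mean over all channels —
the least-assumptive reduction given that no channel-weighting is defined
for the index; a posterior subset `c("Pz","PO7","Oz","PO8")` is available
for alpha-weighted analyses), computes the requested TI variant per subject
and condition, contrasts conditions within subject, and correlates TI with
covariates.

### Numerical edge handling in the filters

Forward–backward filtering is protected against edge transients by
reflection padding: odd (point) reflection for the band-pass, whose
transients are broadband and short. The notch is different: its resonance
rings for hundreds of samples, and any waveform discontinuity at the
data/pad junction — including the DC step an odd reflection introduces —
rings back into the data. The notch therefore pads with an autoregressive
continuation of the boundary (Burg fit, order ≤ 16, on a segment of four
pad lengths): a sinusoid continues exactly, noise continues as stationary
noise of the same colour. With this padding a 10 µV mains sinusoid leaves a
residual below 0.001 µV across the entire record, while a 47 Hz neighbour
is attenuated by less than 5%.

## Inferential conventions

* **Paired contrast**: t on within-subject differences, two-tailed p on
  $n-1$ df. The paired effect size is $d = t/\sqrt{n}$ with the
  normal-approximation interval $d \pm 1.96\sqrt{1/n + d^2/2n}$ — the
  convention that exactly reproduces the published effect size and interval
  from the published t and n. Identically zero difference vectors return
  $t=0, p=1, d=0$; zero-variance non-zero differences are a degenerate-case
  error rather than an infinite t.
* **Descriptives**: sample SD, and the small-sample-adjusted
  Fisher–Pearson $G_1$/$G_2$ shape statistics (the SPSS convention, matched
  against an independent implementation in the tests). Constant vectors are
  flagged, not errors.
* **Correlation families**: pairwise-deletion Pearson r with two-tailed p
  from the t transform on $n_{ij}-2$ df; per-pair complete-case counts are
  reported (missing cells in covariates are first-class). One table = one
  family for multiplicity control.
* **Benjamini–Hochberg FDR** at q = 0.05 within each family, implemented as
  the explicit step-up pass that yields both monotone rejection flags and
  adjusted p-values; the test suite checks it exhaustively against a
  brute-force statement of the definition over all p-multisets of length
  ≤ 8 on a fixed grid (equivalence classes under permutation, with
  permutation equivariance tested separately) and against the reference
  implementation in `stats`. Reports mark nominal-only significance (`*`,
  `**`) distinctly from FDR-surviving pairs (`#`).

## What the synthetic generator emulates

`studySimSpec()` + `simulateStudy()` generate the study conditions: two
eyes-closed 5-minute blocks ("prayer", "relaxation") per subject, 8-channel
10–20 montage at 250 Hz, written as EDF.

* **Band structure.** Each channel is a sum of independent band-limited
  Gaussian noise components (ideal frequency-domain masking, exact target
  variance) plus a $1/f$ background at 10% of the summed band variance.
  Default band variances preserve the relative band composition of the
  published group-mean spectra, scaled to a total of ≈ 71 µV² — a
  scalp-realistic amplitude at which artifact-free EEG stays comfortably
  below the 100 µV screening threshold, as clean EEG should. The published
  raw-power scale itself is an arbitrary device unit and would correspond
  to ±300 µV signals if read as µV² directly.
* **Between-subject variation** is log-normal (SD 0.4 on the log scale,
  matching the strong right skew of raw power), drawn once per subject and
  shared across conditions, as in a paired design.
* **Condition effect.** In the "prayer" condition all numerator-band
  content — the theta/alpha components *and* the background's share inside
  those bands — is multiplied by $1+\varepsilon$ (default 0.25), making the
  population TI difference exactly $\ln(1+\varepsilon)$ by construction.
* **Artifacts.** Spikes (500 µV, 100 ms biphasic) and EMG bursts (0.5 s of
  40–110 Hz noise at 30 µV RMS) are injected into epochs chosen without
  replacement, with an exact injection log. The typical-yield preset
  (`typicalArtifactRates()`: 5.5% spikes + 3.5% EMG) was chosen so that
  injected contamination plus the screening rules' small false-positive
  rate centers the 8–12% rejection yield reported for conservatively
  screened portable EEG.
* **Covariates** (anxiety and Big Five-style scores) are generated at
  realistic means and SDs with user-specified true correlations to the
  subjects' true TI, enabling power and type-I checks of the
  correlation/FDR stage; the default is the null.

Three levels of ground truth are recorded per band and channel: the
component variance, the physical in-band variance (component plus the
background's analytic in-band share), and the *expected estimate* — the
expectation of the 2 s Hann periodogram given the generated spectrum. The
last matters because the Hann window smears power across roughly one bin at
each band edge, so the expected estimate of a narrow band (low alpha spans
four bins) sits 10–15% away from its physical variance. That smearing is a
property of every windowed estimator at this epoch length, not of the
generator; validating estimates against their analytic expectation keeps
the 10% recovery check meaningful. The same smearing is why the recovered
mean condition effect sits about 0.01–0.015 below $\ln 1.25$: the large,
unscaled delta component leaks a little power into the adjacent theta band
and dilutes the planted ratio. The end-to-end recovery test asserts the
documented 0.02 tolerance around $\ln 1.25 = 0.22314$ at 40 subjects and
150 clean epochs per condition.

What the generator does *not* emulate: spatial correlation between
channels (channels are independent unless per-channel gains are supplied),
volume conduction, ocular dipole geometry, non-stationarity within a block,
and reference-montage effects. Passing tests therefore demonstrate that the
pipeline measures what it claims on band-structured signals with known
truth — not that the index is biologically valid, which requires real
recordings and external criteria.

## Problem sizes and runtime choices

The test suite validates at the study's own scale where that is what the
claim is about: the condition-effect recovery uses 40 subjects × 2
conditions × 300 s blocks; the artifact yield check uses four 300 s blocks;
the null-FDR simulation uses 2000 replicates of a 39 × 10 family; power and
type-I surrogates for the covariate stage use 100 and 200 seeded
replicates. Unit tests use 10–60 s recordings, which are ample for the
closed-form oracles.

## Known limitations

* EDF support is deliberately minimal: one sampling rate across signals,
  16-bit samples, no annotation channels (EDF+ annotations are ignored).
* Gamma-band estimates above the notch and near the low-pass corner are
  flagged low-confidence rather than corrected; no EMG spectral
  subtraction is attempted.
* "Approximately 2 s" epochs are fixed at exactly 2.0 s; other epoch
  lengths change the spectral resolution and hence the smearing bias
  discussed above.
* The d = t/√n convention and its normal-approximation CI are reported for
  comparability; they are not the only defensible paired effect-size
  definitions.
* Amplitude thresholds replace human screening with deterministic rules;
  the override mechanism exists precisely because no fixed threshold
  reproduces expert judgement on real data.
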