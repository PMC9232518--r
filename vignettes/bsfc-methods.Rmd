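---
title: "Detecting tumor cell clusters in backscatter flow cytometry traces"
author: "bsfc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tumor cell clusters in backscatter flow cytometry traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsfc)
```

## The measurement and the problem

Backscatter flow cytometry (BSFC) pushes whole blood through a narrow
microfluidic channel (30 × 30 µm²) across a thin illumination slit and
records, at 60 kHz, the light scattered back at three wavelengths
(405, 488, 633 nm) plus two fluorescence bands (FP1 green, FP2 red).
Circulating tumor cell clusters (CTCCs) — aggregates of two or more
tumor cells — are extraordinarily rare but carry a disproportionate
metastatic risk, so the goal is to recognize their scattering pulses in
blood without any label. In the training data the tumor cells express
GFP, so the FP1 channel provides ground truth; the classifier itself
sees only the scattering channels.

Two physical facts organize the whole pipeline:

1. **Transit physics sets pulse width.** Under plug flow the velocity is
   $v = Q/A$; with $Q = 3\,\mu\mathrm{L/min}$ and $A = 900\,\mu\mathrm{m}^2$,
   $v = 55.6$ mm/s. An object of diameter $d$ crossing a slit of width
   $s = 5\,\mu\mathrm{m}$ produces a pulse of duration
   $\Delta t = (d + s)/v$. The largest expected single cell
   (15 µm) gives $\Delta t = 3.6\times 10^{-4}$ s, i.e. 21 samples at
   60 kHz — so pulses **narrower than 20 points** are attributed to
   single cells or leukocytes and removed before classification, a gate
   equivalent to a ~14 µm object size.
2. **Blood scatters.** The background of whole blood dominates the SNR
   budget; the three scattering channels are therefore summed (after
   normalization) into one cumulative signal, trading independent noise
   for coherent pulse amplitude.

## Pipeline stages

**Filtering.** Each 1.5-min segment is band-pass filtered (second-order
Butterworth, 50–6000 Hz) forward–backward, so the response magnitude is
squared and the phase is zero: peak locations are unchanged by
filtering. We subtract the channel mean before filtering; DC lies
outside the passband anyway, and removing it first keeps the
forward–backward edge transient from leaking a large start-up artifact
into the segment. The first and last 1000 samples are still excluded
from peak calling, since the high-pass corner at 50 Hz has a transient
of a few hundred samples.

**Daily power normalization.** Laser power at the sample drifts from day
to day. Each day a 99% diffuse-reflectance standard (spectralon) is
measured at reduced power, giving per-wavelength factors
$\mathrm{Norm}(\lambda) = I_{\lambda,\text{Spectralon}} \cdot
P_{\lambda,\text{Sample}} / P_{\lambda,\text{Spectralon}}$.
We divide each scattering channel by its factor — the direction of the
arithmetic is our choice (only the factor itself is prescribed by the
calibration protocol); division makes traces dimensionless and
day-comparable, and it commutes with the (linear) filter.

**Peak detection.** The threshold is mean + 3 sd of the *entire*
segment. All strict local maxima are candidates (plateaus resolve to
their leftmost sample — a deterministic tie-break), maximal
supra-threshold runs define peak ranges, and each range keeps exactly
its tallest candidate. FWHM is measured above the segment-mean baseline
with linear interpolation at the half-maximum crossings; AUC sums the
baseline-subtracted signal over the range. A 5σ threshold is exposed as
an option for the fluorescence channel but yields the same peaks in
practice, since GFP pulses are far above either threshold.

**Labeling.** A gated scattering peak is a CTCC iff its threshold
range overlaps an FP1 peak's range; range overlap is parameter-free,
which is why we prefer it to a tolerance window. CTCC feature vectors
are centered on the FP1 location (the most reliable estimate of event
center); NC vectors on the scattering peak location. FP1 peaks with no
scattering match are reported separately — these are real fluorescence
events whose scattering signature was too weak, and they bound the
label-free sensitivity from above.

**Features.** Each segment is normalized per channel by one of four
methods (`MAX_PEAK`, `MEAN_PEAK_5SIGMA`, `ZERO_MEAN`, `ZERO_MEDIAN`),
then ±13 points around the event center are taken from each scattering
channel and concatenated in fixed 405, 488, 633 order — 81 values for
three channels. The ±13 window is exactly wide enough to hold the
20-point minimum cluster width. `ZERO_MEAN` — subtract the segment
mean, divide by the segment sd — is the default because it is invariant
to channel gain and offset, i.e. independent of illumination power; the
package asserts this invariance as a test. Normalization statistics
include the peak samples (peaks are a negligible fraction of 5.4 M
samples). The two peak-based methods apply to the scattering channels
only: fluorescence channels carry no scattering peaks and never enter
the feature vectors (FP2 is excluded from all analysis because of
GFP crosstalk). Events whose window would cross a segment edge are
dropped, never padded — padding would fabricate signal, and the loss is
27 samples out of millions.

**Classifier.** Labeled events are extremely imbalanced (tens of CTCCs
against thousands of NCs per day). We therefore train an ensemble of 50
Gentle AdaBoost tree models, each on the *same* CTCC set plus an
independent equal-size NC sample drawn without replacement — every
member sees balanced classes while the ensemble collectively sees a wide
range of NC behavior. Gentle AdaBoost fits each weak learner (a
regression tree capped at 102 internal splits) to the ±1 labels by
weighted least squares, updates the additive score with shrinkage
ν = 0.899, and reweights $w_i \leftarrow w_i e^{-y_i \nu f_m(x_i)}$ for
84 cycles. The gentle variant's leaf values are weighted class-label
means, bounded in [−1, 1], which keeps updates stable on noisy data. We
implement the boosting loop directly (the shrinkage convention —
multiplying the weak learner — follows the common ensemble-toolbox
convention) and delegate tree growing to `rpart` with weighted anova
fitting; the split cap is enforced by pruning to the largest
complexity-table subtree with ≤ 102 splits.

**Cascade evaluation.** The test set is fed to one model at a time;
only events predicted positive survive to the next model. Survivor sets
are nested, so specificity is non-decreasing and sensitivity
non-increasing in the stage count — performance converges to a limit as
models are added, which is the mechanism that lets 50 balanced models
suppress false positives without retraining. Model order is training
order; it is recorded and seedable so order sensitivity can be studied.

**Split harness.** Training pools of 13 days yield
$\binom{13}{10} = 286$ leave-days-out training sets;
`run_evaluation_suite()` trains a cascade per plan against a fixed
held-out test set and reports mean ± sample sd of purity, sensitivity,
specificity and accuracy (Eqs. below). The 3 left-out days of each plan
are a validation set used only for sanity reporting, never for model
selection — hyperparameters are fixed.

**Metrics.** With CTCC positive:
purity = TP/(TP+FP), sensitivity = TP/(TP+FN),
specificity = TN/(TN+FP), accuracy = (TP+TN)/total, each ×100.
Undefined ratios (zero denominators) surface as `NA` with a warning,
never as silent zeros; aggregation skips them.

## The synthetic-data generator

No public raw traces exist, so the simulator is a first-class module
that emulates the spiked whole-blood experiments:

- **Baseline**: per-channel level, slow sinusoidal drift
  (amplitude 0.5, period 30 s), white Gaussian noise; a
  `blood_background_scale ≥ 1` multiplies scattering-channel noise to
  reproduce the blood-vs-media SNR contrast qualitatively.
- **Pulses** are Gaussian with σ = FWHM/2.355. No pulse shape is
  prescribed by the physics beyond unimodality; a Gaussian is the
  simplest form consistent with slit convolution.
- **Event taxonomy**: CTC (single tumor cell, GFP-positive), CTCC
  (cluster, n ≥ 2, GFP-positive), NC (scatter only), GFP_ONLY
  (fluorescence with no scattering signature, default 5% of tumor
  events — such events exist in real data but at an unreported rate).
- **Spectral ratios**: tumor events scatter strongest at 405 nm
  (1 : 0.6 : 0.5 across 405 : 488 : 633); NC events are 633-dominant
  (0.5 : 0.6 : 1). This makes the classes separable but not trivially
  so, consistent with the observation that CTCC signal originates
  primarily from the 405 nm channel.
- **Sizes**: cluster cell counts follow the observed spiked-sample
  distribution (65.8% singles, 17.1% two-cell, 15.0% 3–6, 1.4% 7–9,
  0.7% >9); a cluster of n cells presents a diameter
  $\propto n^{1/3}$, except two-cell clusters whose orientation is
  ambiguous and whose presented length spans one to two cell diameters.
  Single cells are drawn at 8–13 µm so the 20-point gate removes them.
- **Days**: each simulated day draws per-wavelength illumination power
  factors in [0.7, 1.3] together with the matching calibration record,
  so daily normalization is exercised end to end; scattering channels
  are jittered by ±1 sample to emulate inter-wavelength time shifts.
- **Seeding**: one master seed; every stochastic sub-operation derives
  its own seed through a counter-based splitter (`derive_seed`), so
  runs are bit-for-bit reproducible and stages independently
  replayable.

What the simulator does **not** model: Mie scattering or any real
optics (amplitudes are phenomenological), parabolic flow profiles (the
transit calculation assumes plug flow), cell-shape asymmetry, overlap
statistics of real blood, or the empirical SNR distribution of CTCCs in
blood — none is published. Passing tests on synthetic data therefore
demonstrate the *correctness of the algorithms* under known ground
truth, not field performance on real traces; the published
real-data performance (sensitivity ≈ 92.5%, specificity ≈ 95.9%,
purity ≈ 82.8%, accuracy ≈ 95.4% across 286 training-set combinations)
requires the original raw traces, which are not public.

## The synthetic benchmark

The default `pipeline_config()` fixes the benchmark conditions: 5
training and 2 test days, two 10-second segments per day (600,000
samples each — long enough for stable segment statistics, small enough
to run on a laptop), 30 cluster (≥ 3 cells), 10 single-cell and 300 NC
events per day, cumulative-signal SNR ≈ 9 for a single-cell-scale
pulse, zero-mean normalization, all three scattering channels, and a
50-model cascade with the default hyperparameters (84 cycles,
102 splits, ν = 0.899). Classification is benchmarked on clusters of
≥ 3 cells because two-cell clusters cannot be reliably separated from
large single cells by width. On these conditions the cascade reaches
sensitivity ≥ 90% and specificity ≥ 95% (asserted in the test suite,
recomputed by `scripts/acceptance.R`).

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 1), verbose = TRUE)
unlist(res$metrics)
```

## Numerical choices and degenerate inputs

- `width_in_points()` floors $\Delta t f_s$ — conservative for a
  minimum-width gate, and it reproduces the printed 21-point width from
  its own transit time.
- Thresholding a constant (zero-variance) segment yields threshold =
  mean and no peaks; zero-variance channels make moment normalization
  error out with the segment named.
- FWHM falls back to the threshold-range width if the half-max level
  sits below the baseline.
- Expected spike-in counts round to the nearest integer; the reference
  table's printed counts differ by one in places, so consistency checks
  allow ±1.
- Ties everywhere (plateau maxima, equal peak heights, equal label
  overlap) resolve to the earliest index, deterministically.

## Limitations

- Classification below three cells per cluster is out of scope, as is
  variable-length feature extraction for very large clusters (a ±13
  window truncates them).
- The cascade's purity depends strongly on the CTCC/NC imbalance of the
  test set; synthetic-benchmark purity is not comparable to real-data
  purity.
- Only the Gentle-boost ensemble path is implemented; other classifier
  families can be plugged in at `evaluate_cascade()` (any list of
  models with a `predict(..., type = "class")` method works), but no
  alternative is shipped.
- Trace persistence uses (gzipped) CSV; at full 1.5-min segments these
  files are large, and a binary format would be preferable for
  production acquisition volumes.
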