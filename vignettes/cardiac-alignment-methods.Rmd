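---
title: "Cardiac-aligned fMRI waveforms: methods and design choices"
author: "pulseAlign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac-aligned fMRI waveforms: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseAlign)
```

## The problem

Every heartbeat drives a pressure wave through the cerebral arteries,
capillaries, veins and CSF spaces. Fast fMRI acquisitions (simultaneous
multislice, TR well below the cardiac period) sample this pulsation many
times per heartbeat, but each slice of each volume is measured at a
different moment of the cardiac cycle. pulseAlign retrospectively aligns
every slice's samples to the heartbeat peaks measured by a fingertip pulse
oximeter (PPG), averages them into a sub-second cardiac-gated waveform per
voxel, scores the test–retest reliability of that waveform, models it with
a low-rank SVD decomposition, and maps where in the cardiac cycle each
voxel's signal reaches its minimum and maximum. Blood-dominated voxels dip
near systole; CSF-dominated voxels rise — the timing and sign of the
extremum distinguish the compartments without any anatomical prior.

## The procedure

1. **PPG peak detection** (`detectPeaks()`). The PPG trace is low-pass
   filtered at 5 Hz with a third-order Butterworth filter applied forward
   and backward (zero net phase shift). The heartbeat period is the lag of
   the highest autocorrelation peak inside a physiological band (default
   40–150 bpm); peak detection then enforces a minimum peak separation of
   70% of that period. Detected peak times are mapped to the fMRI clock via
   the recording's start-time offset.
2. **Heart-rate stability check** (`rmssdHrv()`). RMSSD — the root mean
   square of successive inter-beat-interval differences — is computed over
   contiguous 20 s windows. If the maximum RMSSD stays below one slice
   acquisition duration (50 ms), beat-to-beat variability is small relative
   to the temporal bin width and no within-scan correction is applied (and
   none is implemented: the method deliberately avoids per-beat time
   warping).
3. **Percent modulation** (`percentModulation()`). The first three volumes
   are discarded; each voxel is converted to percent modulation around its
   temporal mean and a least-squares line is removed. Background voxels
   (non-positive mean) are masked, not errors.
4. **Peak-relative binning** (`alignToPeaks()`, `alignVolume()`). Each
   retained sample is assigned its time relative to every heartbeat peak
   whose epoch window (default cycle fraction −0.5 to +1.0) contains it —
   at most two assignments per sample. Samples pool into fixed-width bins
   one slice-acquisition window wide (50 ms for the SMS protocol), averaged
   separately over even-indexed (0, 2, 4, …) and odd-indexed beats.
5. **Reliability** (`reliabilityR2()`). The zero-referenced
   R² = 100·(1 − Σ(yᵢ−fᵢ)²/Σyᵢ²) between the even (y) and odd (f) bin
   means, over bins populated in both halves. The reference is zero, not
   the mean, because the percent-modulation waveforms are already zero-mean
   and a mean reference would be arbitrary. The score is ≤ 100 and
   unbounded below; independent-noise voxels concentrate near −100 (their
   expected residual power is twice their data power), so reliable voxels
   (conventionally R² > 50 for single-run maps) stand far out of the null.
6. **Waveform model** (`buildWaveformMatrix()`, `svdDecompose()`,
   `cvVarianceExplained()`, `fitBetas()`, `rrmse()`). Odd-beat waveforms
   are linearly resampled onto a standardized cycle-fraction grid,
   unit-normalized and scaled by their R², so the most reliable voxels
   dominate the SVD. Cross-validated variance explained is measured by
   projecting the even-beat matrix onto the leading odd-half components;
   the number of components is chosen as the smallest k exceeding 70%
   held-out variance (two in practice; the package default is fixed at
   k = 2). Across subjects, per-subject components can be stacked and
   decomposed again (`canonicalComponents()`, leave-one-subject-out) to
   give canonical components. Per voxel, least-squares weights β fit the
   waveform as Y = β₁pc₁ + … + βₖpcₖ + ε, and the fit is scored by
   Rrmse = Mrmse/Drmse — RMS model error against the even half over RMS
   even/odd difference. Rrmse < 1 means the model predicts the held-out
   half better than the data predict themselves; a perfect model of a
   signal with additive Gaussian noise has expectation 1/√2 ≈ 0.707.
7. **Extrema timing** (`extremaTimes()`). The modeled waveform's global
   minimum and maximum inside a search window (default −0.5 to 0.66 of the
   cycle) are refined by three-point parabolic interpolation and reported
   in cycle fraction, masked at the reliability threshold.
   `cycleFractionToTime()` converts fractions to milliseconds (0.2 of a
   cycle at 60 bpm is 200 ms).
8. **ROI aggregation** (`aggregateRoi()`, `aggregateZones()`,
   `amplitudeGradientTest()`). Waveforms average over user-supplied label
   volumes; arterial territories (ACA/MCA/PCA) stratified by distance from
   the arterial input are summarized by their modulation amplitude, with a
   descriptive monotonicity report (no inferential statistic is attached).

`runPipeline()` orchestrates all stages from a JSON config or an R list
and writes NIfTI maps, TSV tables and a JSON report;
`inst/cli/pulsealign` is a thin shell wrapper over `simulateDataset()` and
`runPipeline()`.

## Assumptions

- Heart-rate variability is low (RMSSD below one bin width), so pooling
  samples by time-since-peak without per-beat time normalization is valid.
  Bin edges are fixed in seconds; the cycle-fraction axis uses the global
  autocorrelation period, not per-beat intervals.
- No slice-timing or motion correction is applied; the method depends on
  preserving each voxel's raw sampling times.
- The PPG peak is a consistent (if delayed) marker of systole; all timings
  are relative to it, so a constant PPG-to-brain delay is irrelevant.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| filter cutoff / order | 5 / 3 | Hz / – | removes high-frequency noise while preserving the systolic peak |
| heart-rate band | 40–150 | bpm | excludes the zero-lag autocorrelation peak and harmonics |
| min peak distance | 0.7 | cycle fraction | rejects double-counted beats |
| peak prominence | 0.25 | fraction of IQR | rejects dicrotic-notch secondary maxima |
| HRV window / threshold | 20 / 50 | s / ms | ultrashort-window RMSSD against one bin width |
| dropped volumes | 3 | volumes | longitudinal magnetization steady state |
| epoch window | (−0.5, 1.0) | cycle fraction | covers the displayed waveform range plus a full forward cycle |
| bin width | slice duration | s | the native temporal resolution of one slice group |
| grid size | 128 | points | standardized cycle-fraction abscissa for modeling |
| reliability threshold | 50 | R² points | single-run display/masking convention |
| CV threshold / k | 70% / 2 | – | smallest component count with >70% held-out variance |
| search window | (−0.5, 0.66) | cycle fraction | display range of the modeled responses |

## Numerical choices

- **Bin centers** sit on multiples of the slice duration relative to the
  peak (centers, not edges, at −0.5 s, −0.45 s, … for the SMS protocol).
  With an acquisition grid commensurate with the heartbeat the sampling
  comb then lands exactly on bin centers, making the binned waveform exact
  for a noiseless beat-locked signal; the half-open edge convention would
  bias that case by half a bin.
- **Missing bins** (empty in either half) are excluded pairwise from R².
  Whole-volume maps additionally require every core-cycle bin (fraction
  0–1) populated in both halves; slices without that coverage are masked.
- **Component signs** are fixed by flipping each component so its value at
  cycle fraction 0 is negative (blood dips at the PPG peak); SVD signs are
  otherwise arbitrary and cross-subject stacking needs a deterministic
  rule.
- **Negative-R² voxels** are pruned from the waveform matrix rather than
  entered with flipped sign.
- **Extremum ties** resolve to the earliest time; refinement is clamped to
  half a grid step. Flat waveforms have undefined extrema and are masked.
- **Degenerate inputs** raise classed conditions (`pa_too_short`,
  `pa_cycle_not_found`, `pa_insufficient_beats`, `pa_geometry_error`,
  `pa_model_error`, `pa_config_error`, `pa_input_error`) rather than bare
  errors; background voxels and empty labels are masked, not errors.
- The autocorrelation runs on the **filtered** trace (configurable): the
  5 Hz low-pass strengthens the fundamental against broadband noise.
- Per-bin averages weight **samples** equally (not beats): a bin receiving
  two samples from one long beat counts both.
- In single-run mode the pipeline's "canonical" components are the run's
  own leading odd-half components; true canonical components require
  several runs/subjects via `canonicalComponents()`.

## What the synthetic generator emulates — and what it does not

`simConfig()` defaults reproduce the fast-SMS study conditions: 60 bpm
with 10 ms beat-to-beat Gaussian jitter, 220 s of 100 Hz PPG, 8×8×40
voxels acquired as 5 simultaneous groups of 8 slices (TR 250 ms, 50 ms
windows, 878 volumes), and four voxel classes — artery-like (negative
transient peaking at cycle fraction −0.15), vein-like (−, at 0.0),
CSF-like (+, at +0.05) and null — rendered as skewed-Gaussian transients
(onset width 0.08, return width 0.18 of a cycle; steep arrival, shallow
return) of equal 1.5% amplitude, on a baseline of 100 with linear drift
and Gaussian noise.

Two generator features deserve emphasis:

- **Slow heart-rate drift.** Inter-beat intervals carry a low-frequency
  modulation (±1.5% at 0.01 Hz) besides white jitter. Real heart rates
  drift on these scales, and the drift matters structurally: at exactly
  60 bpm the cardiac period is four TRs, so without drift each slice would
  sample only four fixed phases per cycle and most temporal bins would
  stay empty. The drift sweeps the sampling comb across the whole cycle
  while adding <1 ms to RMSSD.
- **Noise calibration.** The default noise (1.0% of baseline per sample)
  was set by simulation so template voxels land at a median even/odd R²
  near 70 — the reliable-voxel regime the method targets. The closed-form
  first-order calibration (`calibrateNoiseSd()`, which equates expected
  residual and data power per bin) returns ~1.5% for the same target
  because it neglects unequal bin occupancy and within-bin waveform slope.

The generator does **not** simulate the biophysical coupling (waveforms
are imposed directly in percent units, not driven through a T1-weighting
forward model), respiration, vasomotion, motion, multi-echo acquisition or
k-space/EPI artifacts. Passing recovery tests on synthetic data therefore
demonstrates the correctness of the alignment/modeling machinery under
known ground truth — not robustness to everything real data contain.
`gradientEchoSignal()` provides the steady-state spoiled gradient-echo
signal equation and its T1/T2* sensitivities for protocol comparisons, but
plays no role in waveform generation.

## Test problem sizes

The test suite validates the full pipeline on an 8×8×40-voxel, 878-volume
synthetic run (the study geometry at reduced in-plane matrix) and smaller
4×4×40 and 2×2×40 grids elsewhere; the Monte-Carlo checks use 10⁴
simulated voxels for the Rrmse calibration and 2000 voxels for the
cross-validated variance check. These sizes keep the suite's runtime
modest while leaving the per-voxel statistics unchanged (every statistic
here is voxel-local or a median over hundreds of voxels).

## Known limitations

- Single-run canonical components are self-derived; leave-one-subject-out
  validation needs multiple subjects.
- The R² masking convention requires full core-cycle coverage; very short
  runs, or acquisitions whose TR is commensurate with a perfectly steady
  heartbeat, mask out (this mirrors a real limitation of the method, which
  relies on natural heart-rate variation for phase coverage).
- Zone tables beyond the canonical closest-to-input examples are
  user-supplied; the package ships only a starter table
  (`inst/extdata/zone_table_starter.tsv`).
- The amplitude measure (max − min of the zone-mean waveform) is a simple
  peak-to-trough contrast; zones average voxels, not region means.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile("sim")
cfg <- simConfig(grid = c(4L, 4L, 40L), seed = 1)
sim <- writeSimulatedDataset(cfg, dir)
res <- runPipeline(list(fmri = sim$paths$bold,
                        physio = sim$paths$physio,
                        out = file.path(dir, "out")))
str(res$report)
```
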