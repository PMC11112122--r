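---
title: "Models and methods behind axotraffic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axotraffic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axotraffic)
```

This vignette explains the quantitative models the package implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical and design choices made where more than one
convention exists.

## The track classification model

A particle track is an ordered list of (frame, x) pixel coordinates along an
oriented axon, one sample per second at 0.175 µm/px. The classifier is a
small, fully deterministic rule system:

1. **Movement test.** Interval *i* (between frames *i* and *i*+1) is
   *moving* iff |Δx| > `movementEpsPx`. The default 0.5 px reproduces the
   changed/stayed-the-same comparison exactly on integer-pixel tracker
   output while tolerating sub-pixel float coordinates from other tracers.
2. **Maximal blocks.** Consecutive intervals with the same movement state
   form blocks; *moving* blocks are additionally split where the
   displacement sign reverses, so a run always has a single direction.
   (With a strictly positive epsilon, a moving interval always has sign ±1,
   so no tie-break is ever needed at a split.)
3. **Cutoffs.** Moving blocks of ≥ `minRunFrames` (5) intervals are *runs*;
   still blocks of ≥ `minPauseFrames` (5) are *pauses*; everything shorter
   is *oscillation*. Segments tile the track exactly — this conservation is
   asserted property-style in the tests.
4. **Track metrics.** Run distance is Σ|Δx| over the run × pixel size; mean
   run speed is distance/duration. A track with no runs is *stationary*;
   pause durations are reported only for mobile tracks. Net displacement is
   (x_end − x_start) × pixel size, signed anterograde-positive, and is
   classified anterograde/retrograde only for mobile tracks reaching
   `netDispThresholdPx` = 5 px (exactly 0.875 µm at defaults); mobile tracks
   below threshold are "none".

Tracks shorter than `minTrackFrames` (20 samples) are rejected with a
logged reason, and tracks with missing frames raise an error rather than
being interpolated — silent gap-filling would corrupt pause statistics.

**Aggregation.** Per-axon summaries are means over tracks (the per-track
mean being the unit of observation); cohort statistics are medians over
axons, with axons as the group *n*. Where a track has several runs in one
direction, its directional speed is the unweighted mean of per-run mean
speeds; a duration-weighted alternative was considered and rejected as the
default because the per-run mean is what per-track averaging of exported
run values produces. The percentage of mobile tracks in each net-direction
class is reported per axon (`pct_net_*`).

## The synthetic track generator

`simulateTracks()` draws, per mobile particle, an alternating sequence of
runs and pauses, with occasional oscillation episodes, and emits positions
rounded to the pixel grid (the movement test operates on pixel
coordinates). Generative choices:

- **Distribution families.** Run lengths (µm), run speeds (µm/s) and pause
  durations (s) are log-normal, parameterized by their *median* with a
  common `sdlog` = 0.3. Only medians of these quantities are established
  for the wild-type condition; the log-normal family and the spread are
  modeling choices — 0.3 gives a realistic coefficient of variation
  (~31%) for organelle transport while keeping the mean within ~5% of the
  median, so per-axon means remain comparable to generative medians.
- **Defaults (wild-type preset).** 56% stationary, pause median 16.4 s,
  anterograde 0.43 µm/s and 5.88 µm, retrograde 0.48 µm/s and 8.71 µm,
  180 frames at 1 s and 0.175 µm/px. The probability that a run is
  retrograde is not an established quantity; 0.5 encodes the approximately
  balanced bidirectional transport seen in wild-type axons, and the net
  retrograde bias then emerges from the longer retrograde runs.
- **Grid representability.** Run durations are drawn in µm and converted to
  frames via the speed; runs shorter than 5 frames are resampled (they
  would be unclassifiable ground truth), and run speeds below 1 px/frame
  are resampled because slower runs cannot be represented on the integer
  pixel grid without zero-displacement frames that would contradict their
  own label. The wild-type speeds (~2.5 px/frame) are far from this floor.
- **Oscillation** is modeled minimally as ±1 px alternating jitter for 1–4
  frames — the least motion satisfying the negative definition "below both
  cutoffs" — and episodes are inserted between two pauses so jitter never
  touches a run boundary. Episode count per mobile track is Poisson with
  mean `oscillationRate` (default 1).
- **Truncation.** The last block is cut at 180 frames; if the cut leaves a
  run or pause below its 5-frame floor, the ground truth relabels it
  oscillation. This guarantees the key invariant used in testing: on
  noiseless tracks the classifier's per-interval labels equal the ground
  truth exactly.

What the generator does **not** emulate: detection noise and tracker errors
(broken or merged traces), photobleaching, sub-pixel localization jitter,
particle crossings, and density-dependent effects. Passing round-trip tests
therefore validates the classification and aggregation logic, not the
robustness of any upstream tracing step.

`simulateCohort()` derives one independent sub-seed per axon from the base
seed, so different base seeds give statistically independent cohorts while
each remains bit-reproducible.

## Kymograph construction

`resamplePolyline()` places `round(L/step) + 1` arc-length-uniform samples
along the traced polyline (endpoints preserved; the realized spacing
deviates from the step by at most step/(2(n−1))). `extractKymograph()`
reduces intensity across `widthPx` (default 10) normal offsets per sample.
The reducer defaults to **maximum** — standard for sparse punctate signal
under a wide band — with mean available; interpolation is bilinear, with a
nearest-neighbour mode whose exact arithmetic underlies the geometry tests
(e.g. reversing the polyline reverses the kymograph columns exactly).
Coordinates are 0-based with pixel centres at integers throughout.
Anterograde is increasing arc length; since direction cannot be inferred
from the image, the ROI carries an explicit `anterogradeSign` set when the
axon is traced.

## AIS structural analyses

**Periodicity.** The autocorrelation is computed on the mean-subtracted
profile with the biased (divide-by-N) estimator and normalized by its lag-0
value, so curve(0) = 1 and side-peak heights are amplitude-normalized. The
period estimate is the lag of the first local maximum after the first local
minimum, requiring a prominence of at least `minProminence` (default 0.1)
above the intervening valley; monotone or noise-like curves yield a missing
value rather than an error. On a 30 nm lag grid a 190 nm lattice reads out
at 180 nm — quantization, not bias; sub-pixel refinement is deliberately
not applied so the estimator matches the conventional grid-based readout.

**Patch detection.** The published thresholds `pa_thre = 0.6` and
`area_thre = 0.7` come from a detection script whose internals are not
restated anywhere; the semantics implemented here are documented stand-ins:
`pa_thre` is relative to the ROI dynamic range above background (background
= 10th percentile of ROI intensities, robust to sparse bright structure),
and `area_thre` is relative to the *median* candidate component area.
Components are 8-connected (a hand-written labelling pass; the available
image-analysis labelling is 4-connected). Smoothing uses a Gaussian of
`smoothingSigmaPx` = 1 px.

**AIS length.** Marker profiles are smoothed with a rolling mean
(`smoothingUm`, default 1 µm), background-subtracted (10th percentile) and
normalized to the maximum; the extent is measured between the outermost
crossings of `thresholdFraction` = 0.33, linearly interpolated between
samples. The 0.33 fraction follows established AIS-boundary criteria that
are conventions rather than derivations, so it is exposed as a parameter.
The measurement is exactly invariant to intensity rescaling.

## Colocalization

Detection runs on channel A only; integrated density is the
background-subtracted sum over the detected footprint, measured identically
in both channels, with per-channel background taken as the median intensity
outside all footprints. The relation is summarized by the OLS fit of B on A
(matching the y-on-x orientation of the calibrated defaults
y = 1578·x + 4156) and the Spearman rank correlation with midranks.

## Statistics

- Median 95% CIs use the distribution-free binomial order-statistic
  construction (the widest symmetric order-statistic pair with ≥ 95%
  coverage); samples too small for that coverage (n < 6) fall back to a
  seeded percentile bootstrap.
- Group comparisons screen each group with the D'Agostino–Pearson omnibus
  test (implemented from the standard skewness/kurtosis z transforms, which
  require n ≥ 8; smaller groups force the nonparametric branch). Two
  groups: Student's t or Mann–Whitney; three or more: one-way ANOVA or
  Kruskal–Wallis with Dunn's post hoc z tests (pooled ranks, tie
  correction). Dunn comparisons default to many-to-one against a stated
  control with Bonferroni correction — the classical Dunn procedure — and
  all-pairs mode is available. A two-factor ANOVA wrapper covers crossed
  per-culture percentage designs.
- A pause lasting exactly 5 frames counts as a pause (the cutoff is
  inclusive by definition), including in per-track pause-duration means.

## Problem sizes and tolerances in the shipped tests

The test suite verifies segmentation against a brute-force oracle on 10⁴
random tracks, label equality on hundreds of noiseless simulated tracks,
period recovery on 100 seeded lattice replicates per spacing (within one
30 nm pixel, ≥ 95/100), round-trip recovery of the wild-type preset medians
on a 50-axon × 20-track cohort (within 10%), and the two-group type-I error
on 4 000 null simulations (0.05 ± 0.0125). The acceptance script uses
100 axons × 20 tracks. These sizes keep the full suite under a minute on a
single core while leaving Monte-Carlo error well inside the asserted
tolerances.

## Known limitations

- The classifier assumes contiguous, single-particle tracks; it does not
  attempt track linking, gap closing or collision resolution.
- Period estimation reports grid-quantized lags; profiles much shorter than
  ~10 periods give unstable side peaks.
- Patch-detection semantics are a documented reconstruction of an external
  tool's behaviour, not a byte-level reimplementation.
- The generators produce idealized noise (additive Gaussian, seeded); they
  are ground-truth machinery for validating the analysis, not simulations
  of microscope physics.
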