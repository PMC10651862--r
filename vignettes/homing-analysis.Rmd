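---
title: "Methods: analyzing lever-anchored firing fields during homing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing lever-anchored firing fields during homing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`homingfields`, the parameters that matter, the design choices made where the
method left room, and what the synthetic-data validation does and does not
show.

## Task and coordinate conventions

The task couples a home base to an 80-cm circular arena via a bridge. All
analyses use a canonical frame: the arena center at (0,0), the bridge center
on the negative-y axis, distances in cm, times in s, rates in Hz, and angles
in degrees in [−180, 180), measured counterclockwise from "south" (0,−1) —
the direction from the arena center toward the bridge. `read_session()`
rotates and translates any stored session into this frame; the transform is
idempotent.

The distance from the animal to the lever is always the distance to the
nearest point of the lever-box rectangle (11.6 × 8.2 cm footprint, long axis
across the lever direction), not to its center. Three thresholds structure a
journey: the animal is *at the lever* within 10 cm of the box wall, at the
*periphery* within 3 cm of the arena edge (radius ≥ 37 cm), and
lever-centered analyses use samples within 12 cm of the box wall. Trials
whose lever-box center lies more than 30 cm (0.75 × radius) from the arena
center are excluded.

Two conventions the method leaves open were fixed as follows:

* **Bridge occupancy.** The animal is "on the bridge" when y < −(arena
  radius + 2 cm). Journey boundaries are transitions across this line. Any
  small offset works because the gap between arena edge and bridge is empty.
* **Error at the periphery.** Defined as the absolute angle at the *arena
  center* between the periphery-arrival point and the bridge center, folded
  to [0, 180]. This is the definition consistent with a 90° chance level for
  uniformly random arrivals, which the test suite verifies analytically. The
  *homing direction* used for drift coupling is a different angle, measured
  at the lever-box center between the vectors to the bridge and to the
  arrival point.

## Behavioral metrics

Path complexity is ln((1 − MVL)·100), with MVL the resultant length of the
unit movement-direction vectors between consecutive samples; it ranges from
a floor of about −2.30 (straight path) to ln(100) ≈ 4.61 (uniform
directions). Degenerate case: MVL is clamped at 0.999 before the log so a
perfectly straight path maps to a finite floor rather than −∞; the clamp
preserves monotonicity in MVL.

Occupancy never assumes a constant sampling rate: each sample's dwell time
is the gap to the next sample, capped at 3× the median gap so tracking
dropouts do not inflate occupancy. Spikes falling inside such gaps are
dropped when binning.

Median splits (short/long search, accurate/inaccurate homing) assign the
median element to the low group, making group sizes differ by at most one
and the split deterministic. The light/dark classifier is a linear SVM under
stratified 10-fold cross-validation; features are standardized per fold with
training-fold statistics, and the fold assignment is seeded.

## Firing-rate estimation

All rate estimates divide spike counts by *smoothed* occupancy and then
smooth the ratio again, with Gaussian kernels renormalized over valid bins —
no wraparound at arena edges, no zero-padding bleed; bins with zero raw
occupancy stay masked. Defaults: 3-cm bins / 5-cm SD for arena maps, 1-cm /
2-cm for lever-centered maps, 20 bins / SD 1 bin for 1D histograms (circular
smoothing for directional bins). Histogram ranges are fixed across light and
dark conditions via the smaller of the two 90th percentiles (linear
interpolation), with fixed minima of −42.5 cm (y coordinate) and 12 cm
(lever distance). The spatial information score is computed from the
*unsmoothed* occupancy probabilities and rates, with 0·log 0 ≡ 0.

## Trial matrices and drift

Trial matrices hold one lever-pressed journey per row over 2-cm (y, lever
distance) or 20° (direction) bins, each row smoothed with SD 2 bins; rows
occupying fewer than 5 bins are dropped. The trial matrix correlation is the
mean Pearson r over all distinct row pairs (jointly valid bins;
zero-variance rows excluded and counted). Its significance, and the
peak-location-vs-lever test, use a within-row shuffle null (500 draws) that
preserves each row's multiset of rates exactly — this also absorbs the
range-restriction artifact that search paths end at the lever. Peak ties
within a row resolve to the bin nearest the row's (circular) center of mass.

Per-trial drift: the matrix is rolled so the mean-rate peak sits at
direction 0; an idealized tuning curve is the mean of rows each re-aligned
to its own peak; each row's drift is the lag of its circular
cross-correlation (mean-subtracted, wraparound) with the idealized curve.
Numerical choices: ties go to the smaller absolute lag, and the peak lag is
refined by parabolic interpolation over its two neighbors (clamped to ±half
a bin), which removes most of the 20° quantization noise. Because the
mean-peak roll references drift to the session-average tuning, a shift
common to all rows is absorbed by construction; passing a fixed `reference`
curve instead makes the estimator exactly shift-equivariant, which is how
the equivariance property is tested.

Drift–homing coupling uses the Fisher–Lee sine-of-pairwise-differences
circular–circular correlation (the standard parameter-free estimator; the
method names only "circular–circular correlation"), a 500-permutation
two-sided p-value, and a least-squares slope after centering both variables
on their circular means. The slope regresses *drift on homing direction* —
drift is plotted against homing direction and slopes below one mean the
field rotates less than the homing direction — so a generator injecting
δ = 0.5·homing + noise is recovered with slope ≈ 0.5.

## Lever-anchored classification

Three criteria, all required: (1) the peak of the firing-rate-vs-lever-
distance curve lies within 10 cm of the box wall *and* exceeds the 95th
percentile of a shuffle distribution — built from 500 circular time-shifts
of the spike train by a uniform offset of at least 20 s, recomputing the
curve's peak each time; (2) the lever-centered 2D map peak exceeds 7.5 Hz;
(3) the Pearson similarity of lever-centered maps from two independent trial
sets exceeds 0.4. "Two independent sets" is implemented as odd/even
lever-pressed journeys (rather than first/second half) to decouple the
split from slow drift; the same odd/even rule builds the A1/A2 and SL1/SL2
style partitions of the remapping analysis. Tuning MVL and preferred
direction come from the rate-weighted resultant of the 36 10°-bin centers
(occupancy-corrected); a per-spike variant is available but not the default,
since raw spike directions ignore occupancy inhomogeneity around the box.

## The synthetic generator

`generate_session()` emulates the study conditions: ~100 trials starting
with seven light trials then alternating; the lever re-placed uniformly
within 0.75 × radius every 4th trial and rotated by a random multiple of 45°
otherwise; search as a correlated random walk (per-step Gaussian turning
noise, SD 10°/step light and 30°/step dark at 50 Hz; goal attraction 0.2
light, 0.05 dark; speeds 25 and 15 cm/s) that steers off the wall and, as in
the task, is forced to the lever after 240 s; a single circumnavigation of
the box at 10 cm/s with the press halfway; and a straight homing path at the
observed mean homing speeds (64.18 light, 31.58 dark cm/s), exiting at
bridge direction + error.

The homing error is von Mises with concentration κ = κ₀/(1 + c·L) on dark
trials (L = search path length) and fixed κ₀ on light trials, where
landmarks prevent error accumulation. κ₀ = 80 and c = 0.1/cm were chosen
once so that the default conditions reproduce the task's reported error
structure (median ≈ 4° light, ≈ 18° dark, positive search-length/error
correlation in darkness); the uniform limit κ → 0 recovers the 90° chance
level. Spikes are inhomogeneous Poisson (per-sample thinning at the dwell
time) from three field templates: Gaussian place fields, Gaussian
lever-wall-distance fields, and lever-anchored fields (von Mises angular
tuning × Gaussian radial envelope at the wall) rotated per trial by
δₜ = slope·homing direction + Gaussian noise. An optional second field set
for dark trials emulates light/dark remapping.

What the generator does *not* emulate: theta rhythmicity and phase
precession, rate adaptation, multi-journey error correction, head direction
distinct from movement direction, overdispersed (non-Poisson) firing, and
at-lever dwell beyond one stereotyped loop (the task does not quantify loop
geometry; one circumnavigation at radius 7 cm is a stand-in). Passing
recovery tests therefore shows the estimators are correct and well
calibrated under the assumed generative structure — not that real data meet
those assumptions.

## Validation scale and limitations

The test suite and `scripts/acceptance.R` run at desk scale chosen to keep
estimator noise well inside the asserted margins: 50-trial sessions for
field detection (20 sessions × 10 neurons for sensitivity/false positives),
100 trials for slope recovery, 200 simulated null neurons for the type-I
calibration of the drift–homing permutation test, and 70 trials × 20 neurons
for the remapping contrasts. The recorded-data headline numbers (e.g. the
0.91 light/dark SVM accuracy, 22–27% lever-coding proportions, 0.66/0.53/0.02
stability correlations) depend on real sessions and are not reproduced by
simulation; the synthetic analogues the acceptance script prints are the
package's own measurements under the generator's conditions.

Known limitations: drift estimates inherit the 20° matrix resolution
(mitigated but not removed by parabolic interpolation), so per-trial drifts
below ~5° are not resolvable; the lever-distance curve shuffle preserves the
spike train's autocorrelation but not any behavioral covariates of firing;
and with fewer than ~15 lever-pressed journeys the split-half criterion (3)
becomes conservative.
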