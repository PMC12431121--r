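---
title: "Methods: the adlmotion ADL neuromotor pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adlmotion ADL neuromotor pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adlmotion)
```

## The problem and the data model

Drinking from a cup and eating with a spoon are the activities of daily
living (ADLs) most often disrupted by upper-limb neuromotor impairment.
To characterize how a healthy shoulder accomplishes them, a wearable
device records, on each arm, six surface-EMG channels (pectoralis major,
anterior/middle/posterior deltoid, upper/lower trapezius; 1000 Hz, 12-bit
ADC over 1.6 V) and one orientation IMU at the arm segment (unit
quaternions at 100 Hz), while a 30 fps video lets an annotator mark the
boundaries of seven contiguous task phases: reach, grasp, transport to
the mouth, in-mouth, return to the table, return to the start position,
and rest. Each subject repeats the task five times with 5 s rests.

`adlmotion` turns such recordings into three group-level products:

1. a **phase schedule** — mean and SD of each phase's duration as a
   percentage of the movement cycle, with the contiguous normalized-time
   intervals implied by the means;
2. per-muscle **activation envelopes** on a common 0–100 % cycle axis,
   with the time, amplitude and phase of each muscle's activation peak;
3. per-motion **joint-angle trajectories** (flexion/extension,
   abduction/adduction, medial/lateral rotation) with signed excursion
   peaks.

## Processing chain

**EMG branch.** Counts are converted to mV around the mid-scale code
(`(count − 2048) · 1600/4095`; a bipolar front end puts 0 V at
mid-scale, and the offset is a configuration knob). The per-channel mean
is subtracted and the signal full-wave rectified. Rectification before
smoothing is a deliberate reading: activation envelopes are non-negative
by definition, and a plain moving average of raw bipolar EMG would
collapse toward zero; DC removal plus `abs()` is the minimal physically
consistent envelope detector. The rectified signal is smoothed with a
1000-sample (1 s) centered moving average, cut into the five annotated
cycles (rest periods are discarded and each cycle's clock restarts at
zero), resampled to 9000 points by linear interpolation over each
cycle's own span, and averaged within subject. The subject mean is kept
on the mV scale *and* min-max normalized to 0–1; group curves are
pointwise means of each version across subjects. Peak statistics are
taken from the mV-scale group mean, because reported peak amplitudes
carry mV units, while the normalized curves match the convention used
for figure-style plots; both are emitted, and the choice is recorded in
the report metadata. No band-pass filter is applied by default (none is
part of the documented chain).

**Kinematic branch.** Quaternions are decomposed as intrinsic Z-Y-X
(aerospace yaw–pitch–roll) Euler angles — the convention must be fixed
for the axes to be anatomically interpretable, and Z-Y-X is the one
under which yaw maps to flexion/extension, roll to
abduction/adduction and pitch to rotation at this sensor placement. Yaw
and roll are unwrapped (±180° branch-cut jumps removed) before any
averaging, then all three axes are smoothed with a 100-sample (1 s)
moving average, segmented by the same annotations, zero-aligned
(each cycle's first sample subtracted, so every trajectory starts at
0°), resampled to 9000 points and averaged within and across subjects.
Near gimbal lock (|pitch| → 90°) yaw and roll are not separable; the
residual rotation is assigned to yaw, roll is set to 0 and the sample is
flagged. The synthetic generator refuses rotation lobes ≥ 90° so locked
samples cannot arise in simulated data.

**Sign conventions.** The two arms mirror each other: extension is
+yaw on both, while abduction is +roll on the dominant and −roll on the
non-dominant arm (and lateral rotation +pitch vs −pitch).
`motion_axis_map()` encodes this; `angle_peak_summary()` reports, for
each motion, the extremum of the group trajectory *in that motion's
direction*, as the raw Euler-axis value — so a dominant-arm adduction
peak prints negative and a non-dominant one positive, matching the
field's reporting convention.

## Numerical choices

* **Moving-average edges** shrink to the available samples (no invented
  padding); for even windows the extra sample is on the earlier side.
  Output length always equals input length.
* **Resampling** spans each cycle's own start→end and preserves the
  endpoints exactly; it is exact for affine signals and the identity
  when grids already match.
* **Phase intervals** are half-open `[start, end)` with the cycle end
  (100 %) assigned to phase 7, so boundary instants belong to exactly
  one phase.
* **SDs** are sample (n−1) standard deviations, 0 for a single cycle.
* **Ties** at equal extrema resolve to the earliest time.
* **Degenerate inputs**: flat cycles min-max–normalize to all zeros;
  zero-length or non-increasing annotations are errors, not warnings.
* Percentages, mV and degrees are kept at full precision internally and
  rounded to one decimal only in report tables.
* Subjects with unreadable or inconsistent trials are excluded
  subject-wise with a logged reason (mirroring how cohorts handle
  device dropouts), never silently patched.

## The synthetic cohort generator

No public recordings exist for this protocol, so validation rests on
parameter recovery: generate data with known truth, run the full
pipeline, and compare. The generator (`simulate_adl_dataset()`) emulates
the study conditions — 30 subjects × 5 trials with 5 s rests, phase
durations around the task's reference schedule, and per-limb activation
and excursion templates seeded from the normative reference magnitudes
so demonstration output is visually comparable to real group curves
(comparability is the only goal; the generator does not attempt to
reproduce any measurement).

* **EMG** is amplitude-modulated Gaussian interference — the standard
  surface-EMG model: the raw signal is zero-mean noise with
  `sigma(t) = baseline + amplitude · G(t)`, `G` a Gaussian bump (SD 8 %
  of cycle) at the muscle's peak time. The expected rectified envelope
  is `sigma(t)·√(2/π)` (half-normal mean), so recovery targets have a
  closed form, including the boxcar attenuation
  (`gaussian_boxcar_attenuation()`). Signals are quantized to 12-bit
  counts and clipped at the rails, like the real front end.
* **Angles** are sums of raised-cosine lobes (smooth, compactly
  supported) plus 0.2° Gaussian jitter, converted to quaternions by the
  exact inverse of the pipeline's Euler convention. The boxcar
  attenuation of a raised-cosine peak is also closed-form
  (`raised_cosine_boxcar_attenuation()`), which is what recovery
  tolerances are computed from.
* **Cycle duration** is nowhere specified for this protocol (tasks are
  performed "at a comfortable speed"); the default is mean 10 s, SD 1 s,
  a typical figure for instrumented drinking/eating cycles in healthy
  adults. It was chosen once and is a configuration parameter.
* **Cohort sampling is moment-matched.** Phase durations use gamma
  marginals (positive support with exactly the template mean and SD —
  a normal truncated at zero would bias short phases upward by a
  substantial fraction of their mean), drawn via Latin-hypercube
  quantile strata, renormalized to sum to 100 % per trial, and
  recentred so the cohort's mean shares equal the template exactly
  (the recentring offsets sum to zero, so row sums stay 100). Burst
  peak times and lobe amplitudes are sampled the same way. This is the
  `MASS::mvrnorm(empirical = TRUE)` idea applied to a benchmark
  generator: the finite cohort *is* the population, so recovery tests
  measure pipeline error rather than Monte-Carlo drift. Boundaries are
  then snapped to the 30 fps frame grid, as a human annotator stepping
  through video would produce (switchable off).

What the generator does **not** emulate — and hence what passing
recovery tests cannot show about real data: volume-conduction crosstalk
between muscles, non-stationary or non-Gaussian EMG statistics, fatigue
and electrode-impedance drift, soft-tissue artefact on the IMU,
between-subject differences in movement *shape* (only timing and
amplitude vary), and real annotator error beyond frame quantization.
Moment matching also means cohort-level sampling noise is absent by
construction, which real cohorts do not enjoy.

## Validation targets and problem sizes

The test suite checks, among others: oracle equivalence of the moving
average against a brute-force windowed mean (200 random signals up to
10⁴ samples), exactness of resampling on affine inputs,
quaternion↔Euler round trips within 1e-6° on 10⁴ random orientations,
the half-normal envelope of rectified Gaussian noise, scale
equivariance of the EMG branch, shift invariance of zero alignment,
byte-level determinism of generated datasets and reports under a fixed
seed, and full-pipeline parameter recovery on a 30-subject × 5-trial
drinking cohort: group phase-duration means within one standard error
of the template, every muscle's envelope peak time within 1.5 % of
cycle of its injected centre, and every injected excursion peak within
10 % of its analytically attenuated value. Unit tests use smaller
cohorts (2–4 subjects, 2–3 trials, 4–8 s cycles) so the default suite
stays fast; the study-scale run lives in the acceptance tests and in
`scripts/acceptance.R`.

Known limitations worth restating: peak amplitudes of very weak
channels (≲ 0.1 mV, under one ADC code of noise) are distorted by
quantization even though their peak *times* survive; excursion lobes
whose support touches the cycle edges interact with the smoothing
window and zero alignment (the eating-task abduction lobe peaking at
12 % of cycle is the closest such case); and the published drinking
schedule itself is internally inconsistent at phases 4 and 6, which
`check_schedule()` flags rather than resolves.

## Package shape

The package follows the classic R modelling idiom where it fits a
descriptive pipeline: one entry point (`adl_analyze()`) returns a
classed object with `print`, `summary` and `plot` methods. `predict`,
`residuals` and a `simulate` method would have no meaning for a
descriptive analysis, so simulation is a first-class generator
(`simulate_adl_dataset()`) rather than a method, and the peak tables
are plain data frames inside the object. A thin command-line wrapper
(`inst/cli/adl.R`) exposes `simulate`, `run` and `check-schedule` for
shell use.
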