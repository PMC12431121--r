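# adlmotion

Bilateral upper-limb EMG + IMU analysis of drinking and eating
activities of daily living (ADLs).

Assessing how the shoulder accomplishes everyday tasks — reaching for a
cup, bringing a spoon to the mouth — is central to rehabilitation after
stroke, where compensatory movement patterns must be detected early.
`adlmotion` implements the complete processing chain for a wearable
device that records, on each arm, six surface-EMG channels (PM, AD, MD,
PD, UT, LT; 1000 Hz, 12-bit ADC over 1.6 V) and an orientation IMU
(unit quaternions, 100 Hz), synchronized with 30 fps video annotation
of a seven-phase task model (reach, grasp, transport, in-mouth, return
to table, return to start, rest).

The pipeline, per subject and limb:

* **EMG**: counts → mV (`(c − 2048)·1600/4095`), DC removal +
  full-wave rectification, 1 s moving-average envelope, segmentation
  into the five annotated cycles, linear resampling of each cycle to a
  9000-sample 0–100 % axis, within-subject averaging, min-max (0–1)
  normalization, cross-subject averaging.
* **Kinematics**: quaternion → intrinsic Z-Y-X Euler angles
  (yaw/pitch/roll), unwrapping, 1 s smoothing, segmentation,
  zero-alignment (every cycle starts at 0°), resampling, averaging.
  Limb-specific sign conventions map the axes to anatomical motions
  (e.g. extension = +yaw on both arms; abduction = +roll dominant,
  −roll non-dominant).
* **Statistics**: group phase schedule (mean ± SD durations, contiguous
  normalized-time intervals), per-muscle activation peaks (time in % of
  cycle, amplitude in mV, phase at peak), per-motion signed excursion
  peaks (degrees).

Because recordings of this protocol are not public, the package ships a
deterministic synthetic-cohort generator with ground-truth JSON
sidecars (amplitude-modulated Gaussian EMG, raised-cosine joint
excursions, moment-matched cohort sampling), so every pipeline stage is
validated by parameter recovery. See the methods vignette
(`vignettes/adl-neuromotor-pipeline.Rmd`) for the model and every
numerical choice.

## Worked example

Simulate a 5-subject drinking cohort, run the full analysis, and print
the group tables:

```r
library(adlmotion)
ds  <- simulate_adl_dataset(synth_config(n_subjects = 5), seed = 7)
fit <- adl_analyze(ds)
summary(fit)
```

```
Phase schedule (drinking task, 25 cycles)
 Phase Interval of Mean Time (%) Mean Duration ± SDT (%)
     1               [0.0, 17.2]              17.2 ± 4.1
     2              [17.2, 21.6]               4.4 ± 3.4
     3              [21.6, 31.4]               9.8 ± 4.4
     4              [31.4, 53.2]              21.8 ± 5.0
     5              [53.2, 66.8]              13.6 ± 3.2
     6              [66.8, 84.7]              17.9 ± 6.6
     7             [84.7, 100.0]              15.3 ± 2.3

EMG activation peaks, dominant arm (group mV envelope):
 muscle peak_time peak_value phase_at_peak
     PM      38.4        0.3             4
     AD      41.7        0.9             4
     MD      42.8        0.4             4
     PD      42.4        0.2             4
     UT      36.4        0.6             4
     LT      41.0        0.4             4

Joint excursion peaks, dominant arm (degrees):
 motion peak_time peak_value phase_at_peak
      F       0.9        0.0             1
      E      70.3        8.6             6
     MR      93.2        0.0             7
     LR      45.5       19.4             4
    ADD      47.8      -27.1             4
```

(Non-dominant tables print as well; output truncated here.) Reading the
tables: the in-mouth phase (phase 4) occupies 31.4–53.2 % of the
normalized cycle and dominates the task; every dominant-arm muscle
peaks inside it, led by the anterior deltoid (0.9 mV at 41.7 % of
cycle); the arm's main excursion is adduction (−27.1° at 47.8 %,
negative = toward the midline on the dominant side) with accompanying
lateral rotation. `plot(fit, "emg")` and `plot(fit, "angles")` draw the
group curves with phase boundaries overlaid; `write_report(fit, dir)`
emits the tables as CSV with the standard column headers.
`check_schedule()` audits any published schedule table for
interval-vs-duration consistency.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/adl.R simulate --task drinking --subjects 30 --seed 1 --out ds/
Rscript inst/cli/adl.R run --in ds/ --out report/
Rscript inst/cli/adl.R check-schedule --task drinking
```

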