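# chestgait

Gait parameters from a single chest-worn accelerometer, and the statistics
to validate them.

Chest-worn devices already used for vital-signs monitoring could also
measure gait, replacing a second lumbar-worn sensor — but only if the gait
endpoints they produce agree with established references. `chestgait`
implements both halves of that question in R:

1. **A single-sensor gait pipeline.** From a tri-axial trunk acceleration
   signal (chest or lumbar, stored in g at a fixed rate), the pipeline
   estimates the vertical axis from the gravity vector, classifies 3-s
   windows as gait / non-gait and merges them into walking bouts, detects
   initial contacts (heel strikes) and final contacts (toe offs) with a
   continuous wavelet transform of the integrated vertical acceleration,
   and converts the per-step vertical centre-of-mass excursion *h* into
   spatial parameters with the inverted pendulum model

   step length = 2·√(2·l·h − h²),

   where *l* is the pendulum length. A stride spans two consecutive
   same-foot initial contacts; gait speed = stride length / stride time and
   cadence = 120 / stride time (steps/min). Endpoints are summarised as the
   per-task, per-visit median, then averaged over visits.

2. **The validation framework.** Bland–Altman bias and 95% limits of
   agreement (bias ± 1.96·SD of the differences), mean absolute difference
   and mean percent error, ICC(2,1) (two-way random effects, absolute
   agreement, single measure) with F-based confidence bounds and the
   poor / moderate / good / excellent benchmarks, Pearson correlation,
   test–retest reliability, mixed-effects models
   `value ~ device * task + age + (1 | subject)` (REML, type-III F tests,
   least-squares-mean device contrasts on Satterthwaite df), and paired
   t-tests on walking-bout statistics.

Because raw validation-study recordings are typically not shareable, the
package ships a **synthetic-data module**: an inverted-pendulum forward
model that generates two-visit, two-device studies (fixed-speed walks and
free-moving activity sessions) with complete ground truth — event times,
bout intervals, per-stride parameters — so every pipeline stage is testable
end to end.

## Worked example

Simulate a 30-s walk (1.25 m/s, stride time 1.05 s, 128 Hz, 0.02 g sensor
noise) and run the full extraction:

```r
library(chestgait)

seg <- simulate_walk_segment(speed = 1.25, stride_time = 1.05, duration = 30,
                             sensor_height = 0.90, sampling_rate = 128,
                             noise_sd = 0.02, seed = 42)
ex <- extract_gait(seg$recording)
ex$strides
#> stride_table: 28 strides (0 rejected by plausibility bounds)
#>   gait speed 1.27 m/s, stride time 1.05 s (medians)
```

The detector found one continuous bout with 28 complete strides; the median
stride time matches the simulated 1.05 s exactly and the median gait speed
(1.27 m/s) recovers the simulated 1.25 m/s to within ~2%.

Agreement between two paired endpoint series:

```r
chest  <- c(1.18, 1.31, 1.02, 1.25, 1.19, 1.08)
lumbar <- c(1.22, 1.35, 1.10, 1.28, 1.24, 1.15)
bland_altman(chest, lumbar)
#> Bland-Altman (n = 6)
#>   bias -0.052 (-0.072, -0.031)
#>   LoA (-0.090, -0.014)

icc <- icc_2way_random_absolute(cbind(chest, lumbar))
classify_agreement(icc$icc)
#> ICC(2,1) = 0.865 (-0.037, 0.984): excellent
```

The chest series reads ~0.05 m/s low (the bias); the limits of agreement
say an individual chest measurement can sit 0.01–0.09 m/s below the lumbar
one; the ICC of 0.865 falls in the "excellent" benchmark band, though with
only 6 subjects its lower bound is wide.

`run_study()` chains everything — simulate, extract, aggregate, agreement
tables, mixed models, bout comparison — into one run directory with every
intermediate persisted as CSV:

```r
report <- run_study(sim_config(n_subjects = 5, seed = 11),
                    pipeline_config(), out_dir = "demo_run")
report$agreement   # chest-vs-lumbar panel per task x endpoint
```

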