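---
title: "Methods: single-sensor gait extraction and device-agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-sensor gait extraction and device-agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chestgait)
```

# The problem

A tri-axial accelerometer worn on the trunk (sternum or L4) records a mix
of gravity, locomotor oscillation and sensor noise. The package answers two
questions: *what are the wearer's spatiotemporal gait parameters* (gait
speed, cadence, stride time, stride length), and *do two wearing locations
or devices agree well enough to substitute for one another*. This vignette
describes the models, the tunable parameters, the numerical choices, and
what the synthetic validation study does and does not establish.

# The extraction pipeline

## Vertical axis

The device may be mounted in any orientation, so the first step estimates
the gravity direction as the mean acceleration vector over the recording
and applies the proper rotation (determinant +1) that maps it onto channel
1. The rotation is exact for a static tilt; slow orientation drift is not
modelled. Gravity (the estimated mean magnitude, nominally 1 g) is then
subtracted from the vertical channel. Degenerate inputs fail loudly: an
all-zero signal, or a mean magnitude outside 0.5–1.5 g (which indicates
either zero-mean noise or data recorded in m/s² but labelled as g — see
`validate_inputs()`).

## Gait bouts from 3-s windows

Each non-overlapping 3-s window is summarised by three features of the
vertical dynamic acceleration:

* `rms_g` — RMS intensity (g);
* `band_fraction` — share of spectral power in the locomotor band
  (0.5–3 Hz);
* `ac_peak` — maximum normalised autocorrelation at lags 0.25–1.5 s
  (step-period periodicity).

A logistic rule, `-6 + 1.2·log10(rms) + 4.5·band_fraction + 4.5·ac_peak >
0`, classifies the window; consecutive positive windows merge into maximal
bouts whose boundaries lie on the window grid (half-open intervals
`[start, end)`). The coefficients were fit once on simulator output and
frozen: on simulated activity sessions, gait and non-gait windows separate
completely in this feature space (a maximum-likelihood logistic fit
diverges by complete separation), so round frozen coefficients with
comfortable margins are preferable to a numerically fragile fitted vector.
The classifier is a transparent stand-in for whatever pre-trained model a
production pipeline would use, and is swappable: any object with a
`predict` method over the feature frame can be passed to
`detect_gait_bouts()`.

A consequence of the window grid is boundary quantisation: a bout boundary
can be off by up to one window at each end. For a 10-s bout the
intersection-over-union with the true interval can drop to ~0.7 from
quantisation alone; for bouts above ~15 s it stays above 0.8. The tests
encode exactly that expectation.

## Contact events

Inside each bout, the vertical dynamic acceleration is de-meaned, converted
to m/s², integrated once (trapezoid rule) to a velocity, high-pass filtered
(drift removal, below), and correlated with a first-derivative-of-Gaussian
wavelet `psi(u) = -u·exp(-u²/2)` — a smoothed differentiator. Minima of the
transform mark initial contacts; differentiating the transform and
re-transforming gives a signal whose maxima mark final contacts. The scale
is tied to the dominant step frequency `f` (periodogram peak in the
locomotor band): `scale = fs / (2·pi·c·f)` samples, placing the wavelet's
peak response at `c·f` with `c = cwt_scale_factor = 1.25` by default
(slightly above the fundamental sharpens the response to the contact
transient without tuning to a harmonic).

Peak picking uses a minimum separation of half a step period (taller peak
wins on conflict) and a height threshold of 0.3 times the 90th percentile
of the transform's absolute value — a quantile, not the maximum, so one
edge transient cannot suppress genuine events. Edges are handled by
reflection padding over the five-scale kernel support. If no dominant
locomotor frequency exists (periodogram peak less than 20 times the mean
spectral power, or under 20% of power in the band), the detector returns
empty events with a warning rather than hallucinating contacts; stillness
and broadband noise take this path.

The events container enforces the alternation invariant structurally: at
most one final contact is retained strictly between each pair of successive
initial contacts (the strongest transform response wins).

## Spatial parameters

Double integration of the vertical acceleration gives the vertical
centre-of-mass displacement; its peak-to-peak amplitude per
inter-initial-contact interval is the step's vertical excursion *h*. Drift
is removed with a zero-phase 4th-order Butterworth high-pass at 0.1 Hz
(`signal::filtfilt`, so effectively 8th order, no phase distortion) after
*each* integration stage — the standard recipe for trunk-accelerometry
displacement, low enough to leave the slowest locomotor content (0.5 Hz)
untouched. The inverted pendulum model converts excursion to step length
`2·√(2·l·h − h²)` with pendulum length `l`; a stride is two consecutive
same-foot initial contacts (every second contact — no left/right labelling
is attempted from a single trunk sensor), its length the sum of the two
step lengths within.

Strides are dropped, and counted in the processing log, when the geometry
is invalid (`h >= l`) or the values are implausible: stride time outside
0.4–2.25 s, stride length outside 0.3–3 m. These guardrails are
deliberately wide — they reject integration blow-ups and false events, not
unusual gait.

The pendulum length comes from the recording's `sensor_height` metadata
when present, else from `sensor_height_fraction` of a 1.70 m default height
(0.53 for lumbar, 0.72 for chest mounts). The simulator always stamps the
metadata (below), so the fallback only matters for externally supplied
recordings.

## Endpoints

Strides are pooled per subject × task × visit cell (across bouts) and
summarised by the median; the 95th percentile of gait speed is added for
the long activity tasks only, where enough steps exist for a stable tail
estimate (linear interpolation between order statistics, `quantile`
type 7). Visit values are then averaged per subject and task; if a visit is
missing the available visit's value is carried — the same convention used
when one visit of one reference device fails in a real study. Pooling
strides rather than averaging per-bout medians is a deliberate choice: with
bouts of very different lengths, per-bout medians would weight a 10-s bout
equally with a 5-min one.

The 9-s / 4-cycle bout filter (`filter_bouts()`) is applied to the
bout-statistics comparison only, not to endpoint medians, mirroring its
role as an outlier control for bout accounting; both thresholds and the
choice of where to apply it are configuration, not code. A "gait cycle"
here is a complete stride: `floor((n_initial_contacts - 1) / 2)`.

# The synthetic study

## Forward model

The generator inverts the pipeline's own spatial model so that estimator
correctness is a testable round trip. Given true gait speed `v` and stride
time `T`, step length is `sl = v·T/2` and the vertical excursion solves the
pendulum chord formula: `h = l − √(l² − (sl/2)²)` (infeasible geometries,
`sl ≥ 2l`, are an explicit error). Vertical displacement is a cosine arc at
step frequency with peak-to-peak `h`; the vertical acceleration channel is
its exact second derivative plus gravity, so double-integrating the
generated signal recovers `h` — the tests require the interior per-step
median within 2%. Initial contacts sit at the displacement minima; ground
-truth final contacts are placed at the midpoint between consecutive
initial contacts, which is where the wavelet re-transform peaks for this
harmonic signal — a generator convention, not a physiological claim.
Anterior–posterior and mediolateral channels carry low-amplitude harmonics
(40% of the vertical amplitude at step frequency, 25% at stride frequency)
so the axis estimator has realistic cross-axis content to reject.

Ground truth satisfies, by construction: `stride length = speed × stride
time` exactly; strictly increasing contacts; every event strictly inside a
bout interval.

## Study design and defaults

The default configuration encodes a two-visit validation design in healthy
adults: 20 subjects, 2 visits, 128 Hz, three self-paced walking speeds plus
an in-lab simulated-activity session (7 min) and an outside-lab session
(20 min) with walking fraction 0.5 and mean bout duration 30 s. Normal-pace
speed is drawn per subject from N(1.25, 0.15²) m/s with slow/fast
multipliers 0.75/1.25, stride time from N(1.05, 0.08²) s — representative
healthy-gait values; the per-task true distributions of any particular
cohort are unknown, so these are stated assumptions, configurable in
`sim_config()`. Walking tasks default to 30 s so each cell has ~25–30
strides for a stable median. Subject parameters at later visits correlate
with visit 1 at `visit_retest_rho = 0.9` (a bivariate-normal construction),
giving the test–retest analysis a known target.

Two device channels share one physical scene. Both are stamped with the
subject's effective pendulum length (0.53 × body height, essentially leg
length): co-located trunk sensors ride the same centre of mass, so their
vertical excursion is identical, and with zero noise, zero bias and no
mounting tilt the two channels are bit-identical by construction. Devices
differ by white sensor noise (lumbar `noise_sd_g = 0.02` g; chest 1.25×,
reflecting the less stable harness mount), an optional additive speed bias
encoded in the chest signal amplitude (default 0), and an independent
random mounting orientation (tilt up to 15°). The RNG is split accordingly:
the session *structure* (bout layout, per-bout ±3% speed/stride-time
jitter, object-handling bursts) draws from a location-independent scene
seed, sensor noise from a location-specific one, and each subject gets its
own substream derived from the study seed — so adding subjects never
perturbs existing ones.

## What the simulation does not show

Non-gait segments are quiet standing plus broadband bursts; they contain no
periodic locomotor-band component, so the window classifier's task is
easier than in free-living data (dish-washing, cycling and fidgeting can be
rhythmic). The walking signal is a stationary harmonic: no turns, slopes,
stops inside a bout, asymmetry, or pathological gait. Sensor noise is white
and gravity is static. Passing the end-to-end tests therefore demonstrates
that the estimator chain is *correct for the model it assumes* — unbiased
inversion, event timing, aggregation arithmetic, agreement statistics — not
that it is robust to every artefact of real recordings. That is exactly the
role of a synthetic validation layer; field accuracy must come from studies
against instrumented references.

# The statistical layer

Bland–Altman limits of agreement use the literal 1.96 multiplier on the SD
of differences; bias CIs use the t distribution, LoA CIs the standard
variance `(1/n + 1.96²/(2(n−1)))·SD²`. Mean percent error is computed
against the *reference* value (pairs with a zero reference are excluded
with a warning). ICC(2,1) — two-way random effects, absolute agreement,
single measure — is computed directly from the two-way ANOVA mean squares,
`(MSR − MSE)/(MSR + (k−1)MSE + k(MSC − MSE)/n)`, with the F-based
confidence interval (Satterthwaite denominator df). Single-measure rather
than average-measure is the default because the question is whether *one*
chest measurement can replace one reference measurement. Negative ICCs are
admissible and returned without error; for strongly negative values the
interval df collapse and the bounds are best regarded as qualitative.
Benchmarks: ≤ 0.4 poor (the boundary itself is poor), < 0.6 moderate,
< 0.75 good, else excellent.

The mixed model is `value ~ device * task + age + (1 | subject)`, REML,
sum-to-zero contrasts, type-III F tests on Satterthwaite denominator df,
and least-squares-mean pairwise device contrasts per task level with
t-based CIs — also Satterthwaite. The model is fit on endpoint *values*
with device as a factor, and between-device errors are read off the device
contrasts, which is what a least-squares-mean difference table reports. No
multiplicity correction is applied by default (Holm or Tukey are a switch);
with few planned contrasts, unadjusted p-values plus the explicit caveat is
the more transparent default. A singular random-intercept fit (subject
variance indistinguishable from zero) is flagged, not hidden: the fixed
effects then coincide with OLS, which the tests verify to 1e-6. Paired
bout-statistics comparisons use two-sided paired t-tests, with exact-tie
handling (all-zero differences report p = 1; an exactly constant nonzero
shift reports p = 0 with a point interval).

# Problem sizes and runtime choices

The test-suite and acceptance-script simulations use sizes chosen to give
stable Monte-Carlo estimates while keeping a full run in minutes on one
core: 20 seeds × 30 s walks for event detection (~1200 contacts), a
20-subject × 2-visit × 3-speed study (120 recordings per location pair) for
end-to-end recovery and chest–lumbar equivalence, 100 random 20×2 fixtures
for the brute-force oracle comparison, 200 replicates each for the F-test
size and contrast-coverage checks (MC standard error ~1.5 percentage
points), and 11 seeds for the bout-fragmentation pattern, evaluated as a
majority because the "totals not significantly different" half of the
pattern is itself a statistical event with α-level false-positive risk.
Session-level tests run some generators at reduced sampling rates where
only the ground-truth layer is under test.

# Known limitations

* The bout classifier is trained (frozen) on the simulator's feature
  distributions; real deployments should re-fit or swap it.
* Event detection assumes one dominant step frequency per bout; strongly
  accelerating or decelerating walking within a bout broadens the
  periodogram peak and can shift the wavelet scale.
* The inverted pendulum model systematically compresses step length at the
  extremes of the excursion range; in real data this appears as the
  well-known underestimation of stride length from trunk sensors. The
  simulator, using the same model forward, cannot expose this bias — only
  studies against external references can.
* Recording I/O is CSV (plus JSON ground truth); there is no HDF5 reader.
* Bout boundaries are quantised to the 3-s window grid.
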