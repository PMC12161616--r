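---
title: "wheelfit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wheelfit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelfit)
```

## The problem

Commercial activity trackers are calibrated for ambulation and mis-measure
physical activity (PA) in manual wheelchair users. A wheelchair-adapted
monitoring stack instead combines a wrist-worn smartwatch (triaxial
accelerometer at 30 Hz, heart rate at 1 Hz) with a wheel-mounted rotation
sensor (5 Hz), and computes six daily measures: energy burned, distance
traveled, moderate-to-vigorous exercise time, sedentary breaks, total push
count, and current heart rate. `wheelfit` implements that computation stack
end to end — raw streams to per-minute features to daily metrics to a
pre-post study analysis — together with a synthetic-data generator that
provides minute-level ground truth, so every stage is testable at desk scale
without hardware.

## Per-minute features

**Intensity (MAD).** For each calendar minute (half-open interval, grid
anchored at local midnight) the mean absolute deviation of the acceleration
vector magnitude is

$$\mathrm{MAD} = \frac{1}{N}\sum_{i=1}^{N} \lvert r_i - \bar r \rvert,
\qquad r_i = \sqrt{a_{x,i}^2 + a_{y,i}^2 + a_{z,i}^2},$$

in g. MAD is computed on the magnitude rather than per axis (the source
material does not state the axis treatment): magnitude is orientation
invariant, consistent with the MAD cut-point literature, and gives the
clean properties tested in the suite (offset invariance, linear scaling).
A minute with zero accelerometer samples is *null* — its MAD is `NA`, never
zero.

**Cut-points.** `threshold_config()` classifies `MAD < sedentary_ceiling`
as sedentary, `MAD >= mvpa_floor` as MVPA, between as light, with the floor
inclusive. The deployed system used published wheelchair-specific
cut-points whose numeric values are not reproduced here; the defaults
(0.02 g, 0.08 g) are documented placeholders in the plausible wrist-MAD
range. Every group-level study statistic in this package consumes daily
values and is independent of these defaults.

**Pushes.** The cited push-count algorithm's internals are likewise not
public, so `count_pushes()` is an explicit, configurable stand-in:
magnitude detrended by a 1 s centered moving average, local maxima at or
above 0.2 g counted with a 0.5 s refractory period, and the detector is
gated to minutes with nonzero wheel rotations (the wheel sensor activates
its gyroscope only during movement). Two bursts inside one refractory
interval count once by construction.

**Odometry and energy.** Distance is `rotations × π × wheel_diameter`
(default 0.61 m, a standard 24-inch wheel); daily distance is the sum of
minute distances. The energy column uses a pluggable linear model of MAD,
heart rate and body mass (`energy_model()`); the shipped coefficients are
an explicitly *not validated* placeholder, because the population-specific
prediction model the deployed app used is unpublished. `hr_last` is the
minute's latest heart-rate sample, forward-filled across null minutes for
at most 5 minutes.

## Daily metrics

**Sedentary breaks.** Awake time is partitioned into consecutive,
non-overlapping 30-minute windows anchored at waketime; a trailing partial
window is ignored. A window contains a break iff it holds at least 2
consecutive non-sedentary minutes, so a 16-hour awake day has at most 32
breaks. Two published phrasings conflict ("above the light intensity"
vs. "nonsedentary PA"); the non-sedentary reading is the default because
the health rationale and the restatement both use it, and a
`break_rule = "mvpa_only"` switch preserves the alternative. Null minutes
are treated as sedentary for break counting (conservative) and excluded
from MVPA. Window anchoring in the deployed app (clock vs. wake aligned)
is unstated; wake-anchored matches the 32-window arithmetic and is what we
implement.

**Alerts.** Within a window, if the first 25 minutes contain no
2-consecutive-minute non-sedentary run, a sedentary-behavior alert fires
at the 25-minute mark. This is exactly `alert_check()` and is tested
against a direct run-length oracle.

**Coverage and valid days.** Coverage is the fraction of the 1440 day
minutes holding at least one accelerometer sample of nonzero magnitude.
The 30% validity threshold is described in the source as "approximately 8
hours"; 30% of 24 h is 7.2 h, and whether the intended denominator was the
24-hour day or awake time is not stated. We use the 24-hour denominator
(matching the arithmetic that ties 30% to one smartwatch battery charge)
and expose `denominator = "awake"` as an override. A valid day needs
coverage ≥ 30%, no abnormal sensor data (nonzero pushes with zero wheel
distance, or an all-zero wheel stream on a day with non-sedentary wrist
minutes), and a participant-confirmed typical day in the daily log.

## The synthetic world

The generator states one fixed world; its defaults were chosen once from
the study's published conditions and are not tuned against tests:

* awake 07:00–23:00 (16 h, the worked example in the source's break
  definition);
* minute intensity mix (sedentary, light, MVPA) = (0.85, 0.12, 0.03), so
  expected MVPA ≈ 29 min/day, near the published baseline mean of
  26.4 min/day;
* smartwatch battery 10.5 h (published range 10–11 h), modeled as hard
  truncation of both watch streams at waketime + battery life; the wheel
  sensor (1.5-month battery) streams on;
* typical-day probability 0.9;
* propulsion: light bouts wheel with probability 0.3 (10–20 pushes/min,
  5–15 rotations/min), MVPA bouts with probability 0.8 (35–55 pushes/min,
  20–40 rotations/min) — push cadences near 1 Hz as observed in
  over-ground propulsion, rotation rates giving on the order of 1–2 miles
  per day.

Bout durations are drawn uniformly from 5–15 min *independently of
intensity*, and bout intensities are i.i.d. with the profile proportions,
so the expected minute-level mix equals the profile proportions and the
bout-level MVPA fraction is exactly binomial — which is what the
distributional test asserts.

Rendering: each awake minute's accelerometer signal is a 1 g gravity
baseline plus a sample-alternating square wave whose amplitude is solved by
bisection so the noise-free minute MAD equals the generator target for the
scheduled intensity (0.008 / 0.045 / 0.15 g), plus one half-sine burst
(~0.4 s, 0.4 g) per scheduled push, plus optional white noise. For a pure
square wave the MAD equals the amplitude exactly, so sedentary minutes hit
their target to machine precision; when push bursts alone already exceed
the target (busy light minutes) the square-wave amplitude is zero and the
minute still stays below the MVPA floor by construction. Heart rate is an
intensity-dependent mean with AR(1) noise — plumbing, not physiology.

What a green round-trip test establishes: the pipeline recovers scheduled
labels, pushes, rotations and MVPA minutes from its own rendered streams
(noise-free recovery is exact; the acceptance property allows ±2 MVPA
min/day and ±1 push/min). What it does not establish: validity on real
wrist data — the renderer does not model gravity reorientation, terrain,
tremor, or genuinely overlapping activities, and the cut-points and energy
coefficients are placeholders.

## Study analysis

Valid days are averaged to one daily mean per participant and phase
(baseline / intervention). Percent change is
`100 × (intervention − baseline) / baseline` rounded to the nearest
integer *half away from zero* — the convention that reproduces every
published table cell (e.g. −10.2/24.0 → −43). The ratio is pre-rounded at
1e−9 so one-decimal inputs whose true ratio is an exact half are not
pushed off the boundary by binary floating point. A change is
"considerable" only strictly beyond ±10%; the boundary itself (no such
cell occurs in the packaged table) is classified as no considerable
change, because the threshold is defined as something to exceed.

**Wilcoxon signed-rank.** Zero differences are dropped; absolute
differences get average ranks under ties; the normal approximation uses
the tie-corrected variance and *no continuity correction* — with the
correction, the packaged table gives Z = 1.94 for exercise time rather
than the published 1.97 (our computed value is 1.965, which the source's
software rounds half-up to 1.97). The effect size is r = Z/√n with n the
pairs entering the test. Z is signed (positive = increase); the source
prints magnitudes, so the sedentary-break statistic appears there as 0.52
while the signed value is −0.52. Comparing this approximation with exact
enumeration over all 2^n sign patterns, the right discrete counterpart is
the exact *mid-p* (half the observed point mass): the uncorrected normal
tail tracks the mid-p within 0.037 uniformly for n ≥ 5, whereas it can
miss the conventional exact p by up to 0.13 — that conventional p is what
the continuity-corrected variant targets. The test suite's enumeration
oracle therefore uses mid-p.

**Paired t.** Both one- and two-sided p-values are always reported: the
published ESES p (.043) equals the one-sided value for t = 1.84, df = 15,
although the text calls the test two-tailed. The published effect
"d = 4.35" is numerically the standard deviation of the paired
differences, not Cohen's d_z (0.46); it is reported as `sd_diff` under
that description.

**Power.** `power_sample_size()` iterates the exact noncentral-t power of
the paired t test to the smallest adequate n. The source reports n = 13
from G*Power for d = 0.93, power 0.8, α = .05, but does not state the
test family; a paired t computation gives a smaller n, so 13 is not
asserted anywhere — the function is validated against a Monte-Carlo
oracle instead.

**Cohort simulator.** `generate_table2_like_cohort()` draws baseline
phase means from Normal(26.4, 16.9) truncated at zero by resampling and
adds `effect` plus Normal(0, 15) change noise (near the published table's
observed change SD once its one 72-minute outlier is set aside).
Intervention values are deliberately not truncated so the null sampling
distribution of the paired difference stays symmetric — the generator is
a statistical testbed for the inference machinery (its type-I error
checks), not a physiologic model.

## Numerical and degenerate-input choices

* Minute grid: half-open `[t, t + 60 s)`, midnight anchored; a sample on
  a boundary belongs to the later minute.
* Stream ingest: malformed rows are skipped and counted (warning);
  non-matching headers and out-of-order timestamps are hard errors naming
  the offence; an empty accelerometer file is a valid day-long gap.
* All-zero differences make the signed-rank test degenerate (`Z` is `NA`
  with a note); fewer than 5 nonzero differences is an error;
  zero-variance differences make the paired t an error.
* A baseline of zero makes percent change undefined (`NA`), reported as
  missing.
* MAD bisection runs 40 halvings on the noise-free minute signal
  (amplitude resolution far below 1e-6 g).

## Limitations

The renderer and the default cut-points/energy coefficients are stand-ins
wherever the deployed system relied on unpublished algorithms; the
packaged per-participant outcome table carries one-decimal phase means, so
group statistics computed from it match the published values at printed
precision, not to machine precision of the unpublished raw data; and the
analysis module implements a single-group pre-post design only — no
control-group or longitudinal machinery.
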