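---
title: "Methods: sleep detection and rhythm patterns from raw wrist actigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep detection and rhythm patterns from raw wrist actigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actirhythm)
```

## Overview

`actirhythm` processes raw recordings from a wrist-worn sensor — triaxial
acceleration in g (±8 g dynamic range, 100 Hz class devices), ambient light
in lux, and wrist temperature in °C — into (1) detected sleep with
intra-sleep awakenings, (2) a registry of 50 day-level activity, sleep and
circadian rhythm patterns, and (3) cohort-level comparisons. Because
free-living wrist recordings with trustworthy ground truth are hard to
share, the package also contains a first-class synthetic-recording
generator whose ground truth drives the whole validation suite.

## Preprocessing

**Calibration.** Accelerometer output is modelled as a linear function of
true acceleration; per axis we apply `a' = gain * a + offset` (gain first).
Manufacturers supply the constants; the map is exactly invertible, which
the tests exploit.

**Resampling.** Input rates that are integer multiples of 10 Hz are reduced
to 10 Hz by non-overlapping block means. Block averaging is a crude
anti-alias filter with an exactly testable contract (constants are
preserved, channel means are preserved to machine precision); interpolation
would buy nothing at these analysis scales.

**Non-wear.** A minute is non-wear-like when the device is simultaneously
*still* (per-axis range < 0.013 g within the minute) and *thermally
off-body* (mean temperature below 26 °C, or cooling faster than
0.2 °C/min, estimated from the two half-minute means). Maximal runs
shorter than 15 min are discarded — very short off-body episodes cannot be
reliably separated from quiet wear, and chasing them inflates false
positives. The three thresholds are configurable defaults chosen as
field-realistic values, not claims of equivalence to any published
constant set; the 15-min floor is the one fixed rule.

## Minute summaries

The 10 Hz triaxial stream is collapsed to two per-minute activity
summaries:

* **movement** — the square root of the sum of squared successive
  differences of the three axes *within* the minute (599 differences per
  axis at 10 Hz). Differencing suppresses the static gravity component and
  sensor drift and emphasises changes of wrist position. Movement is the
  working activity variable for all downstream patterns. We deliberately
  use the **sum**, not the mean, of squared differences: the detector's
  absolute threshold (0.07) is coupled to this convention, and both are
  documented together.
* **xyz variation** — per-minute mean acceleration per axis, the Euclidean
  norm of successive 1-min differences, then a rolling 10-min median
  advanced by 1 min (90 % overlap, right-aligned). This tracks slow
  postural change rather than within-minute jitter.

Light and temperature are summarised as per-minute means. Non-wear minutes
are missing for movement, xyz variation and temperature; ambient light is
retained. Rolling windows that are more than 50 % missing report missing —
this stops non-wear from leaking numeric values into the sleep rules.

## Sleep detection

A minute is a **sleep candidate** when three rules hold jointly and
strictly:

1. rolling 10-min median movement `< 0.07`,
2. rolling 5-min mean xyz variation `< 0.1`,
3. rolling 5-min mean ambient light `< 30` lux.

Candidate runs of at least 30 min are joined left-to-right whenever the
gap between consecutive runs is at most 30 min; each joined gap is
recorded as an **awakening**. Merged blocks whose span (onset to offset,
awakenings included) is under 2 h are removed — the price of not
mislabelling long sedentary spells as sleep. The light rule is what makes
quiet evening wake (reading, screen time) separable from sleep; a
two-rule mode exists for light-less devices but warns loudly.

Design choices worth stating explicitly:

* **Window alignment.** The smoothing windows inside the detector are
  *centred* by default (configurable). Detection is an offline
  computation, so there is no causality constraint, and trailing windows
  would systematically delay every rule transition by roughly half the
  window width — about +5 min on awakening boundaries through the 10-min
  median — where centred windows localise candidate-mask transitions to
  within about a minute of the underlying signal change. The generic
  `rolling_stat()` utility keeps a trailing default, which is the natural
  convention for exploratory summaries.
* **Span, not summed minutes,** is what the 2-h rule tests; "blocks with
  awakenings inside" are still one sleep episode.
* **Sub-30-min candidate runs inside a gap** neither extend sleep nor
  shorten the recorded awakening; they are discarded before joining.
* **Nights** are noon-to-noon local windows; the block with the longest
  span whose onset falls in the window is the main (nocturnal) sleep, ties
  to the earlier onset. Days for activity patterns are midnight-to-midnight
  (the actogram convention); the noon convention keeps main sleep unsplit.
* Timestamps live in one fixed timezone; daylight-saving transitions are
  out of scope for the generator and untested territory for real data.

Two distinct fragmentation totals are reported per sleep:
`awakenings_total_minutes` (summed joined-gap durations) and
`waso_minutes` (minutes inside the sleep window whose rolling 10-min
median movement breaks the candidate rule). The second is a movement-based
superset that also catches restlessness that never split the candidate
mask; both appear in the registry because they answer different questions.

## The pattern registry

`extract_all()` emits one row per complete civil day with 50 named values
(`pattern_registry()`), spanning: nonparametric rest-activity rhythm (M10,
L5, their start times, relative amplitude RA = (M10−L5)/(M10+L5));
distributional summaries of diurnal activity (mean, skewness, five
percentiles, nocturnal share); interday stability (IS, hourly bins, and a
30-min-stepped variant) and intraday variability (IV at hourly, minute,
and 30-min-stepped resolutions); Teager–Kaiser energy and RMSSD with
diurnal/24-h ratios; composite multiscale sample entropy at 5/30/60/120
min scales; sleep timing/duration/fragmentation/entropy/percentiles; sleep
temperature extrema and their times; night-to-night onset/offset phase
differences wrapped to (−12 h, +12 h]; and a single-component 24-h cosinor
(MESOR, amplitude, acrophase). A short-description/unit sidecar is
available as `pattern_definitions()`. A reasonable reading of the
underlying catalogue counts 49 patterns where this registry emits 50
names (the percentile and CMSE entries counted separately make the
arithmetic ambiguous); we keep all 50 rather than drop one.

Numerical conventions that matter:

* **IS** is `(n · Σ_h (x̄_h − x̄)²) / (p · Σ_i (x_i − x̄)²)` over hourly
  window means clock-binned across the recording. For the 30-min-stepped
  variant the windows are built *clock-periodically* (the recording is
  treated as circular for the final cross-midnight windows) so that every
  clock bin holds exactly one window per day; without this the trailing
  day unbalances the bins and the perfectly-repeated-profile limit IS = 1
  is missed by a few tenths of a percent. IS is interday by definition and
  is replicated across that participant's day rows.
* **IV** is `(N · Σ (Δx)²) / ((N−1) · Σ (x − x̄)²)` at the variant's
  resolution; it is ≈ 2 for white noise and small for smooth profiles.
* **Sample entropy** uses embedding m = 2, Chebyshev distance, tolerance
  r = 0.2 × SD of the original minute series (fixed across scales), and
  counts both template lengths over the same N − m vectors, so a constant
  series gives exactly 0. **CMSE** coarse-grains at every offset grid of a
  scale and averages the defined per-offset entropies, stabilising the
  short coarse-grained series at the 60- and 120-min scales.
* **Sleep entropy** histograms use fixed absolute bin edges (60 bins on
  [0, 3] g plus overflow) so values are comparable across participants;
  natural-log Shannon entropy, so k equally occupied bins give ln k.
* **Percentiles** interpolate linearly between order statistics;
  **skewness** is the adjusted Fisher–Pearson sample form.
* **Cosinor** is an ordinary least-squares fit of
  `M + b1 cos(2πt/24) + b2 sin(2πt/24)` per day (consistent with
  day-level characterisation); amplitude `√(b1²+b2²)`, acrophase the
  fitted peak time in [0, 24).
* **Diurnal window** = previous night's main-sleep offset to the current
  night's onset ("rise time to bed time"); days lacking either boundary
  miss their diurnal features. Days with > 20 % non-wear or no main sleep
  are invalid. Sleep onset/offset are reported on a continuous clock
  (00:30 → 24.5 h) so cross-night means are meaningful.

`summarize_participant()` reduces the day table to per-pattern mean and
sample SD across valid days — the participant-level representation used
for cohort statistics.

## Cohort statistics

Distributions are visualised with normalized histograms (discrete) or
Gaussian-kernel KDEs with Silverman bandwidth evaluated as exact kernel
sums. Pairwise group differences use the two-sample Kolmogorov–Smirnov
test with the asymptotic p-value (cohort sizes of a few dozen make the
exact computation unnecessary), or a Pearson chi-square without continuity
correction for count-valued patterns (a message flags expected counts
below 5). Effect sizes are point-biserial correlations with the
first-listed group coded 0, so negative r means lower values in that
group; |r| > 0.3 is flagged "strong" and p < .05 "significant". No
multiple-comparison correction is applied by design — effect sizes are
reported alongside raw p-values and rows are ranked by |r|, so readers can
apply their own correction.

## The synthetic generator

`generate_recording()` draws a seeded multi-day recording plus exact
ground truth. What it emulates: nightly sleep windows (lights-out around
23:30 ± 30 min, duration 8 h ± 30 min) with gravity-plus-noise
acceleration (0.8 mg per-sample noise, a realistic MEMS noise floor),
light near 1 lux and wrist temperature raised by 2 °C; Poisson-count
awakenings (default rate 1/night, durations 5–25 min) with restless
movement and a 40-lux lamp; intermittent daytime activity as a two-state
on/off process (70 % on) with lognormal burst amplitudes (median 0.1 g)
and occasional posture changes; evening light of 80 lux and daytime light
of 250 lux; optional afternoon naps; and non-wear episodes with a
flatlined accelerometer and exponential cooling toward 22 °C ambient
(τ = 8 min). Awakenings are placed at least 45 min from the sleep edges
and 35 min apart so every true sleep fragment can survive the detector's
30-min segment rule, and their durations stay ≤ 29 min so every true
awakening is joinable under the 30-min gap rule. Amplitudes are tuned once
so that the detector's published absolute thresholds separate sleep from
wake on the calibrated-g scale; the underlying field literature does not
pin quantitative amplitude distributions, so these are documented free
parameters of the generator, not claims about any device.

What it does **not** emulate: sleep-stage structure, heart rate, circadian
entrainment or light-driven phase shifts, long-sleeve light occlusion,
device clock drift, or daylight-saving transitions. Passing the validation
suite therefore demonstrates algorithmic correctness under the stated
signal model, not clinical accuracy on real cohorts — real validation
still requires diaries or polysomnography.

`generate_cohort()` / `cohort_plan()` add per-participant habitual
bedtime/duration shifts (SD 20 min) and group-level config deltas; the
default contrast gives the "fragmented" group an awakening rate of 2.5
versus 1 and stronger wake bursts. `write_diary()` produces a per-night
diary (onset, offset, awakening count) with optional Gaussian reporting
noise; zero noise reproduces truth, which is the anchor for the recovery
experiments.

## Validation protocol and problem sizes

The test suite recomputes, from scratch and under fixed seeds: sleep
recovery on 20 participants × 7 nights (night detection rate, median
absolute onset/offset error ≤ 15 min); exact recovery of all inserted
10–25-min awakenings with ≤ 3 min boundary error and per-night totals
within ± 5 min; literal behaviour of every published detector threshold;
non-wear recovery (≥ 95 % overlap for ≥ 20-min episodes, 10-min episodes
never flagged, < 1 % false-positive worn minutes over six 2-day
recordings); rhythm-metric limits (IS = 1 on identical days, permutation
floor < 0.2 over 100 shuffles, mean minute-level IV of white noise within
[1.95, 2.05] over 200 draws, hourly IV of a sinusoid < 0.3); cosinor
recovery (exact noiseless, mean acrophase error < 0.5 h at noise
σ = 0.5 × amplitude over 100 draws); agreement of every summary statistic
with independent brute-force oracles (100 random inputs each, including a
10,000-draw permutation check of the KS p-value); direction and
significance of the cohort contrast on 30 + 30 participants with a
matching null cohort; and bit-identical pipeline reruns. The same
experiments are rerun by `scripts/acceptance.R`, which writes the headline
numbers as JSON.

## Known limitations

* The detector requires ambient light; the two-rule fallback mislabels
  sedentary wake more often and is deliberately noisy about it.
* Wrist temperature mixes body and environment; it is used for non-wear
  detection and within-person sleep features, not between-person
  comparison.
* Thresholds (0.07 g, 0.1 g, 30 lux) are coupled to this package's
  movement/xyz-variation conventions at 10 Hz on calibrated g units;
  different devices or summaries require re-tuning.
* The KS p-value is asymptotic; at very small cohort sizes a permutation
  or exact test would be preferable.
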