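---
title: "Measuring task repetitive practice from a wrist-worn inertial sensor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring task repetitive practice from a wrist-worn inertial sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristrep)
```

## The problem

Task repetitive practice — performing many repetitions of a functional task
such as lifting a cup — is a core strategy in upper-extremity
rehabilitation, and much of it happens unsupervised in home programs.
A wrist-worn activity monitor sampling tri-axial angular velocity
(degrees/s) and acceleration (m/s²) at 62 Hz offers an objective record of
that practice. `wristrep` implements the full chain from such raw streams
to three interpretable per-trial measures and the psychometric battery that
evaluates whether those measures are reliable and valid:

* **duration** (s): stop minus start of a trial — the time a set of
  repetitions took;
* **average total angular velocity** (degrees/s): the within-trial mean of
  $|V_x| + |V_y| + |V_z|$ — typical rotational speed;
* **total SD of acceleration** (m/s²): $\sigma_x + \sigma_y + \sigma_z$,
  the per-axis standard deviations of acceleration summed — variation in
  movement forces.

The session design the package targets is four functional tasks (cup,
handwriting, letter-in-mailbox, shoe tying), each performed under five
conditions — 5, 10 and 20 repetitions at a comfortable pace, 10 at a fast
pace, and a repeated block of 10 comfortable repetitions — with 30-s rests
between conditions and randomized task/condition order. That yields, per
participant, a repetition-count dose ladder (validity of duration), a pace
contrast (validity of all three measures) and a repeated trial
(within-session reliability).

## The synthetic cohort model

No public recording of such sessions exists, so the package ships a
generator whose ground truth makes every downstream stage testable.

**Signal model.** Each repetition is a half-sine burst per axis: angular
velocity $A_c \sin(\pi t / P)$ over a period $P$, with the burst direction
alternating between consecutive repetitions (a to-and-fro task on signed
channels), and an acceleration burst $B_c \sin(\pi t / P)$ riding on a
constant gravity offset. White Gaussian sensor noise is added to every
channel (defaults: 0.5 degrees/s and 0.05 m/s² per axis, upper-end figures
for consumer MEMS parts at this bandwidth). The half-sine is chosen
deliberately: it is smooth, zero at the endpoints, and gives closed-form
expectations — the mean of $|A\sin|$ over a burst is $2A/\pi$, and the
population SD of a half-sine burst occupying a fraction $q$ of its trial is
$B\sqrt{q/2 - 4q^2/\pi^2}$ — so empirical measures can be checked against
analytic oracles to 1%.

**Repetitions are back to back by default** (inter-repetition gap 0). With
a nonzero gap the active fraction of a trial, $q = rP/(rP + (r-1)g)$,
depends on the repetition count $r$, which would leak a repetition-count
effect into the velocity measure. The design intends velocity and
acceleration to be *null* across 5/10/20 repetitions (only duration carries
the dose), so the default keeps $q = 1$; the gap remains a profile field
and all closed forms handle $g > 0$.

**Pace.** The fast condition multiplies burst amplitudes by
`pace_multiplier_fast` (default 1.4) and divides the period by the same
factor: faster means both quicker and more vigorous, so duration drops
while velocity and acceleration SD rise — the alternative hypothesis of the
pace contrast.

**Individual differences.** Each participant carries two log-normal
multipliers (speed, scaling amplitudes; tempo, scaling periods) with
log-scale SD `between_subject_sd` (default 0.25), and every trial draws
log-normal fluctuations with SD `within_subject_sd` (default 0.10).
Multiplicative effects keep all measures positive and make the true
reliability a simple variance ratio: on the log scale the ICC of any
measure across repeated trials is exactly
$\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$ — about 0.86 ("good") at the
defaults. Parameter-recovery studies therefore estimate the ICC on
log-measures; on the raw scale the lognormal attenuates the correlation to
$(e^{\sigma_b^2}-1)/(e^{\sigma_b^2+\sigma_w^2}-1)$ (0.78 when the truth is
0.80), which is a property of the scale, not an estimator defect.

**Task profiles.** The four default profiles are calibrated loosely to
healthy-adult magnitudes (cup ≈ 110 degrees/s mean total angular velocity
and ≈ 3.5 s per repetition; handwriting slow and low-amplitude at ≈ 37
degrees/s; letter and shoe faster and larger). They are plausible
renderings for testing the pipeline, not reproductions of any cohort.

**Reproducibility.** One root seed; participant-level sub-seeds are derived
by counter, and each trial's multipliers are drawn in a fixed sweep before
any signal is rendered, so a cohort is bit-reproducible and the
measure-level path (`render_streams = FALSE`) yields exactly the truth
table of the rendered path without synthesizing 62-Hz signal. Timestamps
sit on an integer-millisecond 62 Hz grid (optional ±2 ms jitter, default
off).

**What the generator does not emulate:** impaired or compensatory movement,
fatigue drift within a session, device dropouts or clock drift, and any
biomechanically realistic limb trajectory. Passing tests demonstrate that
the pipeline recovers what this model encodes; they do not certify
performance on post-stroke movement.

## Segmentation

Manual identification of trial boundaries — visually spotting transitions
between rest and activity — is replaced by baseline-relative thresholds on
the smoothed total angular velocity:

1. **Baseline.** The stream is cut into 1-s chunks, ranked by median raw
   total angular velocity; the quietest decile is pooled. Baseline =
   pooled median; spread = pooled MAD. Estimating the spread from the raw
   (unsmoothed) signal keeps the enter threshold well clear of the
   smoothed rest trace.
2. **Detection.** On a 0.5-s moving average, a window opens above
   `baseline + 5 MAD`, absorbs dips shorter than `min_rest_s` (5 s — half
   the designed 30-s rests would never be mistaken for activity), and
   closes when the trace stays below the exit level for `min_rest_s`. The
   exit level applies the hysteresis factor (0.5) to the *margin above
   baseline*; applying it to the absolute threshold would put the exit
   below the rest-noise floor and windows would never close. Windows with
   less than 2 s above the enter threshold are discarded.
3. **Refinement.** The coarse average widens each edge by up to half its
   window, so boundaries are re-located on a 0.1-s average and then walked
   outward to the rest level (baseline + 1 MAD, bounded by one coarse
   window) — capturing shallow onsets such as a slow participant's
   handwriting, where the enter threshold is crossed well after movement
   begins. Boundaries snap to sample timestamps; windows are half-open
   `[start, stop)`.

All thresholds are data-relative, so segmentation is invariant to uniform
amplitude scaling. On default-noise synthetic sessions the detector stays
within ±0.25 s of ground-truth boundaries with duration errors well under
2%; on zero-noise signal it is exact to about one sampling interval.

**Ambiguity.** A window whose median smoothed total angular velocity is
less than `contrast_floor` (3.0) times its flanking-rest median is flagged
as ambiguous, as is every window of a session whose detected count
disagrees with the manifest — the algorithmic surrogate for "start and stop
could not clearly be identified". Flagged windows keep their labels but are
excluded from the measure table, and the exclusion rate is reported as
`excluded/total (percent)`. The contrast floor is a documented surrogate,
not a claim about what made trials ambiguous for human analysts; raising it
can only flag more windows, never fewer.

## Measures: the signed-versus-rectified choice

Velocity statistics are computed on rectified (absolute-value) channels, as
the parsing step dictates. For the acceleration SD the package defaults to
the **signed** channels: the measure is meant to capture variation in
movement forces, and on a gravity-dominated axis the SD of the rectified
channel equals the signed SD only while the axis never crosses zero — once
it does, rectification folds the distribution and understates the
variation. The rectified alternative is available
(`accel_sd = "rectified"`) and the report records which was used. Sample
SDs use $n-1$; a sample falling exactly on `stop` is excluded (half-open
window).

## The statistical battery

* **Reliability.** Two-way mixed-effects, absolute-agreement ICC on the
  repeated 10-comfortable trials, computed from the mean squares
  (subjects MSR, trials MSC, error MSE): single-measurement form for
  duration, average-of-k for the two averaged signal measures, with
  F-based (McGraw–Wong) confidence intervals. Negative lower bounds are
  reported as computed. Labels: poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9
  ≤ excellent; 0.90 exactly is "excellent" (left-closed boundaries).
* **Repetition-count omnibus.** Shapiro–Wilk per condition column at
  α = 0.05 gates between a one-way repeated-measures ANOVA (with Mauchly's
  sphericity test, Greenhouse–Geisser corrected p reported alongside and
  flagged for use when Mauchly p < 0.05, effect size partial eta squared)
  and the Friedman test (tie-corrected χ², Kendall
  W = χ²/(n(m−1))). A constant column is treated as failing the gate.
  With three independent column gates at α = 0.05, normal data routes to
  the ANOVA with probability 0.95³ ≈ 0.86.
* **Pace contrast.** Paired t-tests on fast − comfortable differences with
  95% CIs, Cohen's $d_z$ = mean(d)/SD(d) (a pooled-SD d is available
  behind a flag; published d values for this design are not consistently
  reproducible from either formula, so printed d is never treated as an
  oracle), and significance at the Bonferroni-corrected α = 0.05/12 =
  0.004167, reported as 0.004.

Degenerate inputs are handled explicitly rather than silently: zero total
variance is an undefined ICC, zero error variance flags an infinite or zero
F, identical paired conditions give t = 0 and p = 1 with a degeneracy flag,
and fully tied Friedman matrices give χ² = 0, W = 0.

## Problem sizes used by the test suite

The statistical studies run at sizes chosen to balance Monte-Carlo error
against desk-scale runtimes: oracle-equivalence on 100 random small
matrices (n ≤ 12); reliability recovery on 50 cohorts of 200 participants
at a true ICC of 0.8; the condition-effect signature on a few hundred
seeded cohorts of 24 participants at the measure level (the generative
truth the raw pipeline estimates); and full 62-Hz rendering with
segmentation on cohorts of 2–10 participants. The signature check asks a
lot of each seed — twelve null omnibus tests must all stay below the
corrected threshold while twelve alternatives all exceed it — so its
expected pass rate is about 0.97 per cohort by type-I arithmetic alone.

## Known limitations

* The segmentation defaults assume designed rests (tens of seconds) between
  trials; free-living data with incidental pauses shorter than `min_rest_s`
  will merge activities.
* The generator's half-sine bursts have no within-trial tempo drift, so it
  cannot express fatigue effects (such as a declining velocity across 20
  handwriting repetitions) without per-trial profile overrides.
* Reliability here is within-session only; test–retest reliability across
  days is out of scope.
* One stream per participant (dominant side); bilateral analyses are not
  implemented.
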