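---
title: "Methods: smoothness metrics, smoothing spans, and skill indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoothness metrics, smoothing spans, and skill indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannulaskill)
```

## Scope and data model

The package analyses simulator-based hemodialysis cannulation trials:
3-D needle-tip position sampled nominally at 100 Hz plus a synchronous
binary flashback channel (an in-needle LED emulating blood return), with
participant-level metadata (expert global-rating-sheet subscores on a
1-7 Likert scale, years of cannulation experience). Time is stored in
seconds and positions in millimetres, with the units fixed in the file
column names (`time_s`, `x_mm`, ...) to prevent silent unit drift.
Sampling more than 1% away from uniform is rejected rather than silently
resampled — Savitzky-Golay filtering assumes uniform spacing — and
`resample_uniform()` is the deliberate, explicit repair path.

All metrics are computed on the *constrained task*: the window from the
first sample whose z position drops below the skin surface
(`t_entry`) to the end of the record. Without a consistent start and end
point, smoothness values are not comparable across trials. Re-emergences
and reinsertions do not move `t_entry`. We adopt a sample-and-hold time
convention: a sample at spacing `dt` covers `[t, t + dt)`, so `t_end` is
the last timestamp plus `dt` and a run of `k` active flash samples spans
`k * dt`. This convention is what makes the flash-ratio extremes exact:
an uninterrupted flashback from onset to the end of the task yields
exactly 1, and a flash-free trial exactly 0.

## Process metrics

Five per-trial process metrics are computed at each smoothing level:
task time `T`, path length `PL` (sum of Euclidean steps of the
*smoothed* position), the number of speed-profile peaks `Pks`, the log
dimensionless jerk

    LDLJ = -ln | (T^5 / PL^2) * integral ||d^3 x / dt^3||^2 dt |,

and the spectral arc length SPARC of the speed profile. The jerk
magnitude is the full 3-D vector norm — the rotation-invariant
generalization of the scalar form — and the integral uses the
trapezoidal rule. One published formulation writes the speed input to
`Pks` as the derivative of the distance-from-origin scalar
`sqrt(x^2 + y^2 + z^2)`; that quantity is origin-dependent, and we read
it as shorthand for the tip speed. The implementation uses the Euclidean
norm of the velocity vector throughout.

For SPARC, the speed profile is zero-padded to
`2^(ceil(log2 n) + padlevel)` points, its FFT magnitude is normalized by
the DC value, an adaptive cutoff is chosen as the largest frequency at
or below `f_max` where the normalized magnitude still reaches
`amp_threshold`, and the metric is the negated arc length of the
spectrum over `[0, omega_c]` with the frequency axis scaled by
`omega_c`. The defaults (`padlevel = 4`, `f_max = 10` Hz,
`amp_threshold = 0.05`) are the metric's published reference values; all
three are exposed as configuration. A printed variant of the arc-length
formula places the square-root exponent on the derivative term alone;
we use the standard arc-length integrand
`sqrt((1/omega_c)^2 + (dVhat/domega)^2)`, consistent with the metric's
verbal definition. SPARC is exactly amplitude-invariant and always below
−1 for nonconstant profiles; LDLJ is scale- and duration-invariant by
construction, with a noise-free minimum-jerk movement attaining
`-ln 720` (its integrated squared jerk is `720 A^2 / T^5` and `PL = A`).

Degenerate inputs are explicit errors, not silent values: identically
zero jerk (log of zero), identically zero speed (normalization by
`V(0) = 0`), a task that ends at its first flashback, and a segment
shorter than the filter window. The cohort sweep converts these into
per-trial exclusion records with reasons, mirroring how a real study
logs unusable trials, and the analysis layer decides exclusion.

## Derivative estimation and the window-span study

Derivatives of orders 0-3 come from a third-order Savitzky-Golay filter
(`signal::sgolayfilt`), i.e. local cubic least-squares fits, with the
terminal windows handled by polynomial-fit extrapolation rather than
signal padding: padding modes distort jerk exactly at the segment
boundaries that dominate short cannulation trials. Derivative scaling
uses the true sample interval. The filter reproduces cubics exactly —
including at the edges — which the tests use as a machine-precision
oracle.

The window span is the studied smoothing parameter. The default sweep
`{5, 25, 51, 101, 201}` samples corresponds to the minimum usable
window, 1/4 s, 1/2 s, 1 s and 2 s at 100 Hz; any odd list is accepted.
Two discretization facts inform the tests: the per-sample jerk from a
cubic fit smooths the jerk discontinuities at submovement junctions, so
discrete squared-jerk integrals of composite movements converge to the
closed form only as the sampling rate grows (the test oracle uses 10x
upsampling); and the boundary fits leave speed-norm ripples of order
1e-5 relative at movement/pause junctions, which a literal
strict-local-maximum peak count registers. `Pks` therefore defaults to
the literal rule (prominence floor 0) with a configurable floor for
noisy data.

## Skill indicators and the statistical model

Three indicators are analysed. **FR** (flash ratio) is the per-trial
objective outcome: the fraction of time from the first flashback to the
task end during which flashback was maintained. **GRS** defaults to the
sum of four expert subscores — needle holding, needle movement,
flashback quality, overall quality — with palpation retained in the
file format but excluded from scoring, since it does not reflect needle
motion; the subscore set is configurable because published summed
ranges are not always consistent with a fixed four-subscore scale.
**Exp** is years of cannulation experience. GRS and Exp are
participant-level and are broadcast to trials by default, so every
regression pools all trials; the within-participant dependence this
induces is accepted, not corrected, for fidelity to the analysis design
being reproduced (a participant-level aggregation alternative is
exposed via `broadcast = FALSE`).

Process metrics are right-skewed, so all but LDLJ are log-transformed
before standardization, and `T`, `PL`, `Pks` receive a negative
modifier so that larger always means better. Two transforms need care:
SPARC is negative, so we use `-log(-SPARC)` (monotone in SPARC, larger
= smoother), with a flag to skip the log; and `Pks` can be 0, so its
log uses `log(Pks + 1)`. Each predictor is z-scored within each window
span, making slopes comparable across metrics.

Each indicator is regressed on each standardized metric by OLS, and
slopes are compared pairwise with Tukey's studentized-range adjustment
at `alpha = 0.05` in two families: metrics within an indicator-by-span
cell, and spans within an indicator-by-smoothness-metric cell. The
error term of the comparison is not uniquely determined by the design
being reproduced, so both natural readings are implemented behind
`method=`: `"pooled"` (default) pools the residual variance across the
r compared regressions, giving half-width `q * sqrt(mean(se_i^2))` in
the balanced standardized design, and `"per_pair"` is a Tukey-adjusted
slope-difference t-test with half-width
`q * sqrt((se_i^2 + se_j^2) / 2)`. Both use `q_{alpha; r, n-r}`. A
1000-replicate null simulation in the test suite confirms the
family-wise type-I error stays at or below the nominal level at the
study size (r = 5, n = 779).

## The synthetic cohort: what it emulates, and what it does not

The clinical dataset is access-restricted, so a seeded generator stands
in for it. Its defaults are the study conditions: 52 participants, 16
trials each (4 attempts on each of 4 fistulas), 100 Hz, and sensor
noise whose local extrema average 0.06 mm. Everything else is a
modelling choice, made once and documented here:

* **Trajectories** are concatenations of minimum-jerk quintic
  submovements with exactly stationary pauses: an approach/insertion
  (1.2-1.8 s) from 15 mm above the skin to 8 mm below, a
  performance-dependent number of brisk corrective submovements
  (Poisson with mean `6 * (1 - performance)`, 0.2-0.45 s each — human
  corrective jabs run a few hundred milliseconds, and the `duration^-5`
  scaling of integrated squared jerk makes this briskness the feature
  that lets skill-driven jerk clear the residual noise floor at
  moderate smoothing), exponential pauses (mean `0.5 s * (1 -
  performance)`), a levelling glide, and a stationary hold. Pauses are
  exactly constant so noise-free peak counts are exact ground truth.
* **Latent skill** is one scalar per participant, N(0.7, 0.2) truncated
  to [0, 1] (chosen so the simulated flash-ratio distribution sits near
  the reported mean of about 0.8). Each trial realizes a
  *performance* scalar `skill + N(0, 0.2)`: this one number drives both
  the trial's kinematic intermittency and its flashback retention, so
  the outcome metric shares trial-level causal variance with the
  process metrics — the structural reason an objective outcome can
  out-fit an observer score, as observed on real data.
* **Sensor noise** is white Gaussian noise low-pass filtered to 15 Hz
  (4th-order zero-phase Butterworth) and scaled per axis so the mean
  absolute local extremum equals the target peak level. Only that
  extrema statistic is treated as known about the real tracker; the
  bandwidth is a free choice surfaced in configuration. Per-trial peak
  levels are lognormal with mean 0.06 mm and coefficient of variation
  0.3, emulating session-to-session variation in electromagnetic
  tracker noise; a constant level across hundreds of trials would make
  the minimally-smoothed jerk integral an artificially clean function
  of trial duration.
* **Flashback** switches on after a performance-dependent onset delay
  and runs in 0.5 s blocks, each extinguished independently with
  probability `0.6 * (1 - performance)`; at performance 1 the flash is
  uninterrupted and FR is exactly 1.
* **Indicators**: GRS subscores are `round(1 + 6 * skill + N(0, 2))`
  clamped to 1-7 (rater noise of 2 points corresponds to the moderate
  inter-rater reliability typical of Likert rating sheets); experience
  is drawn with a weak skill correlation (weight 0.1, configurable to
  0) on a clinic-realistic 0-38 year scale, reflecting the empirical
  finding that experience barely tracks cannulation skill.

The generator does *not* model forces, finger position, physiological
tremor, hand biomechanics, rater idiosyncrasies beyond additive noise,
or learning across the 16 trials. Tests passing on this cohort
therefore demonstrate that the pipeline recovers the qualitative
structure the generator encodes — monotone smoothness degradation with
intermittency, noise corruption at minimal smoothing, outcome >
observer > experience fit ordering — not that real sensor data would
yield the same numbers.

## Problem sizes and numerical tolerances

The test suite runs cohorts of up to 50 participants by 16 trials
(800 trials) across the full five-span sweep, sizes chosen to exercise
the study-scale code paths while keeping the default check fast; the
Tukey calibration uses 1000 null replicates at the study dimensions
(r = 5, n = 779). Analytic anchors are asserted tightly: the
minimum-jerk LDLJ ceiling within 1%, scale-invariance drift within
0.5%, SPARC amplitude invariance and FR extremes at machine precision,
OLS against its closed form at 1e-10. Monte-Carlo properties use fixed
seeds. Savitzky-Golay projection matrices are cached per
(order, span, derivative, interval) since designing the 201-point
filter per trial would dominate a cohort sweep.

## Known limitations

* The pooled-trial regressions ignore within-participant correlation,
  by design fidelity; standard errors for GRS and Exp are accordingly
  optimistic. Mixed-effects reanalysis is out of scope.
* LDLJ's `T^5` normalization means task duration influences the metric
  at every smoothing level; on data where duration itself tracks skill,
  part of LDLJ's apparent association is duration, not smoothness.
* The adaptive SPARC cutoff depends on spectral resolution and hence on
  the zero-padding level for very short trials; the pad level is
  configuration, not estimation.
* The flash channel is taken at face value (no debouncing); an optional
  minimum-run filter exists for noisy hardware but defaults to off,
  keeping the literal definition.
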