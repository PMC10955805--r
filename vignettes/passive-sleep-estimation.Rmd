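---
title: "Passive sleep estimation and PSQI modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive sleep estimation and PSQI modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Wearable sleep monitors are accurate but not accessible to most people;
smartphones are ubiquitous. somnophone implements a smartphone-only
pipeline that estimates *time spent in bed* — used as a proxy for time
spent sleeping — from two passive sensor streams that nearly any phone
produces: tri-axial accelerometer samples (in g) and device-state
events (screen on/off crossed with locked/unlocked). The nightly
estimates are then aligned with *active* data — daily self-reported
sleep duration and quality, and the weekly Pittsburgh Sleep Quality
Index (PSQI, treated on a 0–14 scale, higher = worse) — and fed into a
correlation analysis, a random-intercept mixed linear regression of
PSQI, and a leave-one-out cross-validated linear PSQI predictor.

Because the kind of cohort this pipeline targets (tens of participants
carrying their own phones for about a month) produces data too
sensitive to redistribute, the package ships a synthetic cohort
generator with the same statistical skeleton, so every stage is
testable end to end and all reported numbers are recomputable from
code.

# The estimation model

## From acceleration to jerk

Phone use produces rapidly changing acceleration; a phone resting on a
mattress or nightstand does not. The discriminating signal is **jerk**,
the first time derivative of acceleration. For consecutive samples
$a_1, a_2$ spaced $\Delta t \le$ `max_gap_seconds` apart,

$$ j = \frac{\lVert a_2 - a_1 \rVert_2}{\Delta t} \quad [\mathrm{g/s}], $$

stamped at the pair midpoint. Pairs spaced wider than the gap limit
(default 1 s) are discarded: a first difference across a multi-minute
outage is not a derivative, and the outage should count as missing
data, not as spuriously tiny jerk.

## Otsu's threshold

The activity/rest cut in jerk magnitude is chosen by **Otsu's method**,
borrowed from image binarization: build a histogram and pick the bin
boundary minimizing the weighted sum of within-class variances
(equivalently maximizing between-class variance). Choices the method
itself does not fix, with our defaults:

* **Scale** — jerk magnitudes are heavy-tailed, so the histogram is
  built on $\log_{10}(j + \varepsilon)$ with $\varepsilon = 10^{-6}$
  g/s; the threshold is mapped back to g/s. A `linear` option exists.
* **Bins** — 256, the image-processing convention.
* **Scope** — fitted once per participant over all of that
  participant's jerk values (`threshold_scope = "participant"`). A
  per-day option exists, but a day spent mostly in bed gives the
  thresholder too little wake mass and degenerates; a participant-level
  fit is stable.
* **Ties** — when several boundaries minimize the criterion, the lowest
  is taken, which leans borderline epochs toward ACTIVE and so is
  conservative against overestimating sleep. The test suite checks the
  implementation against an exhaustive boundary scan, comparing class
  assignments (distinct tied boundaries across an empty histogram run
  imply the same assignment).

## Epoch classification and on-events

Time is tiled into 60 s epochs (an actigraphy convention; coarse enough
to be robust, fine enough for minute-level duration resolution). An
epoch is

* **ACTIVE** if any jerk sample in it exceeds the threshold, **or** any
  device *on-event* falls in it — a transition into screen-on or into
  unlocked, both of which imply user interaction (the first event of a
  stream counts when it already shows an on state, since the prior
  state is unknown);
* **MISSING** if it contains no jerk samples and no device events;
* **INACTIVE** otherwise.

## Bridging missing data

Gaps are resolved by their neighbours: a missing run between two
*matching* states takes that shared state (asleep–gap–asleep stays
asleep); between *mismatched* states it becomes INACTIVE, because a
resumption of data collection is most likely caused by user activity —
the gap therefore belonged to the inactive side. Leading and trailing
gaps have one neighbour only, stay MISSING, and count against coverage.

## Coverage and windows

All data are split into 24-hour windows anchored at **local noon**
(noon-to-noon keeps one night's sleep inside one window; a per-
participant timezone offset is applied only at this anchoring step —
storage stays UTC milliseconds). Window coverage is the fraction of
17,280 five-second bins containing at least one accelerometer sample;
device events do not count. Windows under **60%** coverage are
excluded.

Sleep duration per included window comes from the inactive bouts. The
default `longest_bout` policy takes the longest maximal INACTIVE run —
the main rest period. Because "the remaining bouts of inactivity are
sleep" is genuinely ambiguous between that reading and a sum, a
`sum_min_bout` policy (total INACTIVE time in bouts of at least 30 min)
is provided; neither is asserted to be the only defensible choice.
Brief ACTIVE interruptions are *not* merged away by default
(`merge_active_blips_minutes = 0`).

# Alignment

A daily survey answered on local date $D$ reports the night ending on
$D$; the passive window anchored noon $D{-}1$ → noon $D$ carries the
same night key. Duplicate daily responses on one date keep the first
(deterministic and order-independent after sorting). Night **pairing**
is an inner join: only nights with both an active report and a passive
estimate survive — restricting to pairs removes the night-sampling
discrepancy between streams, which is what drives the mean-level
correlation upward in the paired analysis.

Weekly PSQI predictors are averaged over the half-open look-back window
(previous PSQI timestamp, this PSQI timestamp]; a same-moment daily
response counts exactly once. The first PSQI of a participant has no
window and is dropped from modeling; zero-length windows are dropped;
records missing any predictor are flagged and excluded rather than
imputed, since no imputation model is part of the method.

# Statistical layer

* **Correlations** — Pearson $r$ per variable pair over jointly
  available observations, two-sided $p$ from the $t$ distribution with
  $n-2$ df; no multiplicity correction is applied (raw $p$-values are
  reported). Constant series are reported as undefined with a reason.
* **Mixed model** — `psqi ~ quality + active duration + passive
  duration + (1 | participant)`: participants differ in baseline PSQI,
  so the intercept is random; slopes are fixed. REML by default (ML by
  flag); $p$-values use Satterthwaite degrees of freedom. A boundary
  (zero between-participant variance) fit is flagged, not fatal. The
  participant's first PSQI can be added as a fixed effect by flag; the
  default leaves it out of the reporting set.
* **LOOCV predictor** — ordinary least squares on the same three
  predictors, validated leave-one-out. The default unit is a single
  PSQI window record; a participant-level fold option exists since the
  unit of exchangeability is debatable. Rank-deficient folds are
  skipped and counted. Mean absolute error is the headline metric.

# The synthetic cohort

The generator emulates the study conditions the pipeline assumes: 67
participants × 28 days, 5 Hz accelerometer, nightly sleep averaging
7.5 h (between-participant SD 0.75 h, within 1.0 h) starting near 23:30
local. Its pieces, and what they are for:

* **Jerk regimes** — log-normal magnitudes with medians 1 g/s awake and
  0.02 g/s asleep (log10 SDs 0.25 / 0.15). The 50× median separation
  makes thresholding well-posed at defaults; both regimes are config
  for stress testing. Acceleration is built as a random walk whose
  increments have exactly these finite-difference magnitudes, so the
  pipeline's own jerk computation sees the intended distribution.
* **Screen events** — Poisson episodes at 4/h awake, 0/h asleep; each
  episode emits an unlock followed by an off-and-locked event, so
  on-event detection sees genuine transitions.
* **Missingness** — whole random segments (5–25 min) deleted until the
  day's coverage reaches a Beta(8, 2) target (mean 0.8, so roughly 20%
  missing; about 6% of days fall under the 60% cut, reproducing the
  "some participants contribute no valid windows" structure).
* **Surveys** — daily duration = truth + N(0, 0.75 h), answered with
  probability 0.9; trouble-sleeping quality decreases linearly in true
  duration with rounding noise; weekly PSQI (response rate 0.95) comes
  from a linear model on the week's *true* means with a participant
  random intercept (SD 1), slopes (0.2, 0.4, −0.3) and residual SD 0.5,
  rounded and clamped to 0–14. Generating PSQI from truth rather than
  estimates means estimation error attenuates fitted coefficients —
  the realistic regime.
* **Determinism** — each participant's stream is seeded from the cohort
  seed and participant index, so adding a participant does not
  reshuffle the others, and identical configurations produce
  byte-identical output trees.

Because both the true active and passive durations derive from the same
nightly truth, their coefficients in the full-cohort outcome model are
separated only by the differing noise in the observed predictors; for
parameter-recovery studies the package therefore also provides
`simulate_psqi_windows()`, which draws the three predictors
independently and the outcome from the linear-Gaussian model directly
(the rounded 0–14 variant is optional there). Recovery tests use the
unrounded variant, matching the model they invert. A second
light-weight generator, `simulate_night_series()`, produces night-level
duration triples (truth, report, estimate) with missingness completely
at random, for studying the paired-versus-unpaired correlation
contrast at full cohort size without sensor simulation.

**What passing tests do and do not show.** The generator's regimes are
stylized: no naps, no weekend shift, no battery artifacts, no
heavy-tailed bursts inside sleep, and its missingness is random rather
than behaviorally driven (phones die *because* of use patterns).
Recovery of truth under these conditions validates the implementation
and the method's logic, not its field accuracy; the published
real-data correlation and error figures are not reproducible without
the original sensitive dataset and are not asserted anywhere in the
suite.

# Numerical and scale choices

* Timestamps are double-precision milliseconds since the Unix epoch —
  exact for any realistic date (well under 2^53).
* Coverage fractions are exact rational counts over 17,280 bins, so the
  60% inclusion boundary is a sharp comparison, tested one bin either
  side.
* Validation problem sizes: sensor-level checks run 6–8 participants ×
  5–7 days at 1 Hz sampling (sleep-duration recovery is a property of
  regime separation, not sampling rate, and 1 Hz already fills every
  coverage bin); regression-level checks run at the full 67-participant
  survey scale, with 200 replicates for parameter recovery. These sizes
  are the package's validation design.
* Degenerate inputs: all-identical jerk (no threshold exists), fewer
  than two samples, all-missing windows, constant correlation series,
  zero-length PSQI windows and rank-deficient LOOCV folds all produce
  flagged results or clean errors, never silent numbers.

# Known limitations

* Time in bed is a proxy; quiet wakefulness in bed inflates estimates,
  and the method knows nothing of sleep staging or latency.
* A phone left on a desk while its owner sleeps elsewhere produces a
  convincing false bout; nothing in a single-device stream can rule
  this out.
* The noon anchor mishandles day-sleepers (e.g. night-shift workers),
  whose main rest period straddles the window boundary.
* The Otsu threshold assumes both regimes are present in the fitting
  scope; a fully sedentary recording degenerates.
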