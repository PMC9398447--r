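---
title: "Detecting rodent behaviors from keypoint tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rodent behaviors from keypoint tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behaviorkit)
```

## The problem

Markerless pose estimators (DeepLabCut and its relatives) turn behavior
videos into framewise x/y estimates, with a confidence ("likelihood"), for a
handful of body landmarks. Those coordinates are not yet behavioral data:
the estimates jitter from frame to frame, occasionally fail outright, and a
behavior such as freezing, object investigation or vicarious trial and
error (VTE) is defined by a human criterion on top of the kinematics, often
jointly with where the animal is in the arena. behaviorkit covers the path
from a raw tracking table to behavior calls and assay reports, with rule-based
detectors whose every threshold is visible and tunable, plus the machinery
needed to validate and optimize those detectors against human annotations.

## Cleaning the tracks

`smooth_tracking()` runs, per bodypart and axis:

1. **Likelihood thresholding.** Estimates with confidence strictly below
   `likelihood_threshold` (default 0.1, the conventional cutoff for
   low-confidence tracker output) are rejected.
2. **Hampel outlier removal.** Over a centered window (default 7 frames,
   truncated at the series edges) a point deviating from the window median
   by more than 3 scaled MADs (scale 1.4826, the consistency constant for a
   normal distribution) is replaced by that median. This runs on the
   likelihood-passing frames only, so a confident but teleporting estimate
   is still caught.
3. **Spline interpolation.** All rejected frames are filled by a cubic
   spline through the surviving values; runs at either end of the session
   copy the nearest surviving value rather than extrapolate.
4. **LOWESS smoothing.** Locally weighted linear regression (tricube
   weights, no robustness iterations) over a span of
   `max(5, round(0.2 s × fps))` frames. 0.2 s is short enough to preserve
   genuine movement onset/offset at any common frame rate while averaging
   roughly 6–10 estimates of a quasi-stationary pose. The local fit is
   evaluated at every frame; the usual interpolation shortcut between
   evaluation points must be disabled here because downstream metrics
   differentiate the series, and piecewise-linear output would alias
   velocities into constant-speed plateaus.

The stages and defaults are all exposed (`analysis_params()`), and the
pipeline is close to idempotent: re-smoothing a smoothed track moves points
by well under a tenth of a pixel.

**What smoothing does not remove.** With tracker jitter of ~0.5 px at
50 fps and 10 px/cm, the smoothed position of a perfectly still animal
still wanders slowly, and the implied framewise back velocity has a heavy
tail: its median is ~0.4 cm/s but roughly a quarter of still frames exceed
the 0.59 cm/s freezing threshold. Framewise thresholding alone is therefore
not reliable, which is exactly why the freezing detector has a convolution
stage (below). This is worth remembering when sweeping thresholds on new
camera setups.

## Derived keypoints and the metric table

`expand_keypoints()` appends weighted-average landmarks: `head` (mean of
nose and both ears), `ear_mid`, and — when no mid-back point was tracked —
`back_mid` (mean of `ear_mid` and tailbase) as the back-point stand-in. The
weights are configurable per derived point; derived points are computed
from the smoothed sources so they inherit the cleaning.

`compute_metrics()` then builds the framewise repository every detector
reads: linear velocity (cm/s), acceleration (cm/s²), framewise and
cumulative distance (cm) for every keypoint, plus the head angle (degrees,
wrapped to (−180, 180], measured y-up even though image coordinates are
y-down) and its angular velocity (deg/s, magnitude; the signed series is
kept for VTE analysis). First-frame derivatives copy the first computable
value so a session cannot open with an artificial zero-velocity (i.e.
"freezing") frame.

## Freezing

Freezing is the absence of all movement except respiration. The primary
detector thresholds two metrics jointly — back velocity < 0.59 cm/s and
head angular velocity < 15 deg/s, both strict so boundary frames are
deterministic — then:

* **Convolution smoothing.** A centered sliding window (default
  ~0.9 s wide) counts candidate frames; the count is thresholded at about
  one third of the window. This fuses fragmented detections and suppresses
  isolated false positives, and is what makes the per-frame velocity noise
  tail (above) harmless.
* **Minimum bout duration.** Bouts shorter than 0.9 s
  (`ceiling(0.9 × fps)` frames) are rejected, matching the conventional
  minimum used in fear-conditioning scoring.

The jitter variant (`detect_freezing_jitter()`) instead segments the head,
nose and tailbase velocity traces at mean shifts using greedy binary
segmentation with a squared-error objective: recursively place the split
that most reduces the summed squared deviation from segment means, stopping
when the best improvement falls below `residual_threshold`. A segment is
frozen when its mean velocity is below `freeze_velocity_max`, and by
default all three keypoints must agree (configurable to any/majority). The
two knobs have no universal values — the residual threshold reflects the
squared velocity noise of the specific tracker/camera combination — so the
defaults (5 (cm/s)² and 1.5 cm/s) are set for the ~0.5 px-jitter,
50 fps/10 px-per-cm regime and should be re-tuned with `sweep_optimize()`
elsewhere. Binary segmentation is greedy: its first split is provably the
optimal single split, but its k-split solutions can be worse than the
exhaustive optimum for fixed k (the tests bound this on small inputs
rather than pretend equality).

## Object exploration and T-maze analysis

`detect_object_exploration()` marks a frame as exploration only when all
three criteria hold: (A) the nose is within 2 cm (configurable) of the
object boundary — distance to the polygon boundary, not the centroid; (B)
the head is oriented at the object, operationalized as the ray from the ear
midpoint through the nose intersecting the object region; and (C) no
excluded bodypart (nose, ears, tailbase) is inside the object region, which
rejects climbing. The climbing region defaults to the object polygon itself
with a configurable inflation margin, since an inner boundary "2 cm from
the edge" is ill-defined for objects smaller than 4 cm.

For the T-maze, `extract_trials()` opens a trial when the mid-back point
enters the approach zone and closes it at the first subsequent entry into
either reward zone; that side is the choice. Approach re-entries during an
open trial are ignored, entries into effort zones never close a trial, and
an unfinished trailing trial is discarded with a warning — deliberate
choices for the ambiguous cases a real session produces.
`count_head_turns()` unwraps the head-angle trace inside the choice zone
and counts a turn at each direction reversal whose cumulative sweep since
the last counted event reaches 180°; this is one concrete reading of
"opposing head angles within the choice zone", with the sweep angle
configurable. A trial is VTE when the animal spent ≥ 0.6 s in the choice
zone with ≥ 1 head turn.

## Evaluation, optimization, exploration

All accuracy statistics are framewise: each frame is a true/false
positive/negative against the reference annotation, and precision, recall,
F1 and specificity follow from the counts. Zero-denominator statistics are
reported as undefined (`NA`), never silently as zero.
`interrater_report()` applies the same machinery across human raters.
`sweep_optimize()` re-runs the full detector per grid cell (up to four
axes) and reports the F1-argmax, breaking ties toward the smallest
parameter tuple so results are reproducible.

The exploration tools fit a logistic GLM — the natural generalized linear
model for a binary frame label; metrics are z-scored first so the weights
are comparable — after downsampling the majority class to balance the two
frame sets (seeded, and the seed is recorded). The broad mode ranks all
metrics by |weight| and iteratively prunes below a threshold (default 0.1
on the z-scale, roughly three null standard errors at a few thousand
balanced frames).

## Neural alignment

`behavior_auc()` scores a neuron by the area under the ROC curve treating
its framewise activity as a classifier score for behavior frames — computed
as the rank statistic, so it is invariant to any monotone transform of the
fluorescence. Significance comes from a circular-shuffle null: the behavior
vector is rotated by a random nonzero offset (preserving both the bout
structure and the trace autocorrelation, unlike a framewise shuffle) 1000
times; a neuron is excited above the 97.5th null percentile and suppressed
below the 2.5th (linear-interpolation percentiles, strict inequalities).
Raw traces are used by default; whether to binarize events first is left to
the caller. `align_behavior_to_neural()` resamples behavior onto neural
frame times by nearest frame given both rates and a shared origin.

## The synthetic-session generator

`simulate_session()` produces labeled sessions so every detector can be
validated end-to-end without videos:

* **freezing_session** — alternating locomotion (correlated random walk,
  4 cm/s, heading diffusion ~1°/frame) and frozen poses, bout durations
  uniform on 3–6 s and 4–8 s respectively; a rigid five-point skeleton
  (nose 3 cm ahead of the mid-back, ears at 1 cm × ±0.8 cm, tailbase
  3 cm behind) oriented along the heading; i.i.d. Gaussian tracker jitter
  of 0.5 px on every coordinate; 5% of frames per keypoint dropped below
  the 0.1 likelihood cutoff. Defaults: 50 fps, 10 px/cm, 120 s, 40 × 40 cm
  arena. Optional neural traces add unit-variance noise plus an additive
  gain on behavior frames for planted excited (negative for suppressed)
  cells.
* **noe_session** — a 40 × 40 cm arena with a 6 cm square object and
  scripted one-second approach events that satisfy all three exploration
  criteria, interleaved with rest poses and with one violation of each
  criterion (too far, facing away, climbing). Noiseless, so detections are
  exact.
* **tmaze_session** — scripted runs through the eight maze zones at
  20 cm/s and 30 fps, seeded choice sides, and a scripted 200° choice-zone
  head sweep on the VTE fraction of trials (1 s dwell versus 0.2 s
  otherwise, so the 0.6 s criterion discriminates). Noiseless: zone
  transitions occur at the scripted frames exactly.

What the generator does **not** emulate: real pose-estimator error is
autocorrelated and occasionally switch-swaps body parts; real freezing has
respiration-locked micro-movement; real arenas have lens distortion and
perspective. Passing the recovery tests shows the detectors implement their
definitions correctly under realistic noise magnitudes, not that any given
laboratory video will reach the same scores — that is what
`interrater_report()`/`sweep_optimize()`/`validate_detection()` are for on
the user's own annotated data.

## Numerical conventions and problem sizes

Frames are 0-based with inclusive bout ends internally; annotation CSVs on
disk are 1-based inclusive, as common annotation tools count. Changepoint
boundaries are reported 1-based as the first index of the new segment.
Convolution windows are zero-padded and centered, the extra frame trailing
for even widths. Angles wrap to (−180, 180] with −180 mapped to +180.
Percentiles use linear interpolation. An undefined head direction
(coincident nose and ear midpoint) carries the previous frame's angle and
is flagged. The packaged validation suite runs on 60–120 s synthetic
sessions (3,000–6,000 frames), 84-trial mazes, and 500-neuron null
calibrations at 1000 permutations — sizes chosen so the full suite
completes in about a minute while leaving the statistical assertions
well-powered.

## A worked example

```{r example}
cfg <- scenario_config("freezing_session", seed = 7)
ses <- simulate_session(cfg)
sm <- expand_keypoints(smooth_tracking(ses$ts, ses$params),
                       params = ses$params)
metrics <- compute_metrics(sm, ses$params)
freezing <- detect_freezing_velocity(metrics)
freezing
validate_detection(freezing, annotation_to_vector(ses$annotations$freezing))
```
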