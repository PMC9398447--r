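# behaviorkit

Rule-based behavior detection and assay analysis from markerless pose
tracking, for rodent behavioral neuroscience.

Pose estimators such as DeepLabCut output framewise x/y coordinates and a
confidence value per tracked bodypart, but classifying behavior from those
coordinates — and validating the classification against human annotation —
is left to the user. behaviorkit provides that layer as transparent,
tunable heuristics rather than opaque learned classifiers:

* **Track cleaning**: likelihood thresholding (reject p < 0.1), Hampel
  median/MAD outlier removal, cubic-spline gap interpolation, LOWESS
  smoothing; weighted-average derived keypoints (head, ear midpoint,
  back-point stand-in).
* **Kinematic metrics**: linear velocity v(t) = ‖p(t) − p(t−1)‖·fps (cm/s),
  acceleration, distances, head angle θ(t) and angular velocity |Δθ|·fps
  (deg/s), for every tracked and derived keypoint.
* **Freezing detection**: frames with back velocity < 0.59 cm/s **and**
  head angular velocity < 15 deg/s, fused by a sliding-window count
  (window ≈ 0.9 s, count threshold ≈ window/3) and a 0.9 s minimum bout;
  plus a changepoint ("jitter") variant that segments velocity traces by
  greedy binary segmentation on a squared-error objective.
* **Assay analyzers**: ROI occupancy/entries (elevated plus maze, open
  field), novel-object exploration (nose within 2 cm of the object
  boundary, head oriented at the object, climbing excluded), T-maze trial
  extraction with choice detection, head-turn counting (≥ 180° sweeps) and
  VTE classification (≥ 0.6 s in the choice zone, ≥ 1 head turn).
* **Evaluation tools**: framewise precision / recall / F1 =
  2PR/(P+R) / specificity against reference annotations, inter-rater
  reports, threshold-sweep optimization, logistic-GLM metric exploration,
  discrimination index (A − B)/(A + B), time-window/ROI filtering.
* **Neural alignment**: per-neuron ROC/AUC for behavior coding with a
  1000-permutation circular-shuffle null (excited > 97.5th percentile,
  suppressed < 2.5th).
* **Synthetic sessions**: scripted freezing / object-exploration / T-maze
  sessions with ground-truth labels, so the whole stack is testable
  without any video.

## Worked example

```r
library(behaviorkit)

cfg <- scenario_config("freezing_session", seed = 7)   # 120 s, 50 fps, 10 px/cm
ses <- simulate_session(cfg)

sm      <- expand_keypoints(smooth_tracking(ses$ts, ses$params), params = ses$params)
metrics <- compute_metrics(sm, ses$params)
freezing <- detect_freezing_velocity(metrics)
freezing
#> Behavior 'freezing': 14 bouts, 3017/6000 frames (50.3%)

validate_detection(freezing, annotation_to_vector(ses$annotations$freezing))
#> Framewise evaluation (n=6000): P=0.997 R=0.930 F1=0.963 Spec=0.997
```

The session alternates scripted locomotion (4 cm/s) with frozen poses
under 0.5 px tracker jitter; the detector recovers the scripted freezing
bouts with F1 ≈ 0.96, the errors concentrated in the smoothing-blurred
frames at bout transitions. The same session drives the T-maze and
object-exploration examples in the vignette
(`vignettes/behavior-detection.Rmd`), which documents the model, the
defaults, and every numerical convention.

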