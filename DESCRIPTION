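Package: behaviorkit
Title: Behavior Detection and Assay Analysis from Markerless Pose Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts markerless keypoint-tracking timeseries (DeepLabCut-dialect
    CSV) into smoothed kinematic metrics and detects human-defined rodent
    behaviors with tunable heuristics: velocity-threshold and
    changepoint ("jitter") freezing detection, novel object exploration, and
    vicarious trial and error at T-maze choice points. Includes ROI-based assay
    analyzers (elevated plus maze, open field, T-maze trial extraction and
    choice detection), framewise classifier evaluation
    (precision/recall/F1/specificity), inter-rater comparison, threshold-sweep
    optimization, GLM-based metric exploration, alignment of behavior with
    per-neuron activity traces via ROC/AUC against a circular-shuffle null, and
    a synthetic-session generator that produces labeled trajectories for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mgcv,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
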