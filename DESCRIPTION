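Package: posemotion
Title: Quantifying Actor Motion in Video Stimuli from Pose-Estimation Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the bodily motion of an actor in a video
    clip from per-frame body-pose keypoint data produced by OpenPose-style
    pose-estimation systems. Aggregates per-frame JSON keypoint files into a
    tabular per-clip format, detects and imputes failed or low-confidence
    keypoint observations, computes per-point velocity and acceleration by
    frame differencing, and reduces them to a single motion time series via
    the Euclidean norm of the summed velocity (or acceleration) vectors.
    Also detects which arm(s) the actor moved, probes technical video
    metadata through an external tool, draws keypoint heatmaps and motion
    time-series plots, and generates fully synthetic keypoint fixtures with
    known ground-truth kinematics for testing and validation. Designed for
    stimulus control in sign language and gesture research, where video
    materials must be matched on the actor's movement across conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
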