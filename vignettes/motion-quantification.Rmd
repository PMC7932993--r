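---
title: "Quantifying actor motion from pose-estimation keypoints"
author: "posemotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actor motion from pose-estimation keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posemotion)
```

## The problem

Sign language and gesture experiments present participants with video clips
of an actor signing or gesturing. The technical side of such stimuli
(duration, framerate, encoding) is easy to match across conditions; the
*kinematic* side is not: two condition sets of equal clip length can still
differ systematically in how much, how fast, and with which hand the actor
moves, and that difference can masquerade as a condition effect — for
instance in cortical regions sensitive to biological motion. Markerless
pose estimators such as OpenPose recover a 2-D body-pose skeleton in every
frame of an already-recorded clip, which makes it possible to quantify the
actor's movement retroactively, with no motion-capture hardware.

`posemotion` turns that per-frame keypoint output into per-clip motion
measures: it aggregates the estimator's one-JSON-file-per-frame output into
a tabular per-clip format, repairs tracking dropouts, computes per-point
velocity and acceleration by frame differencing, and reduces them to a
single motion time series per clip.

## The measure

Let \(p_{t,i} = (x_{t,i}, y_{t,i})\) be the pixel position of keypoint
\(i\) in frame \(t\) (image coordinates: origin top-left, y downward), for
a model with \(N\) points (25 for the body25 skeleton). Velocity is the
frame-difference quotient

\[
v_{t,i} \;=\; \frac{p_{t+1,i} - p_{t,i}}{\Delta t},
\qquad \Delta t = 1/\mathrm{fps},
\]

in pixels per second, one value per frame *transition* (\(n-1\) transitions
for an \(n\)-frame clip; acceleration is the second difference, \(n-2\)
entries, px/s²). The clip's motion feature at transition \(t\) is the
Euclidean norm of the *sum* of all keypoint vectors,

\[
MF_1(t) \;=\; \Bigl\lVert \sum_{i=1}^{N} v_{t,i} \Bigr\rVert ,
\]

computed by `en_of_sums()`. Two properties of this definition are worth
making explicit:

* **Closed form under rigid translation.** If all \(N\) points share a
  displacement \(d\) px/frame, \(MF_1 = N \cdot \mathrm{fps} \cdot
  \lVert d \rVert\) at every transition — e.g. 25 points moving (1, 0)
  px/frame at 25 fps give exactly 625 px/s. This is the main numerical
  anchor in the test suite.
* **Cancellation.** The vectors are summed *before* the norm, so equal and
  opposite motions (two hands converging) cancel to zero. That is the
  definition's intent — it measures net bodily displacement, not activity —
  but where total articulator activity is wanted, `sum_of_norms()`
  (\(\sum_i \lVert v_i \rVert\)) is provided under its own name. It is
  never the default.

The per-clip headline scalar for condition matching is the series sum
(`summary()` of a `motion_series` also reports mean, peak, and peak
transition).

## Cleaning: dropouts and low-confidence points

Pose estimators occasionally fail on a point in a frame, emitting an
all-zero \((x, y, c)\) triplet, or fit it with low confidence
\(c\). Feeding either into a difference quotient makes the point "jump",
producing spurious velocity spikes, so before differencing an observation
is declared invalid when it is an all-zero triplet **or** \(c\) falls
strictly below a cutoff (default 0.3; strictly, so \(c = 0.30\) is kept).
Invalid cells are imputed from the same point's valid neighbours:

* an isolated gap takes the mean of the previous and following valid
  frames;
* a *run* of invalid frames is filled by linear interpolation between the
  bounding valid frames — the natural generalization of the isolated-gap
  mean, and the one that makes imputation exact on any affine trajectory
  (a property the tests assert to 1e-9);
* runs touching the clip boundary take the nearest valid value (no
  extrapolation, which could overshoot);
* a point with *no* valid observation anywhere in the clip is an error —
  there is nothing defensible to impute from.

Confidence values are deliberately not rewritten after imputation: an
imputed coordinate is not a high-confidence observation, and provenance is
kept out-of-band in the mask returned via the `"imputed"` attribute.
Cleaning is consequently idempotent on values, and it never alters a valid
cell.

## Laterality

`det_hand()` classifies which arm(s) moved, using the body25 arm chains
(shoulder–elbow–wrist; 0-based indices 2–4 right, 5–7 left, anatomical
labels). Each side's motion is the speed \(\sqrt{v_x^2 + v_y^2}\) summed
over its three points and all transitions. The rule: *none* when both
sides fall below an absolute floor (default 1 px/s summed — essentially
numerical silence); *both* when the smaller side reaches at least
`rel_threshold` (default 0.5) of the larger; otherwise the larger side.
This decision rule and its constants are this package's own heuristic —
no published reference algorithm exists for the task — so every constant
is an argument, and mirror symmetry (flipping the clip and swapping the
left/right point columns swaps the side sums exactly) is enforced by
test rather than assumed.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| `fps` | I/O, kinematics | 25 | clip frame rate; sets \(\Delta t\). Velocities scale linearly with it, so it must match the source video. |
| `cutoff` | cleaning | 0.3 | confidence below which (strictly) a point-frame is imputed |
| `person_policy` | frame parsing | `first` | which person to keep in multi-person frames (`highest_mean_confidence`, `error_if_multiple` available) |
| `rel_threshold` | laterality | 0.5 | side-balance ratio above which a clip is "both-handed" |
| `abs_floor` | laterality | 1 px/s | summed side motion below which a side counts as still |
| `threshold_frac`, `min_len` | segment detection | 0.1, 3 | burst threshold as a fraction of the series max; minimum burst/merge length in transitions |
| `bin_size` | heatmap | 10 px | spatial bin edge for the frontal density plot |

Units are pixels and seconds throughout; the package never converts to
physical units because the camera geometry is unknown.

## Numerical and interface choices

* **Velocity units.** The difference quotient is divided by
  \(\Delta t = 1/\mathrm{fps}\), giving px/s rather than px/frame. Either
  convention is internally consistent; px/s was chosen so that clips of
  different framerates are comparable. The frame-rate-scaling tests
  (doubling fps doubles every value, exactly) pin the convention down.
* **Tabular dialect.** One row per frame, interleaved per-point triplet
  columns `x0,y0,c0,x1,y1,c1,…` matching the flat JSON array order, plus a
  `#model=… fps=… source=…` comment line so a file round-trips model and
  framerate. Values are serialized with 17 significant digits, so
  write-then-read reproduces every double bit-exactly — that is what makes
  "re-running the chain is byte-identical" a meaningful contract.
  Column-blocked layouts (all x, then all y) found in other tools are not
  read; the header names make a mismatch fail loudly.
* **Frame order** comes from the numeric suffix of each JSON filename,
  never from directory listing order; gaps in the numbering are an error
  by default (`missing = "zero"` opts into zero-fill-then-impute).
* **Coordinates** stay in the estimator's image convention (y down). Only
  the heatmap inverts the y axis, and only for display.
* **Video metadata** is read through a pluggable prober function whose
  default shells out to `ffprobe` with a pinned JSON contract. The
  indirection keeps the subprocess boundary explicit and lets tests feed
  canned probe output; the ffprobe path itself errors with an installation
  hint when the binary is missing.

## The synthetic-clip generator

`trajectory_spec()` / `generate_fixture()` produce complete synthetic
clips — per-frame JSON files plus ground truth — from per-point motion
programs (static, linear drift, constant acceleration, Gaussian-windowed
bursts), optional Gaussian coordinate noise, and scripted dropout (all-zero
triplets or sub-cutoff confidences). Valid-cell confidences are drawn
uniformly from [0.6, 1], dropout confidences from [0, 0.3); both choices
are arbitrary but fixed and seed-controlled, and a fixed seed regenerates
byte-identical files. Ground-truth velocity, acceleration, and the motion
series are derived from the noise-free trajectory, so with zero noise the
whole pipeline must reproduce them to 1e-9 end-to-end — that, plus the
closed forms above, is what the test suite and the acceptance script
check. Test problem sizes are deliberately desk-scale (clips of 10–125
frames, 25 points, 100 random sequences for the oracle comparison); every
check is analytic, so nothing is gained from larger inputs.

What the generator does *not* emulate: real detector error structure
(confidence-correlated coordinate bias, person swaps, jitter with heavy
tails), occlusion geometry, camera motion, or rolling-shutter effects.
Passing tests therefore demonstrate the *algebra* of the pipeline on
OpenPose-shaped data, not the behaviour of any detector on real footage.

## Known limitations

* 2-D only: out-of-plane motion is invisible, and pixel velocities are not
  comparable across different camera distances or resolutions.
* \(MF_1\)'s cancellation property means a perfectly symmetric two-handed
  sign can register near-zero net motion; inspect `sum_of_norms()` when
  that matters.
* Multi-person scenes are reduced to one person per frame by
  `person_policy`; there is no identity tracking across frames.
* The laterality rule is a heuristic on three arm points per side; it does
  not see handshape, and bit-compatibility with other implementations of
  arm-choice classification is not claimed.
* Segment detection is a fixed-threshold heuristic intended for plot
  shading and rough onset/offset estimates, not a validated annotation
  algorithm.
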