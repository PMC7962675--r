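---
title: "Detecting microsaccades from iris-texture motion: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microsaccades from iris-texture motion: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Microsaccades are rapid fixational eye movements with amplitudes below about
0.5 degrees of visual angle. Video eye trackers that locate a single large
landmark per frame (the pupil centre, or pupil plus corneal reflection) hit a
noise floor near the size of these movements: a fraction-of-a-pixel error in
one landmark translates directly into spurious velocity. `irisvel`
implements the alternative strategy of tracking the *population* of local
iris-texture features between consecutive frames. The motion estimate per
frame is the geometric median of many matched feature displacements, which is
robust to individual mismatches and reaches well below single-landmark
precision. Around that core the package provides the full measurement chain:
compensation of residual head motion by planar similarity transforms, feature
matching restricted to an iris mask, velocity calibration by linear
regression, edge-preserving denoising, and an adaptive velocity-threshold
event classifier.

Because small-eye-movement ground truth cannot be obtained from recordings
alone, the package includes a synthetic scene renderer that produces eye
videos with known per-frame gaze, known injected head motion, exact iris
masks, and an event log. Every stage is tested against that ground truth.

## The synthetic scene

`scene_config()` + `build_trajectory()` + `render_scene()` draw one or two
textured iris disks (band-pass noise with angular streaks and a dark pupil;
`generate_iris_texture()`) on a face-like background with a bright sclera and
four high-contrast "cheek" patches used by the stabilizer. Gaze in degrees is
converted to pixels at `px_per_degree` (default 40 px/deg; recordings do not
fix this scale, so experiments must state theirs), the iris is placed with
sub-pixel bilinear interpolation, a per-frame similarity transform moves the
whole scene (head motion), and Gaussian sensor noise is added.

Modelling choices, and what they mean for the tests:

* **Saccade kinematics.** Each saccadic event has a raised-cosine velocity
  profile: smooth, unimodal, integral equal to the amplitude, and peak
  velocity equal to `main_sequence_slope * amplitude` (default slope
  47 s^-1). The profile's duration is then fixed at `2 / slope` (about 43 ms,
  roughly four frames at 96 fps). In-flight kinematics are not otherwise
  constrained by the method being tested, so the simplest profile satisfying
  the main-sequence relation was chosen.
* **Fixational drift** is a mean-reverting random walk (Ornstein-Uhlenbeck,
  relaxation time 1 s, short-lag diffusion `drift_sigma^2 t`, default
  `drift_sigma` 0.1 deg/sqrt(s)), lightly low-pass filtered. Pure Brownian
  drift would wander out of any fixation area over a minute; mean reversion is
  both physiologically sensible and necessary for bounded rendering.
* **Benchmark event directions** are fixation-maintaining: once the
  accumulated event displacement exceeds 0.25 deg, the next microsaccade
  points back toward the fixation target with 25-degree angular jitter. Real
  microsaccades correct fixation error in exactly this way; independent
  uniform directions would make gaze position a random walk.
* **Eye motion is rendered as pure 2-D translation** of the iris disk — no
  3-D eyeball rotation, corneal refraction, torsion, eyelashes, or pupil
  dynamics. The tracker itself treats frame-to-frame iris motion as a 2-D
  shift, so the renderer exercises exactly the signal model the tracker
  assumes. Consequences: passing tests show the chain recovers motion under
  its own signal model with realistic noise, sampling and head motion; they do
  not show robustness to perspective foreshortening, torsional slip, blinks,
  or specular reflections on real eyes.
* The rigid-head experiment's "about 2 mm at about 1 Hz" motion is emulated
  as a 12 px, 1 Hz sinusoid, since the mm-to-px factor of the original
  recordings is not available.

## Head-motion compensation

Every frame is aligned to the first frame of the video with a 4-DOF
similarity transform (uniform scale, rotation, translation). Affine and
homography alignments were deliberately not implemented: their extra degrees
of freedom accumulate skew and perspective error over thousands of frames,
which is why the similarity model is the one worth cascading.

Per consecutive frame pair, each of four rectangular facial patches is
matched independently (feature detection, brute-force L2 descriptor matching,
Lowe ratio test at 0.75, RANSAC), and each patch's matches are collapsed to a
single correspondence by taking the geometric median of the source points and
of the destination points. The four correspondences give a closed-form
least-squares similarity fit. Transforms are cascaded within a keyframe block
and the chain is re-anchored by matching each new keyframe directly to the
previous keyframe, every 480 frames (5 s at 96 fps) by default — less
frequent realignment accumulates drift, more frequent realignment raises
jitter frequency. The parameter discontinuity at each keyframe switch is
logged as jitter. If fewer than three patches match confidently in a pair,
the previous pairwise transform is reused and a warning recorded.

Frames are warped *into* reference coordinates by inverse mapping with
bilinear interpolation (whether the original work warped forward or inverse
is not stated; inverse warping avoids holes and is the package's choice).

## Feature detection and sub-pixel matching

No OpenCV binding is available to R, and only displacement statistics are
consumed downstream, so the detector is interchangeable by design and is
implemented in-package: a single-scale difference-of-Gaussians blob detector
(the spatial-frequency band of iris texture is narrow), 9x9 contrast-
normalised intensity-patch descriptors, brute-force L2 matching with the
ratio test, and RANSAC under a 2-D translation model with a 1.5 px inlier
radius (per-patch and per-iris motion is locally translational). Matched
displacements are refined to sub-pixel accuracy by a few Lucas-Kanade
(inverse-compositional) translation updates of each destination point,
clamped to ±1 px of the integer match; on rendered scenes with known
fractional shifts this puts the geometric-median shift error near 0.01–0.03
px, which is what makes 0.5%-level calibration and sub-degree-per-second
velocity noise possible at 40 px/deg.

## Velocity, calibration, denoising

Iris features are extracted from a CLAHE-equalised grayscale image (clip
limit 2, 8x8 tiles; CLAHE raises the matchable-feature count on low-contrast
irises), restricted to the iris mask eroded by 5 px so descriptor patches
stay on iris texture. The per-frame motion sample is the geometric median of
the matched shifts (Weiszfeld iteration, tolerance 1e-7, perturbation restart
on data-point collisions). Samples with fewer than 8 inliers are gaps;
up to 3 consecutive gap frames are bridged by zero-order hold, longer runs
become NA.

The relative position trace is the cumulative sum of shifts. Calibration is
ordinary least squares of known target angles on the median plateau position
per target (first 0.15 s of each fixation discarded as landing time), per
axis; velocity is `gain * shift * fps`.

Total-variation denoising solves `min ½||x−y||² + λ TV(x)` *exactly* with a
direct non-iterative solver; the test suite checks it against a generic
box-constrained convex solver applied to the dual. λ defaults to 0.1 for all
traces (per-eye/axis overrides are supported, as unusually noisy recordings
may need 0.15–0.20). Whether the original chain denoises position or
velocity is ambiguous ("the raw signal"); the package denoises the
**position** trace per axis by default and differentiates afterwards
(`tvd_domain = "velocity"` switches). On a monotone stretch — a saccade in
flight — any monotone solution has the same total variation, so TVD leaves
in-flight samples essentially untouched while flattening sub-λ drift
wiggles: exactly the edge-preserving behaviour the detector needs.

Cyclopean velocity is the per-frame arithmetic mean of the two eyes'
velocity vectors, then the Euclidean magnitude (pure vergence cancels); a gap
in either eye is a gap in the output.

## Event detection

A two-component 1-D Gaussian mixture is fitted by EM (deterministic
two-means initialisation at the lower/upper quartiles) to cyclopean speeds
below 20 deg/s — the cut that keeps large saccades out of the fit. The two
components represent tracking noise and microsaccades. The detection
threshold is `max(noise_mean + 3·noise_sd, 3.84)` deg/s: mean plus three
sigma covers 99.7% of the noise component, and 3.84 deg/s is the empirical
noise-floor lower bound (treated as a fixed constant; no closed form is
claimed for it). The mixture is fitted once per trial (a static fit was
sufficient; sliding-window refits are out of scope). The microsaccade
component is used only for diagnostics, as its role in the thresholding rule
is not specified beyond the noise side.

Runs of samples above threshold (minimum run length 1, configurable) become
candidate events; events whose peak frames are closer than 5 frames (52 ms at
96 fps) are merged, so post-saccadic oscillations and overshoot corrections
are not double-counted. Event onset/offset are extended to the flanking local
minima of the speed trace, under strict-descent semantics so a denoised-flat
stretch next to an event is itself the minimum. Amplitude is the Euclidean
displacement of the (per-eye and mean) position between the two
flanking-minimum frames. Events with peak speed at or above 50 deg/s are
labelled saccades and excluded from microsaccade outputs. Events overlapping
gap frames are dropped with a warning.

Peak speed is estimated by 3-point parabolic interpolation around the peak
sample. At 96 fps a ~43 ms raised-cosine event spans about four frames, and
each discrete velocity sample is the mean velocity over a frame interval; the
maximum sample therefore underestimates the true peak by 5–18% depending on
phase. The parabola removes the phase-dependent part of that bias (the
residual windowing loss of ~5% remains), which keeps recovered main-sequence
slopes within a few percent of the generator's.

Scoring against ground truth is greedy one-to-one onset matching within ±50
ms; an optional interval de-duplication filter (one voluntary movement per
target interval) is available for task designs that prescribe it.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `px_per_degree` | 40 | px/deg | image scale; free choice, stated per experiment |
| `fps` | 96 | Hz | target recording rate |
| keyframe interval | 480 | frames | drift vs jitter-frequency trade-off (5 s) |
| Lowe ratio | 0.75 | – | standard ratio-test value (not stated by the source method) |
| RANSAC inlier radius | 1.5 | px | translation-model tolerance per patch |
| min inliers per sample | 8 | matches | below it the frame is a gap |
| TVD λ | 0.1 | deg | one value for all traces; per-eye overrides possible |
| GMM input cut | 20 | deg/s | keeps saccades out of the mixture |
| threshold floor | 3.84 | deg/s | empirical noise-floor bound |
| saccade cut | 50 | deg/s | microsaccade/saccade label split |
| min peak separation | 5 | frames | 52 ms; merges oscillation peaks |
| `drift_sigma` | 0.1 | deg/√s | fixational drift diffusion in the renderer |
| sensor noise | 2 | grey levels | renderer default |

## Numerical choices and degenerate inputs

Weiszfeld iteration stops at 1e-7 px or 200 iterations and restarts with a
small perturbation when an iterate lands on a data point. The similarity fit
is the closed-form complex-Procrustes solution and errors out when all
source points coincide. Ellipse fitting uses the direct algebraic
least-squares formulation with the ellipse constraint, on centred/scaled
coordinates for conditioning; fewer than five points or collinear points are
errors. The TVD solver handles NA gaps by denoising each finite segment
independently; λ = 0 returns the input. The CLAHE wrapper pads images by edge
replication to a tile multiple and crops back. Empty match sets, blank
patches, all-gap traces and empty training sets raise errors or warnings
rather than propagating silently. Mixture fits refuse fewer than 50 usable
samples (callers fall back to the floor threshold) and identical samples
(degenerate variance).

The U-Net trainer follows the published recipe (two 3x3 conv + batch norm +
ReLU blocks per stage, 2x2 max pooling, nearest-neighbour upsampling by two
with skip concatenation, pixel-wise softmax cross-entropy, Adam at lr 1e-4
with moment decays 0.55/0.99, batch size 8); depth and width are
config-exposed because the published depth/channel counts are not stated
(defaults: depth 4, base 64). Batch-norm placement is Conv → BN → ReLU, the
conventional reading of the ambiguous description. The backward pass is
verified against finite differences in the test suite. Labelled frames whose
eyelids fully cover the iris are a known labelling inconsistency; the label
path here (ellipse + lid clipping) can produce empty masks, which callers
should flag and exclude rather than train on.

## Test problem sizes

The suite exercises the full chain at sizes chosen to keep every stage's
behaviour measurable: unit fixtures of a few frames; the standard detection
benchmark of 65 s at 96 fps (9-point calibration phase plus 60 s with 20
injected microsaccades of 0.2–0.5 deg, sinusoidal 12 px / 1 Hz head motion,
two eyes at 480x320 px); and a 960-frame rigid-scene stabilization benchmark.
The acceptance script reruns the detection benchmark end to end from a seed.

## Known limitations

* The renderer's translation-only eye model cannot expose failure modes
  caused by torsion, perspective, blinks, eyelashes or corneal reflections.
* The classical fallback segmenter assumes a dark pupil inside a brighter
  iris inside a bright sclera; it is a pipeline/test utility for rendered
  scenes, not a general segmenter.
* The U-Net trainer is pure R and sized for small synthetic sets; training
  at the published scale (hundreds of 224x224 frames, 40 epochs) is
  possible but slow without a GPU framework.
* Torsional eye movements are ignored by design, and blink handling is
  limited to gap bridging and the calibration gap-free requirement.
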