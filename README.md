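# irisvel

Video-based detection of microsaccades — fixational eye movements smaller
than about 0.5° of visual angle — from the motion of **iris texture
features** between frames, rather than from the position of a single
landmark such as the pupil centre.

The package is for vision and oculomotor researchers who record
high-resolution eye video (the reference conditions are 96 fps recordings)
and need to resolve eye movements near or below the noise floor of
pupil/corneal-reflection trackers, and for methods developers who want each
stage of such a pipeline individually testable against ground truth.

## The method

For each pair of consecutive, head-stabilized frames, features are detected
in a CLAHE-equalised grayscale image inside the iris mask, matched by
brute-force L2 descriptor comparison with Lowe's ratio test and RANSAC, and
the per-frame iris motion is the **geometric median** of the matched
displacements:

    m_t = argmin_m Σ_k || d_k(t) − m ||        (d_k = matched feature shifts, px)
    v_t = g · m_t · f_s                        (g: deg/px by calibration, f_s: fps)

Position is the cumulative sum of shifts, calibrated by linear regression on
known fixation targets, and denoised by exact 1-D total-variation
minimisation, `min_x ½‖x−y‖² + λ·TV(x)` with λ = 0.1, which flattens drift
noise while leaving saccadic edges intact. Head motion is removed beforehand
by cascading 4-DOF similarity transforms estimated from geometric-median
correspondences of four facial patches, with keyframe realignment every 480
frames.

Events are classified with an adaptive velocity threshold (I-VT): a
two-component Gaussian mixture is fitted to cyclopean speeds below 20 deg/s
(noise vs microsaccade distributions) and the threshold is

    θ = max( μ_noise + 3 σ_noise , 3.84 deg/s )

Runs above θ become events; peaks closer than 5 frames (52 ms) are merged;
events peaking at ≥ 50 deg/s are saccades; amplitude is the gaze
displacement between the flanking minima of the cyclopean speed trace, and
the main sequence (peak velocity vs amplitude) is fitted through the origin.

A synthetic scene renderer (textured iris disks, scripted gaze with
raised-cosine saccade kinematics on a main-sequence slope of 47 s⁻¹,
Ornstein–Uhlenbeck fixational drift, injected planar head motion, exact
masks and event logs) makes every stage testable without recordings. An iris
segmentation toolkit is included: least-squares ellipse fitting with eyelid
clipping by quadratics for label construction, a small U-Net trainer
(pixel-wise cross-entropy, Adam at lr 1e-4, β₁ 0.55, β₂ 0.99, batch 8), the
IoU metric, and a classical fallback segmenter for CNN-free runs.

## Worked example

Simulate a short two-eye recording — a 9-point calibration phase followed by
3 s of fixation with two injected microsaccades (0.35° and 0.45°), sinusoidal
head motion of 12 px at 1 Hz — and run the full pipeline:

```r
library(irisvel)
cfg <- pipeline_config(
  scene      = scene_config(),            # two eyes, 480x320 px, 96 fps, 40 px/deg
  duration_s = 3,
  events     = list(gaze_event("microsaccade", 0.8, 0.35, 15),
                    gaze_event("microsaccade", 2.0, 0.45, 200)),
  calibration = list(extent_deg = 1, dwell_s = 0.4),
  head_motion = list(kind = "sinusoid", amplitude = 12, frequency = 1),
  seed = 42)
res <- run_pipeline(cfg)
res
#> pipeline run: threshold 3.84 deg/s; 2 events (2 microsaccades)
#>   vs truth: 2 hits, 0 misses, 0 false alarms
```

The adaptive threshold stayed at the 3.84 deg/s floor (the drift-noise
component is well below it), both injected events were detected with no
false alarms, and the event table carries onsets, parabolic-refined peak
speeds and flanking-minima amplitudes:

```r
subset(res$events, select = c(onset_s, peak_speed, amplitude, label))
#>    onset_s peak_speed amplitude        label
#> 1 4.776042   16.01423 0.4060619 microsaccade
#> 2 5.994792   19.07991 0.4045461 microsaccade
res$calib[[1]]
#> calibration: gain (0.024844, 0.025116) deg/px, R^2 (0.9978, 0.9970)
```

Onsets are absolute (the calibration phase occupies the first 4 s); the
recovered calibration gain is within ~1% of the renderer's true scale
(1/40 = 0.025 deg/px). `plot_outputs(res)` writes the speed trace with event
shading, the main-sequence scatter, and a rate boxplot.

A command-line front end with `simulate`, `stabilize`, `track`, `detect`,
`evaluate` and `run` subcommands is installed at `inst/cli/irisvel.R`.

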