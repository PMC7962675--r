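Package: irisvel
Title: Microsaccade Detection from Iris-Texture Motion in Eye Videos
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Video-based detection of small eye movements (microsaccades)
    from the motion of iris texture features between frames. Provides a
    synthetic eye-video renderer with ground-truth gaze, head motion and
    iris masks; planar head-motion compensation by similarity transforms
    estimated from geometric-median feature correspondences in facial
    patches, cascaded with periodic keyframe realignment; iris velocity
    estimation from masked feature matching (CLAHE preprocessing, Lowe
    ratio test, RANSAC, geometric median of matched shifts), linear
    regression calibration and exact 1-D total-variation denoising; and
    adaptive velocity-threshold event detection with a two-component
    Gaussian mixture on the cyclopean speed trace. Includes an iris
    segmentation toolkit: least-squares ellipse fitting, eyelid clipping
    by quadratics, a small U-Net trainer, and a classical fallback
    segmenter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
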