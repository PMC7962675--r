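# Synthetic eye-scene generator: textured iris disks on a face-like
# background with four high-texture stabilization patches, scripted gaze
# trajectories, injected planar head motion, ground-truth masks and event
# logs. Every downstream stage of the pipeline is testable against the
# renderer's ground truth without any recorded data.

#' Synthetic scene configuration
#'
#' Geometry, optics and noise of the rendered eye video. Defaults mirror
#' the recording conditions the pipeline targets (96 fps); the pixels-per
#' -degree scale of real recordings is not fixed by the method, so the
#' default (40 px/deg) is a package choice that all experiments state.
#'
#' @param frame_width,frame_height Frame size in px.
#' @param fps Frame rate in Hz (default 96).
#' @param px_per_degree Image scale in px per degree of gaze (default 40).
#' @param iris_radius,pupil_radius Iris and pupil radii in px
#'   (`pupil_radius < iris_radius`).
#' @param texture_seed Seed for the iris texture (same seed, identical
#'   texture).
#' @param texture_band Spatial wavelength band (px) of the iris texture.
#' @param sensor_noise_sigma Additive Gaussian sensor noise, grey levels.
#' @param eyelid_occlusion Fraction of the iris height covered by the
#'   upper eyelid, in [0, 0.4].
#' @param n_eyes 1 or 2.
#' @param interocular_px Distance between eye centres (two-eye mode).
#' @return List of class `scene_config` with derived fields `eye_centers`
#'   (n_eyes x 2 matrix) and `patch_regions` (list of 4 rectangles
#'   `c(x0, y0, w, h)` for head stabilization).
#' @export
scene_config <- function(frame_width = 480, frame_height = 320, fps = 96,
                         px_per_degree = 40, iris_radius = 30,
                         pupil_radius = 12, texture_seed = 1,
                         texture_band = c(3, 9), sensor_noise_sigma = 2,
                         eyelid_occlusion = 0, n_eyes = 2,
                         interocular_px = 180) {
  if (fps <= 0 || px_per_degree <= 0) stopf("fps and px_per_degree must be positive")
  if (frame_width <= 0 || frame_height <= 0) stopf("frame dimensions must be positive")
  if (pupil_radius >= iris_radius)
    stopf("pupil radius (%g) must be smaller than iris radius (%g)",
          pupil_radius, iris_radius)
  if (!n_eyes %in% 1:2) stopf("n_eyes must be 1 or 2")
  if (eyelid_occlusion < 0 || eyelid_occlusion > 0.4)
    stopf("eyelid_occlusion must be in [0, 0.4]")
  cx <- frame_width / 2; cy <- frame_height / 2
  centers <- if (n_eyes == 2)
    rbind(c(cx - interocular_px / 2, cy), c(cx + interocular_px / 2, cy))
  else rbind(c(cx, cy))
  ps <- 40  # textured patch content side
  pm <- 14  # margin for head-motion excursion inside the extraction rect
  corners <- rbind(c(34, 34), c(frame_width - 34, 34),
                   c(34, frame_height - 34), c(frame_width - 34, frame_height - 34))
  patches <- lapply(seq_len(4), function(i) {
    c(x0 = max(1, corners[i, 1] - ps / 2 - pm), y0 = max(1, corners[i, 2] - ps / 2 - pm),
      w = ps + 2 * pm, h = ps + 2 * pm)
  })
  structure(list(frame_width = frame_width, frame_height = frame_height,
                 fps = fps, px_per_degree = px_per_degree,
                 iris_radius = iris_radius, pupil_radius = pupil_radius,
                 texture_seed = texture_seed, texture_band = texture_band,
                 sensor_noise_sigma = sensor_noise_sigma,
                 eyelid_occlusion = eyelid_occlusion, n_eyes = n_eyes,
                 interocular_px = interocular_px,
                 eye_centers = centers, patch_content = ps,
                 patch_centers = corners, patch_regions = patches),
            class = "scene_config")
}

#' Generate a synthetic iris texture
#'
#' Radially organised band-pass noise with angular streak modulation and a
#' dark pupil, standing in for the local iris texture features that the
#' tracker follows. Deterministic given `texture_seed`; the texture has
#' enough local contrast for a blob detector to find well over 50
#' keypoints inside the iris annulus at default settings.
#'
#' @param config A [scene_config()].
#' @return Square grey matrix of side `2 * iris_radius`, values [0, 255].
#' @export
generate_iris_texture <- function(config) {
  r <- config$iris_radius
  side <- 2 * r
  with_seed(config$texture_seed, {
    base <- matrix(stats::rnorm(side^2), side, side)
    lo <- config$texture_band[1] / 2.355  # wavelength -> gaussian sigma
    hi <- config$texture_band[2] / 2.355
    bp <- EBImage::gblur(base, sigma = lo) - EBImage::gblur(base, sigma = hi)
    bp <- bp / stats::sd(bp)
    cx <- r + 0.5
    xs <- matrix(rep(seq_len(side), each = side), side) - cx
    ys <- matrix(rep(seq_len(side), times = side), side) - cx
    ang <- atan2(ys, xs)
    # angular streaks: a seeded Fourier series over the polar angle
    nh <- 12
    amps <- stats::rnorm(nh); phs <- stats::runif(nh, 0, 2 * pi)
    streak <- matrix(0, side, side)
    for (h in seq_len(nh)) streak <- streak + amps[h] * cos((h + 4) * ang + phs[h])
    streak <- streak / stats::sd(streak)
    tex <- 128 + 34 * (0.75 * bp + 0.45 * streak)
    rad <- sqrt(xs^2 + ys^2)
    # dark pupil with a soft edge
    pe <- pmin(pmax(rad - config$pupil_radius + 0.5, 0), 1)
    tex <- tex * pe + (28 + 4 * base) * (1 - pe)
    pmin(pmax(tex, 0), 255)
  })
}

#' Gaze event specification
#'
#' @param kind One of `"microsaccade"`, `"saccade"`, `"drift_segment"`,
#'   `"pursuit_segment"`.
#' @param onset Onset time in s.
#' @param amplitude Amplitude in deg (>= 0).
#' @param direction Movement direction in deg (polar, 0 = rightward).
#' @param main_sequence_slope Peak-velocity/amplitude ratio in 1/s
#'   (default 47). For saccadic kinds the peak velocity is
#'   `slope * amplitude` and the duration follows from the raised-cosine
#'   velocity profile (`2 / slope`).
#' @param duration Duration in s; derived for saccadic kinds, required for
#'   drift/pursuit segments.
#' @return List of class `gaze_event`.
#' @export
gaze_event <- function(kind, onset, amplitude, direction = 0,
                       main_sequence_slope = 47, duration = NULL) {
  kind <- match.arg(kind, c("microsaccade", "saccade", "drift_segment",
                            "pursuit_segment"))
  if (amplitude < 0 || onset < 0) stopf("amplitude and onset must be >= 0")
  saccadic <- kind %in% c("microsaccade", "saccade")
  if (saccadic) {
    duration <- 2 / main_sequence_slope
  } else if (is.null(duration)) {
    stopf("%s events need an explicit duration", kind)
  }
  structure(list(kind = kind, onset = onset, amplitude = amplitude,
                 direction = direction,
                 main_sequence_slope = main_sequence_slope,
                 duration = duration,
                 peak_velocity = if (saccadic) main_sequence_slope * amplitude else NA_real_),
            class = "gaze_event")
}

# analytic raised-cosine displacement profile: fraction of the amplitude
# travelled at phase u in [0, 1]
raised_cosine_pos <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u - sin(2 * pi * u) / (2 * pi)
}

#' Build a per-frame gaze trajectory from scripted events
#'
#' Fixational drift is a low-pass, mean-reverting random walk
#' (Ornstein-Uhlenbeck; diffusion `drift_sigma^2 t` at short lags,
#' relaxation time 1 s, lightly smoothed). Saccadic events contribute a
#' smooth, unimodal raised-cosine velocity profile whose integral equals
#' the amplitude and whose peak equals `slope * amplitude`. Binocular mode
#' yields identical (conjugate) trajectories for both eyes unless a
#' per-eye offset is given.
#'
#' @param events List of [gaze_event()]s, sorted, non-overlapping.
#' @param duration Total duration in s.
#' @param config A [scene_config()].
#' @param drift_sigma Drift diffusion in deg/sqrt(s) (default 0.1).
#' @param seed Seed for the drift.
#' @param per_eye_offset Optional n_eyes x 2 matrix of constant per-eye
#'   gaze offsets in deg.
#' @return List of class `gaze_trajectory`: `gaze` (n_frames x 2 x n_eyes
#'   array, deg), `saccadic` (n_frames x 2 conjugate saccadic component),
#'   `events` (data frame with realized onset/offset frames, peak
#'   velocity, amplitude), `fps`, `times`.
#' @export
build_trajectory <- function(events, duration, config, drift_sigma = 0.1,
                             seed = 1, per_eye_offset = NULL) {
  fps <- config$fps
  n <- round(duration * fps)
  times <- (seq_len(n) - 1) / fps
  ev <- Filter(function(e) e$kind %in% c("microsaccade", "saccade"), events)
  other <- Filter(function(e) !e$kind %in% c("microsaccade", "saccade"), events)
  # overlap check over expanded durations
  all_ev <- events[order(vapply(events, function(e) e$onset, 0))]
  if (length(all_ev) > 1) {
    on <- vapply(all_ev, function(e) e$onset, 0)
    off <- on + vapply(all_ev, function(e) e$duration, 0)
    bad <- which(on[-1] < off[-length(off)])
    if (length(bad))
      stopf("overlapping events: %s",
            paste(sprintf("(%d,%d)", bad, bad + 1), collapse = ", "))
  }
  sacc <- matrix(0, n, 2)
  ev_log <- data.frame(kind = character(0), onset_s = numeric(0),
                       offset_s = numeric(0), onset_frame = integer(0),
                       offset_frame = integer(0), amplitude = numeric(0),
                       direction = numeric(0), peak_velocity = numeric(0))
  for (e in ev) {
    u <- (times - e$onset) / e$duration
    disp <- e$amplitude * raised_cosine_pos(u)
    dir <- c(cos(e$direction * pi / 180), sin(e$direction * pi / 180))
    sacc <- sacc + cbind(disp * dir[1], disp * dir[2])
    ev_log <- rbind(ev_log, data.frame(
      kind = e$kind, onset_s = e$onset, offset_s = e$onset + e$duration,
      onset_frame = min(n, floor(e$onset * fps) + 1L),
      offset_frame = min(n, ceiling((e$onset + e$duration) * fps) + 1L),
      amplitude = e$amplitude, direction = e$direction,
      peak_velocity = e$peak_velocity))
  }
  pursuit <- matrix(0, n, 2)
  for (e in other) {
    if (e$kind == "pursuit_segment") {
      u <- pmin(pmax((times - e$onset) / e$duration, 0), 1)
      dir <- c(cos(e$direction * pi / 180), sin(e$direction * pi / 180))
      pursuit <- pursuit + cbind(e$amplitude * u * dir[1], e$amplitude * u * dir[2])
    }
  }
  drift <- matrix(0, n, 2)
  if (drift_sigma > 0) {
    drift <- with_seed(seed, {
      dt <- 1 / fps; tau <- 1
      d <- matrix(0, n, 2)
      step_sd <- drift_sigma * sqrt(dt)
      for (ax in 1:2) {
        z <- stats::rnorm(n, sd = step_sd)
        x <- numeric(n)
        for (i in 2:n) x[i] <- x[i - 1] * (1 - dt / tau) + z[i]
        d[, ax] <- x
      }
      # light low-pass to remove frame-to-frame white jitter
      k <- stats::dnorm(-3:3, sd = 1.2); k <- k / sum(k)
      apply(d, 2, function(x) stats::filter(c(rep(x[1], 3), x, rep(x[n], 3)),
                                            k, sides = 2)[4:(n + 3)])
    })
  }
  gaze <- array(0, c(n, 2, config$n_eyes))
  for (eidx in seq_len(config$n_eyes)) {
    g <- sacc + drift + pursuit
    if (!is.null(per_eye_offset)) g <- sweep(g, 2, -per_eye_offset[eidx, ])
    gaze[, , eidx] <- g
  }
  structure(list(gaze = gaze, saccadic = sacc, drift = drift,
                 events = ev_log, fps = fps, times = times,
                 duration = duration),
            class = "gaze_trajectory")
}

#' Injected planar head motion
#'
#' Translation-dominant per-frame similarity transforms emulating small
#' head movements (the rigid-model experiment uses a sinusoid of ~12 px at
#' ~1 Hz). Frame 1 is always the identity.
#'
#' @param kind `"sinusoid"` or `"random_walk"`.
#' @param amplitude Peak translation in px (>= 0).
#' @param frequency Sinusoid frequency in Hz.
#' @param n_frames Number of frames.
#' @param fps Frame rate.
#' @param seed Seed (random walk).
#' @param direction_deg Translation direction of the sinusoid (deg).
#' @param rotation_amp Peak rotation in radians (default 0).
#' @param scale_amp Peak fractional scale excursion (default 0).
#' @param center Pivot (x, y) in px about which rotation/scale act
#'   (typically the frame centre).
#' @return List of `similarity_transform`s, one per frame.
#' @export
make_head_motion <- function(kind = c("sinusoid", "random_walk"),
                             amplitude = 12, frequency = 1, n_frames = 96,
                             fps = 96, seed = 1, direction_deg = 30,
                             rotation_amp = 0, scale_amp = 0,
                             center = c(0, 0)) {
  kind <- match.arg(kind)
  if (amplitude < 0) stopf("amplitude must be >= 0")
  t <- (seq_len(n_frames) - 1) / fps
  if (kind == "sinusoid") {
    ph <- sin(2 * pi * frequency * t)
    dir <- c(cos(direction_deg * pi / 180), sin(direction_deg * pi / 180))
    tx <- amplitude * ph * dir[1]; ty <- amplitude * ph * dir[2]
    th <- rotation_amp * ph; sc <- 1 + scale_amp * ph
  } else {
    w <- with_seed(seed, {
      sd_step <- if (n_frames > 1) amplitude / sqrt(n_frames) else 0
      cbind(cumsum(stats::rnorm(n_frames, sd = sd_step)),
            cumsum(stats::rnorm(n_frames, sd = sd_step)))
    })
    w <- sweep(w, 2, w[1, ])
    k <- stats::dnorm(-4:4, sd = 1.5); k <- k / sum(k)
    sm <- apply(w, 2, function(x) stats::filter(c(rep(x[1], 4), x, rep(x[n_frames], 4)),
                                                k, sides = 2)[5:(n_frames + 4)])
    sm <- sweep(sm, 2, sm[1, ])
    tx <- sm[, 1]; ty <- sm[, 2]; th <- rep(0, n_frames); sc <- rep(1, n_frames)
  }
  lapply(seq_len(n_frames), function(i) {
    # rotation/scale pivot about `center`: t_eff = c + t - s R c
    ct <- cos(th[i]); st <- sin(th[i])
    rc <- sc[i] * c(ct * center[1] - st * center[2],
                    st * center[1] + ct * center[2])
    similarity_transform(s = sc[i], theta = th[i],
                         tx = center[1] + tx[i] - rc[1],
                         ty = center[2] + ty[i] - rc[2])
  })
}
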