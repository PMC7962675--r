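# Iris velocity estimation: stabilized frames + iris masks -> per-eye motion
# samples (geometric-median shift of matched iris features), velocity and
# position traces, regression calibration, TV denoising, cyclopean speed.

#' Tracking configuration for iris velocity estimation
#'
#' @param feature A [feature_config()] for iris feature matching. The
#'   default lowers the DoG response threshold relative to the patch
#'   matcher because CLAHE-equalised iris texture is mid-contrast.
#' @param clahe_clip,clahe_tiles CLAHE parameters (clip limit 2, 8x8 tiles).
#' @param min_inliers Minimum RANSAC inliers for a valid motion sample
#'   (default 8); frames below it are gaps.
#' @param max_hold Maximum consecutive gap frames bridged by zero-order
#'   hold of the last valid shift (default 3); longer gaps become `NA`.
#' @param mask_erode Pixels to erode the iris mask by before keypoint
#'   selection, keeping descriptor patches on iris texture (default 5).
#' @return List of class `track_config`.
#' @export
track_config <- function(feature = feature_config(response_threshold = 1.2,
                                                  max_keypoints = 300),
                         clahe_clip = 2, clahe_tiles = 8,
                         min_inliers = 8, max_hold = 3, mask_erode = 5) {
  structure(list(feature = feature, clahe_clip = clahe_clip,
                 clahe_tiles = clahe_tiles, min_inliers = min_inliers,
                 max_hold = max_hold, mask_erode = mask_erode),
            class = "track_config")
}

#' Masked feature matches between consecutive equalised frames
#'
#' Same matching pipeline as patch matching for head stabilization, with
#' source keypoints restricted to the iris mask.
#'
#' @param eq1,eq2 CLAHE-equalised grayscale frames.
#' @param mask Binary iris mask for the first frame (non-empty).
#' @param config A [track_config()].
#' @param seed RANSAC seed.
#' @return A `match_set` (see [match_features()]).
#' @export
masked_matches <- function(eq1, eq2, mask, config = track_config(), seed = 1) {
  if (!any(mask > 0)) stopf("iris mask is empty")
  match_features(eq1, eq2, config$feature, mask = erode_mask(mask, config$mask_erode),
                 seed = seed)
}

# binary erosion by a square structuring element of radius r
erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  as.matrix(EBImage::erode(mask > 0, EBImage::makeBrush(2 * r + 1, "box"))) > 0
}

#' Track per-frame iris motion through a stabilized video
#'
#' For every consecutive frame pair, equalises the eye-region crop with
#' CLAHE, matches iris features restricted to the mask, and records the
#' geometric median of the matched keypoint shifts as the frame's motion
#' sample. Samples with fewer than `min_inliers` inliers are flagged
#' invalid.
#'
#' @param video An `iris_video` (stabilized).
#' @param masks Per-frame binary masks: a list of matrices, or a function
#'   `masks(i)` returning the mask of frame `i` (so masks need not be
#'   materialised for long videos). Masks are in cropped eye-box
#'   coordinates, or full-frame when their dimensions say so.
#' @param box Optional eye box `c(x0, y0, w, h)` cropping the frames.
#' @param config A [track_config()].
#' @param seed Seed for the RANSAC stages.
#' @return Data frame (one row per frame pair): `frame`, `dx`, `dy` (px,
#'   sub-pixel geometric-median shift), `n_matches`, `valid`.
#' @export
track_iris <- function(video, masks, box = NULL, config = track_config(), seed = 1) {
  n <- video_length(video)
  crop <- function(m) {
    if (is.null(box)) m
    else m[box[2]:(box[2] + box[4] - 1), box[1]:(box[1] + box[3] - 1)]
  }
  out <- data.frame(frame = seq_len(n - 1), dx = NA_real_, dy = NA_real_,
                    n_matches = 0L, valid = FALSE)
  eq_prev <- clahe_gray(crop(video_get(video, 1)), config$clahe_clip, config$clahe_tiles)
  kp_prev <- prepare_keypoints(eq_prev, config$feature)
  for (i in seq_len(n - 1)) {
    eq_next <- clahe_gray(crop(video_get(video, i + 1)),
                          config$clahe_clip, config$clahe_tiles)
    m_i <- if (is.function(masks)) masks(i) else masks[[i]]
    mask_i <- if (all(dim(m_i) == dim(eq_prev))) m_i else crop(m_i)
    # keypoint detection restricted to the mask neighbourhood; large
    # inter-frame motion (calibration saccades) falls back to the full crop
    kp_next <- prepare_keypoints_roi(eq_next, config$feature,
                                     roi_from_mask(mask_i, margin = 18))
    kp_src <- subset_keypoints(kp_prev, erode_mask(mask_i, config$mask_erode))
    m <- if (nrow(kp_src$kp) == 0) NULL else
      match_features(eq_prev, eq_next, config$feature,
                     kp1 = kp_src, kp2 = kp_next, seed = derive_seed(seed, i))
    if (is.null(m) || !m$ok || m$n < config$min_inliers) {
      kp_full_prev <- prepare_keypoints(eq_prev, config$feature)
      kp_next <- prepare_keypoints(eq_next, config$feature)
      kp_src <- subset_keypoints(kp_full_prev, erode_mask(mask_i, config$mask_erode))
      m <- if (nrow(kp_src$kp) == 0) NULL else
        match_features(eq_prev, eq_next, config$feature,
                       kp1 = kp_src, kp2 = kp_next, seed = derive_seed(seed, i))
    }
    if (!is.null(m) && m$ok && m$n >= config$min_inliers) {
      gm <- geometric_median(m$dst - m$src)
      out$dx[i] <- gm[1]; out$dy[i] <- gm[2]
      out$n_matches[i] <- m$n; out$valid[i] <- TRUE
    } else {
      out$n_matches[i] <- if (is.null(m)) 0L else m$n
    }
    eq_prev <- eq_next
    kp_prev <- kp_next
  }
  out
}

# bounding box of the mask's positive pixels, expanded by a margin
roi_from_mask <- function(mask, margin = 18) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(y0 = max(1, min(idx[, 1]) - margin),
    y1 = min(nrow(mask), max(idx[, 1]) + margin),
    x0 = max(1, min(idx[, 2]) - margin),
    x1 = min(ncol(mask), max(idx[, 2]) + margin))
}

# keypoints detected on a subimage, reported in full-image coordinates
prepare_keypoints_roi <- function(img, config, roi) {
  if (is.null(roi)) return(prepare_keypoints(img, config))
  sub <- img[roi["y0"]:roi["y1"], roi["x0"]:roi["x1"]]
  kp <- prepare_keypoints(sub, config)
  kp$kp$x <- kp$kp$x + roi["x0"] - 1L
  kp$kp$y <- kp$kp$y + roi["y0"] - 1L
  kp
}

# restrict a prepared keypoint set to mask-positive locations
subset_keypoints <- function(kp, mask) {
  keep <- mask[cbind(kp$kp$y, kp$kp$x)] > 0
  list(kp = kp$kp[keep, , drop = FALSE],
       desc = kp$desc[keep, , drop = FALSE])
}

#' Bridge short tracking gaps and integrate shifts to a position trace
#'
#' Invalid motion samples are bridged by zero-order hold of the last valid
#' shift for up to `max_hold` consecutive frames; longer runs become `NA`
#' gaps. The relative position is the cumulative sum of the per-frame
#' shifts, starting at 0.
#'
#' @param track Data frame from [track_iris()].
#' @param max_hold Maximum gap length bridged by hold (default 3).
#' @return List with `shift` (n x 2 px, `NA` in gaps) and `pos` ((n+1) x 2
#'   px relative position trace, `NA` once a long gap is crossed until the
#'   trace restarts at the next valid sample).
#' @export
integrate_track <- function(track, max_hold = 3) {
  n <- nrow(track)
  sh <- cbind(track$dx, track$dy)
  # bridge whole invalid runs of length <= max_hold by holding the last
  # valid shift; longer runs (and runs at the trace start) stay NA
  r <- rle(!track$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] <= max_hold && starts[k] > 1) {
      sh[starts[k]:ends[k], 1] <- sh[starts[k] - 1, 1]
      sh[starts[k]:ends[k], 2] <- sh[starts[k] - 1, 2]
    }
  }
  pos <- rbind(c(0, 0), apply(sh, 2, function(z) {
    z[is.na(z)] <- 0; cumsum(z)
  }))
  gap <- c(FALSE, is.na(sh[, 1]))
  pos[gap, ] <- NA
  list(shift = sh, pos = pos)
}

#' Calibrate the px-to-degree mapping by linear regression
#'
#' Ordinary least squares per axis of the known gaze target position
#' against the relative pixel position during the calibration routine.
#'
#' @param pos_px (n x 2) relative position trace in px over the
#'   calibration window (no gaps allowed).
#' @param schedule Data frame with columns `onset_s`, `offset_s`,
#'   `gaze_x_deg`, `gaze_y_deg`: calibration target fixation intervals and
#'   their known gaze angles. At least 2 distinct targets per axis.
#' @param fps Frame rate of the trace.
#' @param settle_s Time discarded at the start of each fixation interval
#'   while the eye lands on the target (default 0.15 s).
#' @return A `calibration_model`: per-axis `gain` (deg/px), `offset`
#'   (deg), and `r_squared`.
#' @export
calibrate <- function(pos_px, schedule, fps, settle_s = 0.15) {
  if (nrow(schedule) < 2) stopf("calibration needs at least 2 targets")
  px <- matrix(NA_real_, nrow(schedule), 2)
  for (k in seq_len(nrow(schedule))) {
    i0 <- max(1L, ceiling((schedule$onset_s[k] + settle_s) * fps) + 1L)
    i1 <- min(nrow(pos_px), floor(schedule$offset_s[k] * fps))
    if (i1 < i0) stopf("calibration interval %d is empty at %g fps", k, fps)
    win <- pos_px[i0:i1, , drop = FALSE]
    if (anyNA(win)) stopf("gap in the calibration window (target %d); calibration requires a gap-free trace", k)
    px[k, ] <- apply(win, 2, stats::median)
  }
  tgt <- cbind(schedule$gaze_x_deg, schedule$gaze_y_deg)
  fit_axis <- function(ax) {
    if (length(unique(tgt[, ax])) < 2)
      stopf("axis %d has fewer than 2 distinct calibration targets", ax)
    f <- stats::lm(tgt[, ax] ~ px[, ax])
    list(gain = unname(stats::coef(f)[2]), offset = unname(stats::coef(f)[1]),
         r2 = summary(f)$r.squared)
  }
  fx <- fit_axis(1); fy <- fit_axis(2)
  if (!is.finite(fx$gain) || fx$gain == 0 || !is.finite(fy$gain) || fy$gain == 0)
    stopf("degenerate calibration gain")
  structure(list(gain = c(x = fx$gain, y = fy$gain),
                 offset = c(x = fx$offset, y = fy$offset),
                 r_squared = c(x = fx$r2, y = fy$r2)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration: gain (%.5g, %.5g) deg/px, R^2 (%.4f, %.4f)\n",
              x$gain[1], x$gain[2], x$r_squared[1], x$r_squared[2]))
  invisible(x)
}

#' Scale a motion sample to a velocity in deg/s
#'
#' Velocity is the scaled motion vector times the sampling rate:
#' `v = gain * shift * fps` per axis.
#'
#' @param shift n x 2 matrix (or length-2 vector) of per-frame px shifts;
#'   `NA` rows are gaps.
#' @param calib A `calibration_model` (or list with a `gain` field).
#' @param fps Frame rate in Hz.
#' @return n x 2 matrix of velocities in deg/s (`NA` in gaps).
#' @export
to_velocity <- function(shift, calib, fps) {
  shift <- rbind(shift)
  cbind(shift[, 1] * calib$gain[1] * fps, shift[, 2] * calib$gain[2] * fps)
}

#' Per-eye position and velocity traces from a motion track
#'
#' Integrates the per-frame shifts, applies the calibration, total
#' variation denoises (by default in the position domain, per axis), and
#' differentiates back to velocity.
#'
#' @param track Data frame from [track_iris()].
#' @param calib A `calibration_model`.
#' @param fps Frame rate.
#' @param tvd_lambda TVD regularization (default 0.1); a length-2 vector
#'   gives per-axis values.
#' @param tvd_domain `"position"` (default) or `"velocity"` — which signal
#'   is denoised.
#' @param max_hold Gap bridging limit, see [integrate_track()].
#' @return List of class `velocity_trace`: `pos_deg` ((n+1) x 2), `vel`
#'   (n x 2 deg/s), `fps`, `gap` (logical, per velocity sample).
#' @export
velocity_trace <- function(track, calib, fps, tvd_lambda = 0.1,
                           tvd_domain = c("position", "velocity"),
                           max_hold = 3) {
  tvd_domain <- match.arg(tvd_domain)
  lam <- rep(tvd_lambda, length.out = 2)
  it <- integrate_track(track, max_hold = max_hold)
  pos_deg <- cbind(it$pos[, 1] * calib$gain[1] + calib$offset[1],
                   it$pos[, 2] * calib$gain[2] + calib$offset[2])
  if (tvd_domain == "position") {
    den <- cbind(tvd_denoise(pos_deg[, 1], lam[1]), tvd_denoise(pos_deg[, 2], lam[2]))
    vel <- apply(den, 2, diff) * fps
    pos_out <- den
  } else {
    vel_raw <- apply(pos_deg, 2, diff) * fps
    vel <- cbind(tvd_denoise(vel_raw[, 1], lam[1]), tvd_denoise(vel_raw[, 2], lam[2]))
    pos_out <- pos_deg
  }
  structure(list(pos_deg = pos_out, vel = vel, fps = fps,
                 gap = is.na(vel[, 1]) | is.na(vel[, 2])),
            class = "velocity_trace")
}

#' Cyclopean speed from left and right eye velocity traces
#'
#' Per-frame vector mean of the two eyes' velocities, then the Euclidean
#' magnitude. Pure vergence (equal and opposite velocities) cancels; a gap
#' in either eye propagates to the output.
#'
#' @param left,right n x 2 velocity matrices in deg/s.
#' @return Length-n numeric vector of absolute cyclopean speed (deg/s).
#' @export
cyclopean_speed <- function(left, right) {
  left <- rbind(left); right <- rbind(right)
  if (nrow(left) != nrow(right)) stopf("velocity traces differ in length")
  vx <- (left[, 1] + right[, 1]) / 2
  vy <- (left[, 2] + right[, 2]) / 2
  sqrt(vx^2 + vy^2)
}
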