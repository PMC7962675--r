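# End-to-end pipeline: simulate (or ingest) -> stabilize -> segment ->
# track -> detect -> evaluate, with one config, derived per-stage seeds,
# and a run manifest. Stages write file artifacts (CSV/JSON; optional PNG
# frame stacks) so each can be rerun and inspected independently.

#' Pipeline configuration
#'
#' @param scene A [scene_config()].
#' @param duration_s Experiment duration in s (after calibration).
#' @param events List of [gaze_event()]s with onsets relative to the
#'   experiment start.
#' @param calibration List with `extent_deg` (half-range of the 3 x 3
#'   target grid, default 1), `dwell_s` (per-target fixation, default
#'   0.6). Set to `NULL` to skip calibration and use the known
#'   px-per-degree scale instead.
#' @param head_motion List of arguments for [make_head_motion()], or
#'   `NULL` for a static head.
#' @param drift_sigma Fixational drift diffusion, deg/sqrt(s).
#' @param stabilize Logical; run head-motion compensation.
#' @param keyframe_interval Keyframe realignment interval (frames).
#' @param segmenter `"fallback"` (classical segmenter), `"truth"`
#'   (ground-truth masks; for ablation runs), or `"precomputed"` (read
#'   binary mask PNGs from `masks_dir`, named
#'   `mask_eye<e>_<frame>.png` in stabilized full-frame coordinates).
#' @param masks_dir Directory of precomputed masks (only with
#'   `segmenter = "precomputed"`).
#' @param tvd_lambda TVD regularization (default 0.1).
#' @param detection A [detection_config()].
#' @param tolerance_ms Event-matching tolerance for scoring.
#' @param seed Master seed; every random stage receives a derived
#'   sub-seed.
#' @param out_dir Output directory for artifacts (`NULL`: tempdir).
#' @param write_video Logical; also dump rendered frames as PNG stacks.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_config(), duration_s = 60,
                            events = list(),
                            calibration = list(extent_deg = 1, dwell_s = 0.6),
                            head_motion = list(kind = "sinusoid",
                                               amplitude = 12, frequency = 1),
                            drift_sigma = 0.1, stabilize = TRUE,
                            keyframe_interval = 480,
                            segmenter = c("fallback", "truth", "precomputed"),
                            masks_dir = NULL,
                            tvd_lambda = 0.1,
                            detection = detection_config(),
                            tolerance_ms = 50, seed = 1, out_dir = NULL,
                            write_video = FALSE) {
  structure(list(scene = scene, duration_s = duration_s, events = events,
                 calibration = calibration, head_motion = head_motion,
                 drift_sigma = drift_sigma, stabilize = stabilize,
                 keyframe_interval = keyframe_interval,
                 segmenter = match.arg(segmenter), masks_dir = masks_dir,
                 tvd_lambda = tvd_lambda,
                 detection = detection, tolerance_ms = tolerance_ms,
                 seed = seed, out_dir = out_dir, write_video = write_video),
            class = "pipeline_config")
}

# 3 x 3 calibration target grid and its fixation schedule
calibration_schedule <- function(calibration) {
  e <- calibration$extent_deg
  grid <- expand.grid(x = c(-e, 0, e), y = c(-e, 0, e))
  n <- nrow(grid)
  data.frame(onset_s = (seq_len(n) - 1) * calibration$dwell_s,
             offset_s = seq_len(n) * calibration$dwell_s,
             gaze_x_deg = grid$x, gaze_y_deg = grid$y)
}

# piecewise-constant calibration gaze component over the full timeline
calibration_gaze <- function(schedule, times) {
  g <- matrix(0, length(times), 2)
  for (k in seq_len(nrow(schedule))) {
    sel <- times >= schedule$onset_s[k] & times < schedule$offset_s[k]
    g[sel, 1] <- schedule$gaze_x_deg[k]
    g[sel, 2] <- schedule$gaze_y_deg[k]
  }
  g
}

#' Warp-crop video regions into reference coordinates
#'
#' Warps every frame into reference coordinates by its stabilization
#' transform and returns the crops of one or more fixed rectangles —
#' without keeping the full stabilized frames in memory.
#'
#' @param video An `iris_video`.
#' @param transforms Per-frame `similarity_transform`s to the reference.
#' @param boxes List of rectangles `c(x0, y0, w, h)` in reference
#'   coordinates (or a single rectangle vector).
#' @return A list of `iris_video` crops (one per box), or a single
#'   `iris_video` when one rectangle was given.
#' @export
stabilize_crop <- function(video, transforms, boxes) {
  single <- !is.list(boxes)
  if (single) boxes <- list(boxes)
  n <- video_length(video)
  out <- lapply(boxes, function(b) vector("list", n))
  for (i in seq_len(n)) {
    wf <- warp_similarity(video_get(video, i), transforms[[i]], bg = 168)
    for (k in seq_along(boxes)) {
      b <- boxes[[k]]
      out[[k]][[i]] <- frame_to_raw(
        wf[b[2]:(b[2] + b[4] - 1), b[1]:(b[1] + b[3] - 1)])
    }
  }
  vids <- lapply(seq_along(boxes), function(k)
    structure(list(data = out[[k]], h = boxes[[k]][4], w = boxes[[k]][3],
                   n = n, fps = video$fps), class = "iris_video"))
  if (single) vids[[1]] else vids
}

#' Run the full pipeline on a synthetic scene
#'
#' Executes simulate, stabilize, segment, track, detect and evaluate in
#' order and writes a run manifest plus tabular artifacts (traces CSV,
#' events CSV/JSON, ground truth).
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `score` (hits / misses /
#'   false alarms), `events` (detected), `truth` (injected events),
#'   `speed`, `traces` (per-eye `velocity_trace`s), `calib`, `threshold`,
#'   `gmm`, `stabilization` summary, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (config$segmenter == "precomputed" &&
      (is.null(config$masks_dir) || !dir.exists(config$masks_dir)))
    stopf("segmentation stage disabled but required mask artifact is missing: %s",
          config$masks_dir %||% "<masks_dir not set>")
  t_start <- proc.time()[["elapsed"]]
  timings <- c()
  stage_time <- function(name) {
    now <- proc.time()[["elapsed"]]
    timings[[name]] <<- now - t_start
    t_start <<- now
  }
  out_dir <- config$out_dir %||% file.path(tempdir(), sprintf("irisvel-run-%d", config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$scene
  fps <- sc$fps

  ## ---- simulate -------------------------------------------------------
  have_calib <- !is.null(config$calibration)
  schedule <- if (have_calib) calibration_schedule(config$calibration) else NULL
  calib_dur <- if (have_calib) max(schedule$offset_s) + 0.4 else 0
  total_s <- calib_dur + config$duration_s
  ev_shift <- lapply(config$events, function(e) {
    e$onset <- e$onset + calib_dur; e
  })
  traj <- build_trajectory(ev_shift, total_s, sc,
                           drift_sigma = config$drift_sigma,
                           seed = derive_seed(config$seed, 1))
  if (have_calib) {
    cg <- calibration_gaze(schedule, traj$times)
    for (e in seq_len(sc$n_eyes)) traj$gaze[, , e] <- traj$gaze[, , e] + cg
  }
  n_frames <- dim(traj$gaze)[1]
  head <- if (is.null(config$head_motion)) NULL else
    do.call(make_head_motion,
            c(config$head_motion,
              list(n_frames = n_frames, fps = fps,
                   seed = derive_seed(config$seed, 2),
                   center = c(sc$frame_width / 2, sc$frame_height / 2))))
  scene <- render_scene(sc, traj, head, seed = derive_seed(config$seed, 3))
  gt_paths <- write_ground_truth(scene, out_dir)
  if (config$write_video) write_frames(scene$video, file.path(out_dir, "frames"))
  stage_time("simulate")

  ## ---- stabilize ------------------------------------------------------
  if (config$stabilize) {
    stab <- cascade_align(scene$video, sc$patch_regions,
                          keyframe_interval = config$keyframe_interval,
                          seed = derive_seed(config$seed, 4), warp = FALSE)
    transforms <- stab$transforms
  } else {
    stab <- NULL
    transforms <- replicate(n_frames, similarity_transform(), simplify = FALSE)
  }
  tf_df <- data.frame(frame = seq_len(n_frames),
                      t(vapply(transforms, st_params, numeric(4))),
                      keyframe = seq_len(n_frames) %in% (stab$keyframes %||% 1))
  utils::write.csv(tf_df, file.path(out_dir, "transforms.csv"), row.names = FALSE)
  stage_time("stabilize")

  ## ---- segment + track (per eye) --------------------------------------
  max_gaze <- (if (have_calib) config$calibration$extent_deg else 0.8) + 0.35
  eyes <- seq_len(sc$n_eyes)
  traces <- list(); tracks <- list()
  seg_warn <- 0
  boxes <- lapply(eyes, function(e) eye_box(sc, e, max_gaze_deg = max_gaze))
  crops <- stabilize_crop(scene$video, transforms, boxes)
  if (!config$write_video) { scene$video <- NULL; gc(FALSE) }
  for (e in eyes) {
    box <- boxes[[e]]
    crop_v <- crops[[e]]
    full_box <- c(1, 1, box["w"], box["h"])
    # masks are produced lazily, one frame at a time, as the tracker asks
    mask_fun <- local({
      e_loc <- e; box_loc <- box
      function(i) {
        if (config$segmenter == "fallback") {
          withCallingHandlers(
            fallback_segment(video_get(crop_v, i), full_box),
            warning = function(w) { seg_warn <<- seg_warn + 1
                                    invokeRestart("muffleWarning") })
        } else if (config$segmenter == "precomputed") {
          mp <- file.path(config$masks_dir,
                          sprintf("mask_eye%d_%06d.png", e_loc, i))
          if (!file.exists(mp)) stopf("missing mask artifact: %s", mp)
          fm <- png::readPNG(mp)
          if (length(dim(fm)) == 3) fm <- fm[, , 1]
          (fm[box_loc["y0"]:(box_loc["y0"] + box_loc["h"] - 1),
              box_loc["x0"]:(box_loc["x0"] + box_loc["w"] - 1)] > 0.5) * 1
        } else {
          fm <- scene_mask(scene, i, e_loc, canonical = TRUE)
          fm[box_loc["y0"]:(box_loc["y0"] + box_loc["h"] - 1),
             box_loc["x0"]:(box_loc["x0"] + box_loc["w"] - 1)]
        }
      }
    })
    tracks[[e]] <- track_iris(crop_v, mask_fun, box = NULL,
                              seed = derive_seed(config$seed, 10 + e))
    crops[[e]] <- NA
    rm(crop_v)
    gc(FALSE)
  }
  rm(crops)
  stage_time("segment_track")

  ## ---- calibrate ------------------------------------------------------
  calibs <- list()
  for (e in eyes) {
    it <- integrate_track(tracks[[e]])
    if (have_calib) {
      calibs[[e]] <- calibrate(it$pos, schedule, fps)
    } else {
      g <- 1 / sc$px_per_degree
      calibs[[e]] <- structure(list(gain = c(x = g, y = g),
                                    offset = c(x = 0, y = 0),
                                    r_squared = c(x = NA, y = NA)),
                               class = "calibration_model")
    }
  }

  ## ---- velocity + detection ------------------------------------------
  for (e in eyes)
    traces[[e]] <- velocity_trace(tracks[[e]], calibs[[e]], fps,
                                  tvd_lambda = config$tvd_lambda)
  speed <- if (sc$n_eyes == 2)
    cyclopean_speed(traces[[1]]$vel, traces[[2]]$vel)
  else sqrt(traces[[1]]$vel[, 1]^2 + traces[[1]]$vel[, 2]^2)
  # analysis window: the experiment phase, after calibration settles
  w0 <- floor(calib_dur * fps) + 1
  speed_exp <- speed[w0:length(speed)]
  pos_exp <- lapply(traces, function(tr) tr$pos_deg[w0:nrow(tr$pos_deg), , drop = FALSE])
  gmm <- fit_velocity_gmm(speed_exp, config$detection)
  threshold <- adaptive_threshold(gmm, config$detection)
  events <- detect_events(speed_exp, pos_exp, threshold, config$detection)
  events$onset_s <- (events$onset + w0 - 1 - 0.5) / fps
  events$offset_s <- (events$offset + w0 - 1 + 0.5) / fps
  events$peak_s <- (events$peak_frame + w0 - 1) / fps
  write_traces_csv(tracks, traces, fps, file.path(out_dir, "traces.csv"))
  write_events(events, out_dir)
  stage_time("detect")

  ## ---- evaluate -------------------------------------------------------
  truth <- scene$events
  micro <- events[events$label == "microsaccade", , drop = FALSE]
  valid_s <- sum(!is.na(speed_exp)) / fps
  score <- score_detection(micro$onset_s, truth$onset_s,
                           tolerance_ms = config$tolerance_ms,
                           valid_time_s = valid_s)
  stage_time("evaluate")

  manifest <- list(
    package_version = as.character(utils::packageVersion("irisvel")),
    seed = config$seed,
    stages = c("simulate", "stabilize", "segment", "track", "detect", "evaluate"),
    timings_s = as.list(timings),
    n_frames = n_frames, fps = fps,
    px_per_degree = sc$px_per_degree,
    calibration_s = calib_dur,
    threshold_deg_s = threshold,
    segmentation_warnings = seg_warn,
    artifacts = list(
      ground_truth = gt_paths[[2]], events_json = gt_paths[[1]],
      transforms = file.path(out_dir, "transforms.csv"),
      traces = file.path(out_dir, "traces.csv"),
      detected_events = file.path(out_dir, "events.csv"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(score = score, events = events, truth = truth,
                 speed = speed, speed_exp = speed_exp, traces = traces,
                 tracks = tracks, calib = calibs, threshold = threshold,
                 gmm = gmm,
                 stabilization = if (is.null(stab)) NULL else
                   list(keyframes = stab$keyframes, jitter = stab$jitter,
                        fallbacks = stab$warnings),
                 window_start_frame = w0, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline run: threshold %.3g deg/s; %d events (%d microsaccades)\n",
              x$threshold, nrow(x$events),
              sum(x$events$label == "microsaccade")))
  cat(sprintf("  vs truth: %d hits, %d misses, %d false alarms\n",
              x$score$hits, x$score$misses, x$score$false_alarms))
  invisible(x)
}

write_traces_csv <- function(tracks, traces, fps, path) {
  rows <- NULL
  for (e in seq_along(tracks)) {
    tr <- tracks[[e]]; vt <- traces[[e]]
    n <- nrow(tr)
    rows <- rbind(rows, data.frame(
      frame = tr$frame, time_s = (tr$frame - 0.5) / fps, eye = e,
      dx_px = tr$dx, dy_px = tr$dy, n_matches = tr$n_matches,
      vx_deg_s = vt$vel[, 1], vy_deg_s = vt$vel[, 2],
      x_deg = vt$pos_deg[seq_len(n), 1], y_deg = vt$pos_deg[seq_len(n), 2],
      gap_flag = as.integer(vt$gap)))
  }
  utils::write.csv(rows, path, row.names = FALSE)
}

write_events <- function(events, out_dir) {
  utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
  jsonlite::write_json(events, file.path(out_dir, "events.json"),
                       dataframe = "rows", digits = NA)
}

#' The standard synthetic detection benchmark
#'
#' The package's reference experiment: a two-eye scene at 96 fps and 40
#' px/deg, a 9-point calibration phase, then `duration_s` of fixation
#' with `n_events` conjugate microsaccades (amplitudes uniform in
#' `amp_range` on main-sequence slope 47 1/s, random directions),
#' fixational drift, default sensor noise, and sinusoidal planar head
#' motion (12 px at 1 Hz).
#'
#' @param seed Master seed.
#' @param duration_s Experiment duration (default 60 s).
#' @param n_events Number of injected microsaccades (default 20).
#' @param amp_range Amplitude range in deg (default 0.2 to 0.5).
#' @param head Logical; inject head motion (default `TRUE`).
#' @return A [pipeline_config()].
#' @export
benchmark_config <- function(seed = 1, duration_s = 60, n_events = 20,
                             amp_range = c(0.2, 0.5), head = TRUE) {
  ev <- with_seed(derive_seed(seed, 99), {
    slots <- seq(1.2, duration_s - 1.2, length.out = n_events)
    onsets <- slots + stats::runif(n_events, -0.4, 0.4)
    amps <- stats::runif(n_events, amp_range[1], amp_range[2])
    # fixation-maintaining directions: microsaccades correct accumulated
    # fixation error, so once gaze has wandered the next event points back
    # toward the fixation target (with angular jitter) instead of letting
    # the event sequence random-walk out of the fixation area
    cum <- c(0, 0)
    dirs <- numeric(n_events)
    for (k in seq_len(n_events)) {
      dirs[k] <- if (sqrt(sum(cum^2)) < 0.25) stats::runif(1, 0, 360) else
        (atan2(-cum[2], -cum[1]) * 180 / pi + stats::rnorm(1, 0, 25)) %% 360
      cum <- cum + amps[k] * c(cos(dirs[k] * pi / 180), sin(dirs[k] * pi / 180))
    }
    lapply(seq_len(n_events), function(k)
      gaze_event("microsaccade", onset = onsets[k], amplitude = amps[k],
                 direction = dirs[k]))
  })
  pipeline_config(
    scene = scene_config(),
    duration_s = duration_s, events = ev,
    head_motion = if (head) list(kind = "sinusoid", amplitude = 12,
                                 frequency = 1) else NULL,
    seed = seed)
}

#' Diagnostic figures for a pipeline run
#'
#' Writes three PNG figures: the cyclopean speed trace with detected
#' events shaded and the threshold line, the main-sequence scatter, and a
#' per-bin microsaccade-rate boxplot.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (default: the run's `out_dir`).
#' @param bin_s Bin width in s for the rate boxplot (default 10).
#' @return Invisibly, the figure paths.
#' @export
plot_outputs <- function(result, dir = result$out_dir, bin_s = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fps <- result$traces[[1]]$fps
  p1 <- file.path(dir, "speed_trace.png")
  grDevices::png(p1, width = 1400, height = 500)
  tt <- (seq_along(result$speed_exp) - 0.5) / fps
  graphics::plot(tt, result$speed_exp, type = "l", col = "steelblue",
                 xlab = "time (s)", ylab = "cyclopean speed (deg/s)",
                 main = "Cyclopean speed with detected events")
  ev <- result$events
  for (i in seq_len(nrow(ev))) {
    col <- if (ev$label[i] == "saccade") grDevices::rgb(1, 0, 0, 0.25)
           else grDevices::rgb(0, 0.8, 0, 0.25)
    graphics::rect((ev$onset[i] - 0.5) / fps, 0, (ev$offset[i] + 0.5) / fps,
                   max(result$speed_exp, na.rm = TRUE), col = col, border = NA)
  }
  graphics::abline(h = result$threshold, lty = 2)
  grDevices::dev.off()
  p2 <- file.path(dir, "main_sequence.png")
  grDevices::png(p2, width = 600, height = 600)
  micro <- ev[ev$label == "microsaccade" & ev$amplitude > 0, ]
  graphics::plot(micro$amplitude * 60, micro$peak_speed, log = "xy",
                 xlab = "amplitude (arcmin)", ylab = "peak speed (deg/s)",
                 main = "Main sequence")
  graphics::abline(h = 50, lty = 3)
  grDevices::dev.off()
  p3 <- file.path(dir, "rate_boxplot.png")
  grDevices::png(p3, width = 500, height = 500)
  bins <- floor(micro$onset_s / bin_s)
  rate <- as.numeric(table(factor(bins, levels = unique(bins)))) / bin_s
  graphics::boxplot(rate, ylab = "microsaccades / s",
                    main = sprintf("Rate per %gs bin", bin_s))
  grDevices::dev.off()
  invisible(c(p1, p2, p3))
}
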