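# Shared synthetic fixtures, built in code at test time.

# compact single-eye scene for render/track tests
small_scene <- function(...) {
  scene_config(frame_width = 260, frame_height = 200, n_eyes = 1, ...)
}

# identity transforms for a video
identity_transforms <- function(n) {
  replicate(n, similarity_transform(), simplify = FALSE)
}

# render a short single-eye scene and return crops/masks ready for tracking
tracked_fixture <- function(events = list(), duration = 0.5, drift_sigma = 0.1,
                            seed = 3, noise = TRUE, config = small_scene(),
                            max_gaze_deg = 0.8) {
  traj <- build_trajectory(events, duration, config, drift_sigma = drift_sigma,
                           seed = seed)
  scn <- render_scene(config, traj, NULL, seed = seed + 1, noise = noise)
  box <- eye_box(config, 1, max_gaze_deg = max_gaze_deg)
  cv <- stabilize_crop(scn$video, identity_transforms(video_length(scn$video)), box)
  masks <- lapply(seq_len(video_length(cv)), function(i) {
    m <- scene_mask(scn, i, 1)
    m[box["y0"]:(box["y0"] + box["h"] - 1), box["x0"]:(box["x0"] + box["w"] - 1)]
  })
  list(scene = scn, box = box, crops = cv, masks = masks, traj = traj,
       config = config)
}

# 16 small image/mask training pairs for the segmentation net
unet_pairs <- function(n = 16, seed = 42, side = 32) {
  pairs <- list(images = vector("list", n), masks = vector("list", n))
  for (i in seq_len(n)) {
    sc <- scene_config(frame_width = 64, frame_height = 64, iris_radius = 14,
                       pupil_radius = 6, n_eyes = 1, texture_seed = seed + i)
    traj <- build_trajectory(list(), 1 / sc$fps, sc, drift_sigma = 0, seed = i)
    traj$gaze[, , 1] <- matrix(irisvel:::with_seed(seed * 1000 + i,
                                                   stats::runif(2, -0.15, 0.15)), 1)
    scn <- render_scene(sc, traj, NULL, seed = seed + i)
    pairs$images[[i]] <- as.matrix(EBImage::resize(video_get(scn$video, 1), side, side))
    pairs$masks[[i]] <- round(as.matrix(EBImage::resize(scene_mask(scn, 1, 1),
                                                        side, side)))
  }
  pairs
}

# known px-per-degree calibration model
known_calibration <- function(px_per_degree = 40) {
  g <- 1 / px_per_degree
  structure(list(gain = c(x = g, y = g), offset = c(x = 0, y = 0),
                 r_squared = c(x = NA_real_, y = NA_real_)),
            class = "calibration_model")
}

# the standard detection benchmark, computed once and shared by the
# acceptance blocks that examine different aspects of the same run
.benchmark_cache <- new.env(parent = emptyenv())
benchmark_run <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.benchmark_cache[[key]]))
    .benchmark_cache[[key]] <- run_pipeline(benchmark_config(seed = seed))
  .benchmark_cache[[key]]
}
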