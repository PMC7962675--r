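test_that("scene config validates its geometry", {
  expect_error(scene_config(pupil_radius = 40, iris_radius = 30), "smaller")
  expect_error(scene_config(fps = 0), "positive")
  expect_error(scene_config(eyelid_occlusion = 0.6), "0, 0.4")
  sc <- scene_config()
  expect_length(sc$patch_regions, 4)
  expect_equal(nrow(sc$eye_centers), 2)
})

test_that("trajectories obey the main-sequence kinematics and conserve amplitude", {
  sc <- small_scene()
  # no events, no drift: constant gaze
  t0 <- build_trajectory(list(), 0.3, sc, drift_sigma = 0)
  expect_true(all(t0$gaze == 0))
  # a 0.3 deg microsaccade at slope 47: peak velocity 14.1 deg/s,
  # displacement exactly 0.3 deg
  ev <- list(gaze_event("microsaccade", onset = 0.1, amplitude = 0.3, direction = 0))
  t1 <- build_trajectory(ev, 0.4, sc, drift_sigma = 0)
  expect_equal(t1$events$peak_velocity, 14.1)
  disp <- t1$saccadic[nrow(t1$saccadic), ] - t1$saccadic[1, ]
  expect_lt(abs(sqrt(sum(disp^2)) - 0.3), 1e-9)
  # increments across the realized event window sum to the amplitude
  win <- t1$events$onset_frame:t1$events$offset_frame
  inc <- colSums(apply(t1$saccadic[win, ], 2, diff))
  expect_lt(abs(sqrt(sum(inc^2)) - 0.3), 1e-9)
  # 1 deg saccade: peak 47 deg/s; duration from the raised-cosine profile
  t2 <- build_trajectory(list(gaze_event("saccade", 0.1, 1, 90)), 0.4, sc, 0)
  expect_equal(t2$events$peak_velocity, 47)
  expect_equal(t2$events$offset_s - t2$events$onset_s, 2 / 47)
  # numerical peak of the analytic profile matches slope * amplitude
  tt <- seq(0, 2 / 47, length.out = 4001)
  v_num <- diff(1 * irisvel:::raised_cosine_pos(tt / (2 / 47))) / diff(tt)
  expect_equal(max(v_num), 47, tolerance = 1e-4)
  # overlap rejection
  bad <- list(gaze_event("microsaccade", 0.1, 0.3), gaze_event("microsaccade", 0.11, 0.3))
  expect_error(build_trajectory(bad, 0.5, sc, 0), "overlap")
})

test_that("binocular trajectories are conjugate unless a per-eye offset is given", {
  sc <- scene_config()
  ev <- list(gaze_event("microsaccade", 0.1, 0.25, 45))
  tr <- build_trajectory(ev, 0.3, sc, drift_sigma = 0.1, seed = 4)
  expect_identical(tr$gaze[, , 1], tr$gaze[, , 2])
  off <- rbind(c(0, 0), c(0.1, -0.05))
  tr2 <- build_trajectory(ev, 0.3, sc, drift_sigma = 0.1, seed = 4,
                          per_eye_offset = off)
  expect_equal(tr2$gaze[, 1, 2] - tr2$gaze[, 1, 1], rep(0.1, dim(tr2$gaze)[1]))
})

test_that("head motion generators honour amplitude, identity start and seeds", {
  z <- make_head_motion("sinusoid", amplitude = 0, n_frames = 10)
  expect_true(all(vapply(z, irisvel:::st_is_identity, TRUE)))
  hm <- make_head_motion("sinusoid", amplitude = 7, frequency = 1, n_frames = 96,
                         fps = 96, direction_deg = 0)
  expect_true(irisvel:::st_is_identity(hm[[1]]))
  expect_equal(max(abs(vapply(hm, function(t) t$tx, 0))), 7, tolerance = 1e-3)
  r1 <- make_head_motion("random_walk", 5, n_frames = 50, seed = 8)
  r2 <- make_head_motion("random_walk", 5, n_frames = 50, seed = 8)
  expect_identical(vapply(r1, st_params, numeric(4)), vapply(r2, st_params, numeric(4)))
  expect_true(irisvel:::st_is_identity(r1[[1]]))
})

test_that("the renderer is rigid-consistent and linear in px_per_degree", {
  sc <- small_scene(sensor_noise_sigma = 0)
  traj <- build_trajectory(list(), 3 / sc$fps, sc, drift_sigma = 0)
  scn <- render_scene(sc, traj, NULL, noise = FALSE)
  expect_identical(scn$video$data[[1]], scn$video$data[[2]])
  # gaze step of 0.25 deg at 40 px/deg: iris centroid moves 10 px
  traj$gaze[2:3, 1, 1] <- 0.25
  scn2 <- render_scene(sc, traj, NULL, noise = FALSE)
  cen <- function(m) colMeans(which(m > 0, arr.ind = TRUE))  # (y, x)
  d <- cen(scene_mask(scn2, 2, 1)) - cen(scene_mask(scn2, 1, 1))
  expect_equal(unname(d), c(0, 10), tolerance = 1e-6)
  # doubling px_per_degree doubles the displacement
  sc80 <- small_scene(px_per_degree = 80, sensor_noise_sigma = 0)
  scn3 <- render_scene(sc80, traj, NULL, noise = FALSE)
  d80 <- cen(scene_mask(scn3, 2, 1)) - cen(scene_mask(scn3, 1, 1))
  expect_equal(unname(d80), c(0, 20), tolerance = 1e-6)
  # pure head translation moves the iris centroid rigidly
  hm <- list(similarity_transform(), similarity_transform(tx = 5),
             similarity_transform())
  traj0 <- build_trajectory(list(), 3 / sc$fps, sc, drift_sigma = 0)
  scn4 <- render_scene(sc, traj0, hm, noise = FALSE)
  d2 <- cen(scene_mask(scn4, 2, 1)) - cen(scene_mask(scn4, 1, 1))
  expect_equal(unname(d2), c(0, 5), tolerance = 1e-6)
  # out-of-bounds gaze is an error
  traj_bad <- build_trajectory(list(), 2 / sc$fps, sc, drift_sigma = 0)
  traj_bad$gaze[2, 1, 1] <- 5
  expect_error(render_scene(sc, traj_bad, NULL), "outside frame")
})

test_that("ground-truth artifacts are written as JSON and CSV", {
  sc <- small_scene()
  traj <- build_trajectory(list(gaze_event("microsaccade", 0.05, 0.3)), 0.15, sc, 0)
  scn <- render_scene(sc, traj, NULL, seed = 1)
  d <- withr::local_tempdir()
  paths <- write_ground_truth(scn, d)
  expect_true(all(file.exists(paths)))
  gt <- utils::read.csv(file.path(d, "ground_truth.csv"))
  expect_equal(nrow(gt), video_length(scn$video))
  ev <- jsonlite::read_json(file.path(d, "events.json"), simplifyVector = TRUE)
  expect_equal(ev$amplitude, 0.3)
})
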