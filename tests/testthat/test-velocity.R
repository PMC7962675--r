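test_that("CLAHE grayscale conversion is deterministic and shape-preserving", {
  set.seed(9)
  f <- matrix(runif(90 * 110, 40, 90), 90, 110)  # low-contrast frame
  eq1 <- clahe_gray(f)
  expect_identical(eq1, clahe_gray(f))
  expect_equal(dim(eq1), dim(f))
  rgb <- array(rep(f, 3), c(dim(f), 3))
  expect_equal(dim(clahe_gray(rgb)), dim(f))
  # on a low-contrast rendering, CLAHE does not lose masked keypoints
  sc <- small_scene()
  fx <- tracked_fixture(duration = 2 / sc$fps, drift_sigma = 0, config = sc)
  low <- 110 + 0.25 * (video_get(fx$crops, 1) - 110)  # contrast-compressed
  cfg <- track_config()$feature
  n_plain <- nrow(detect_keypoints(low, cfg, mask = fx$masks[[1]]))
  n_clahe <- nrow(detect_keypoints(clahe_gray(low), cfg, mask = fx$masks[[1]]))
  expect_gte(n_clahe, n_plain)
})

test_that("velocity scaling is gain x shift x fps per axis", {
  calib <- known_calibration(10)  # gain 0.1 deg/px
  v <- to_velocity(c(1, 0), calib, 96)
  expect_equal(as.numeric(v), c(9.6, 0))
  expect_equal(as.numeric(to_velocity(c(0, 0), calib, 96)), c(0, 0))
  expect_equal(to_velocity(c(0.5, -2), calib, 192),
               2 * to_velocity(c(0.5, -2), calib, 96))
})

test_that("gap bridging holds short dropouts and NA-flags long ones", {
  tr <- data.frame(frame = 1:8, dx = c(1, 1, NA, NA, 1, NA, NA, NA),
                   dy = 0, n_matches = c(10, 10, 0, 0, 10, 2, 1, 0),
                   valid = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  it <- integrate_track(tr, max_hold = 2)
  expect_equal(it$shift[3:4, 1], c(1, 1))   # zero-order hold
  expect_true(all(is.na(it$shift[6:8, 1]))) # run of 3 > max_hold
  expect_equal(nrow(it$pos), 9)
  expect_equal(it$pos[1, ], c(0, 0))
})

test_that("calibration recovers exact gains and rejects bad windows", {
  sched <- data.frame(onset_s = (0:3) * 0.5, offset_s = (1:4) * 0.5,
                      gaze_x_deg = c(-1, 0, 1, 0), gaze_y_deg = c(0, -1, 0, 1))
  fps <- 96
  n <- 4 * 0.5 * fps
  tgt <- irisvel:::calibration_gaze(sched, (seq_len(n + 1) - 1) / fps)
  pos_px <- cbind(tgt[, 1] * 40 + 3, tgt[, 2] * 40 - 5)  # exact gain 1/40
  # exact data: lm warns about a perfect fit, which is the point here
  cal <- suppressWarnings(calibrate(pos_px, sched, fps))
  expect_equal(unname(cal$gain), c(1 / 40, 1 / 40), tolerance = 1e-12)
  expect_equal(unname(cal$r_squared), c(1, 1))
  expect_error(calibrate(pos_px, sched[1, , drop = FALSE], fps), "2 targets")
  gappy <- pos_px; gappy[30, 1] <- NA
  expect_error(calibrate(gappy, sched, fps), "gap")
})

test_that("cyclopean speed averages the eyes and cancels vergence", {
  both <- matrix(rep(c(3, 4), each = 5), 5, 2)
  expect_equal(cyclopean_speed(both, both), rep(5, 5))
  left <- cbind(rep(2, 4), 0); right <- cbind(rep(-2, 4), 0)
  expect_equal(cyclopean_speed(left, right), rep(0, 4))
  gl <- left; gl[2, ] <- NA
  expect_true(is.na(cyclopean_speed(gl, right)[2]))
  expect_error(cyclopean_speed(left, right[1:3, ]), "length")
})

test_that("masked matching tracks a rendered sub-pixel iris shift", {
  sc <- small_scene()
  fx <- tracked_fixture(duration = 3 / sc$fps, drift_sigma = 0, config = sc)
  # inject a known fractional gaze step and re-render
  traj <- fx$traj
  traj$gaze[2:3, 1, 1] <- 0.55 / 40   # 0.55 px
  traj$gaze[2:3, 2, 1] <- -0.30 / 40
  scn <- render_scene(sc, traj, NULL, seed = 4)
  b <- fx$box
  crop <- function(i) video_get(scn$video, i)[b["y0"]:(b["y0"] + b["h"] - 1),
                                              b["x0"]:(b["x0"] + b["w"] - 1)]
  eq1 <- clahe_gray(crop(1)); eq2 <- clahe_gray(crop(2))
  m <- masked_matches(eq1, eq2, fx$masks[[1]])
  expect_true(m$ok)
  gm <- geometric_median(m$dst - m$src)
  expect_lt(abs(gm[1] - 0.55), 0.1)
  expect_lt(abs(gm[2] + 0.30), 0.1)
  expect_error(masked_matches(eq1, eq2, matrix(0, nrow(eq1), ncol(eq1))), "empty")
})

test_that("integrated velocity recovers an injected saccade amplitude within 10%", {
  sc <- small_scene()
  ev <- list(gaze_event("microsaccade", onset = 0.15, amplitude = 0.35,
                        direction = 25))
  fx <- tracked_fixture(events = ev, duration = 0.45, drift_sigma = 0.1,
                        config = sc, seed = 11)
  tr <- track_iris(fx$crops, fx$masks, seed = 2)
  expect_gt(mean(tr$valid), 0.95)
  # integrate the scaled shifts (raw trace, before denoising) and take the
  # displacement across the event window
  pos <- integrate_track(tr)$pos / 40
  w0 <- fx$traj$events$onset_frame - 1
  w1 <- min(fx$traj$events$offset_frame + 2, nrow(pos))
  d <- pos[w1, ] - pos[w0, ]
  expect_lt(abs(sqrt(sum(d^2)) - 0.35) / 0.35, 0.10)
})
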