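test_that("a static video stabilizes to identity transforms", {
  sc <- scene_config(sensor_noise_sigma = 0)
  traj <- build_trajectory(list(), 6 / sc$fps, sc, drift_sigma = 0)
  scn <- render_scene(sc, traj, NULL, noise = FALSE)
  st <- cascade_align(scn$video, sc$patch_regions, keyframe_interval = 480)
  pars <- vapply(st$transforms, st_params, numeric(4))
  expect_lt(max(abs(pars - c(1, 0, 0, 0))), 1e-6)
  expect_identical(st$stabilized$data[[3]], scn$video$data[[3]])
  expect_error(cascade_align(scn$video, sc$patch_regions, keyframe_interval = 1),
               ">= 2")
})

test_that("a translating scene is aligned back to the reference", {
  sc <- scene_config()
  n <- 12
  hm <- lapply(seq_len(n), function(i) similarity_transform(tx = i - 1))
  traj <- build_trajectory(list(), n / sc$fps, sc, drift_sigma = 0)
  scn <- render_scene(sc, traj, hm, seed = 4)
  st <- cascade_align(scn$video, sc$patch_regions, warp = FALSE)
  for (k in c(4, 8, 12)) {
    p <- st_params(st$transforms[[k]])
    expect_lt(abs(p["tx"] + (k - 1)), 0.25)
    expect_lt(abs(p["ty"]), 0.25)
  }
})

test_that("recovered transforms match ground truth on a noiseless rigid scene", {
  sc <- scene_config(sensor_noise_sigma = 0)
  n <- 48
  hm <- make_head_motion("sinusoid", amplitude = 9, frequency = 2, n_frames = n,
                         fps = sc$fps, rotation_amp = 0.4 * pi / 180,
                         center = c(sc$frame_width / 2, sc$frame_height / 2))
  traj <- build_trajectory(list(), n / sc$fps, sc, drift_sigma = 0)
  scn <- render_scene(sc, traj, hm, noise = FALSE)
  st <- cascade_align(scn$video, sc$patch_regions, warp = FALSE)
  terr <- 0; rerr <- 0
  for (k in seq(2, n, by = 3)) {
    rec <- st_params(st$transforms[[k]])
    tru <- st_params(st_inverse(hm[[k]]))
    terr <- max(terr, abs(rec[3:4] - tru[3:4]))
    rerr <- max(rerr, abs(rec[2] - tru[2]) * 180 / pi)
  }
  expect_lt(terr, 0.25)
  expect_lt(rerr, 0.1)
})

test_that("keyframe chaining keeps composition consistency and bounded jitter", {
  sc <- scene_config(sensor_noise_sigma = 0)
  n <- 30
  hm <- make_head_motion("sinusoid", amplitude = 6, frequency = 3, n_frames = n,
                         fps = sc$fps)
  traj <- build_trajectory(list(), n / sc$fps, sc, drift_sigma = 0)
  scn <- render_scene(sc, traj, hm, noise = FALSE)
  st <- cascade_align(scn$video, sc$patch_regions, keyframe_interval = 10,
                      warp = FALSE)
  expect_equal(st$keyframes, c(1, 11, 21))
  # jitter at keyframe switches on a noiseless rigid scene stays small
  expect_lt(max(st$jitter), 0.5)
  # transforms still undo the injected motion across keyframe blocks
  for (k in c(15, 25, 30)) {
    rec <- st_params(st$transforms[[k]])
    tru <- st_params(st_inverse(hm[[k]]))
    expect_lt(max(abs(rec[3:4] - tru[3:4])), 0.3)
  }
})

test_that("stabilization metrics match hand-computed values", {
  constant <- cbind(rep(5, 8), rep(3, 8))
  m0 <- stabilization_metrics(constant, constant)
  expect_equal(m0$before$mse_x, 0)
  expect_equal(m0$before$std_y, 0)
  # track alternating 0/+1 px from the reference: MSE 0.5, STD 0.5
  alt <- cbind(5 + rep(c(0, 1), 5), rep(3, 10))
  m1 <- stabilization_metrics(alt, constant[rep(1, 10), ])
  expect_equal(m1$before$mse_x, 0.5)
  expect_equal(m1$before$std_x, 0.5)
  expect_equal(m1$after$mse_x, 0)
  expect_error(stabilization_metrics(alt, constant), "length")
})

test_that("degraded patches trigger the fallback transform with a warning", {
  sc <- scene_config(sensor_noise_sigma = 0)
  n <- 4
  hm <- lapply(seq_len(n), function(i) similarity_transform(tx = 0.5 * (i - 1)))
  traj <- build_trajectory(list(), n / sc$fps, sc, drift_sigma = 0)
  scn <- render_scene(sc, traj, hm, noise = FALSE)
  # blank out three patches in frame 3 so fewer than 3 match confidently
  f3 <- video_get(scn$video, 3)
  for (p in 1:3) {
    rg <- sc$patch_regions[[p]]
    f3[rg[2]:(rg[2] + rg[4] - 1), rg[1]:(rg[1] + rg[3] - 1)] <- 128
  }
  scn$video <- video_set(scn$video, 3, f3)
  w <- testthat::capture_warnings(
    st <- cascade_align(scn$video, sc$patch_regions, warp = FALSE))
  expect_true(all(grepl("reusing previous", w)))
  # both pairs touching the degraded frame fall back
  expect_equal(st$warnings, c(3, 4))
  # the reused pairwise transform keeps the cascade close to the truth
  expect_lt(abs(st_params(st$transforms[[2]])["tx"] + 0.5), 0.1)
})
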