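ellipse_points <- function(cx, cy, a, b, ang, n) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + a * cos(th) * cos(ang) - b * sin(th) * sin(ang),
        cy + a * cos(th) * sin(ang) + b * sin(th) * cos(ang))
}

test_that("direct least-squares ellipse fitting recovers forward-generated conics", {
  # circle case from 6 points
  circ <- fit_ellipse_lsq(ellipse_points(100, 100, 30, 30, 0, 6))
  expect_lt(max(abs(circ$center - c(100, 100))), 1e-6)
  expect_lt(abs(circ$a - 30), 1e-6)
  expect_lt(abs(circ$b - 30), 1e-6)
  # general ellipse from 8 points
  e <- fit_ellipse_lsq(ellipse_points(100, 80, 40, 25, 30 * pi / 180, 8))
  expect_lt(max(abs(e$center - c(100, 80))), 1e-6)
  expect_lt(abs(e$a - 40), 1e-6)
  expect_lt(abs(e$b - 25), 1e-6)
  expect_lt(abs(e$angle - 30 * pi / 180), 1e-6)
  # underdetermined and degenerate input
  expect_error(fit_ellipse_lsq(ellipse_points(0, 0, 10, 5, 0, 4)), ">= 5")
  line <- cbind(1:6, 2 * (1:6) + 1)
  expect_error(fit_ellipse_lsq(line))
})

test_that("eyelid clipping intersects the ellipse with the lid quadratics", {
  e <- fit_ellipse_lsq(ellipse_points(60, 60, 30, 20, 0, 10))
  full <- clip_eyelids(e, dim = c(120, 120))
  expect_equal(sum(full), pi * 30 * 20, tolerance = 0.02)
  # lids far outside: mask unchanged
  far_up <- cbind(c(10, 60, 110), c(2, 1, 2))
  far_lo <- cbind(c(10, 60, 110), c(118, 119, 118))
  expect_equal(clip_eyelids(e, far_up, far_lo, dim = c(120, 120)), full)
  # a horizontal upper lid through the centre halves the area
  half <- clip_eyelids(e, cbind(c(10, 60, 110), c(60, 60, 60)), dim = c(120, 120))
  expect_equal(sum(half) / sum(full), 0.5, tolerance = 0.02)
  # clipping never increases the area
  set.seed(2)
  for (k in 1:5) {
    lid <- cbind(c(20, 60, 100), 60 + rnorm(3, 0, 15))
    expect_lte(sum(clip_eyelids(e, upper_pts = lid, dim = c(120, 120))), sum(full))
  }
  expect_error(clip_eyelids(e, upper_pts = cbind(1:2, 1:2), dim = c(120, 120)),
               ">= 3")
})

test_that("IoU matches hand-counted cases and is symmetric", {
  m <- matrix(0, 6, 6)
  a <- m; a[2:3, 2:3] <- 1           # 2x2 square
  b <- m; b[2:3, 3:4] <- 1           # overlapping 2x2 square, 1x2 strip shared
  expect_equal(iou(a, a), 1)
  disj <- m; disj[5:6, 5:6] <- 1
  expect_equal(iou(a, disj), 0)
  expect_equal(iou(a, b), 2 / 6)
  expect_equal(iou(b, a), iou(a, b))
  expect_equal(iou(m, m), 1)  # both empty
  expect_error(iou(a, matrix(0, 5, 6)), "shapes")
  # symmetry over random masks
  set.seed(3)
  for (k in 1:10) {
    p <- matrix(rbinom(64, 1, 0.4), 8, 8)
    g <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_identical(iou(p, g), iou(g, p))
  }
})

test_that("the fallback segmenter reaches IoU >= 0.85 on unoccluded synthetic eyes", {
  for (seed in 1:3) {
    sc <- small_scene(texture_seed = seed)
    traj <- build_trajectory(list(), 2 / sc$fps, sc, drift_sigma = 0.05, seed = seed)
    scn <- render_scene(sc, traj, NULL, seed = seed)
    box <- eye_box(sc, 1, max_gaze_deg = 0.5)
    pred <- fallback_segment(video_get(scn$video, 1), box)
    expect_gte(iou(pred, scene_mask(scn, 1, 1)), 0.85)
  }
  # no annulus in a blank box: empty mask with a warning
  blank <- matrix(150, 100, 100)
  expect_warning(out <- fallback_segment(blank, c(10, 10, 80, 80)), "pupil")
  expect_equal(sum(out), 0)
})
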