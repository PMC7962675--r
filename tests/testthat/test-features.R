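test_that("geometric median handles degenerate and collinear sets", {
  expect_equal(geometric_median(cbind(4.2, -1)), c(4.2, -1))
  # symmetric cloud: the centre by symmetry
  sym <- rbind(c(11, 10), c(9, 10), c(10, 11), c(10, 9))
  expect_lt(max(abs(geometric_median(sym) - c(10, 10))), 1e-6)
  # collinear shifts: the 1-D median
  col3 <- rbind(c(0, 0), c(1, 0), c(5, 0))
  expect_lt(max(abs(geometric_median(col3) - c(1, 0))), 1e-6)
  expect_error(geometric_median(matrix(0, 0, 2)), "empty")
})

test_that("geometric median matches the grid-search oracle and resists outliers", {
  set.seed(11)
  pts <- rbind(matrix(rep(c(2, 1), 20), ncol = 2, byrow = TRUE) + rnorm(40, 0, 0.02),
               c(30, -15), c(30, -15))
  gm <- geometric_median(pts)
  expect_lt(max(abs(gm - gm_grid_oracle(pts, res = 0.01))), 0.05)
  expect_lt(max(abs(gm - c(2, 1))), 0.1)
  # contamination property: up to 20% gross outliers move the estimate < 0.1 px
  for (k in c(2, 4)) {
    base <- matrix(rep(c(-0.4, 0.7), 16), ncol = 2, byrow = TRUE) +
      matrix(rnorm(32, 0, 0.01), ncol = 2)
    contaminated <- rbind(base, matrix(rep(c(40, 25), k), ncol = 2, byrow = TRUE))
    expect_lt(max(abs(geometric_median(contaminated) - geometric_median(base))), 0.1)
  }
})

test_that("patch correspondence collapses matches to geometric medians", {
  m <- structure(list(src = rbind(c(10, 10), c(11, 10), c(9, 10), c(10, 11), c(10, 9)),
                      dst = rbind(c(14, 8), c(15, 8), c(13, 8), c(14, 9), c(14, 7)),
                      dist = rep(0.1, 5), n = 5L, ok = TRUE), class = "match_set")
  co <- patch_correspondence(m)
  expect_lt(max(abs(co$src - c(10, 10))), 1e-6)
  expect_lt(max(abs(co$dst - c(14, 8))), 1e-6)
  single <- structure(list(src = cbind(3, 4), dst = cbind(5, 6)), class = "match_set")
  co1 <- patch_correspondence(single)
  expect_equal(co1$src, c(3, 4))
  expect_error(patch_correspondence(structure(list(src = matrix(0, 0, 2)),
                                              class = "match_set")), "empty")
})

test_that("iris texture gives a rich, seed-stable keypoint population", {
  cfgA <- scene_config(texture_seed = 1)
  tex <- generate_iris_texture(cfgA)
  expect_equal(dim(tex), rep(2 * cfgA$iris_radius, 2))
  expect_identical(tex, generate_iris_texture(cfgA))
  texB <- generate_iris_texture(scene_config(texture_seed = 2))
  expect_gt(mean(abs(tex - texB) > 1), 0.01)
  kp <- detect_keypoints(tex, feature_config(response_threshold = 1.2, border = 5))
  r <- sqrt((kp$x - cfgA$iris_radius - 0.5)^2 + (kp$y - cfgA$iris_radius - 0.5)^2)
  expect_gte(sum(r > cfgA$pupil_radius & r < cfgA$iris_radius), 50)
  expect_error(generate_iris_texture(scene_config(pupil_radius = 31)), "smaller")
})

test_that("patch matching recovers synthetic shifts and flags blank patches", {
  set.seed(7)
  base <- irisvel:::gauss_blur(matrix(runif(150 * 150, 0, 255), 150, 150), 1) -
          irisvel:::gauss_blur(matrix(runif(150 * 150, 0, 255), 150, 150), 3)
  base <- 128 + 60 * base / stats::sd(base)
  shifted <- warp_similarity(base, similarity_transform(tx = 4, ty = -2), bg = 128)
  region <- c(30, 30, 90, 90)
  m <- match_patch(base, base, region)
  expect_true(m$ok)
  expect_lt(max(abs(m$dst - m$src)), 1e-6)
  m2 <- match_patch(base, shifted, region)
  expect_true(m2$ok)
  d <- m2$dst - m2$src
  expect_true(all(abs(d[, 1] - 4) < 0.5))
  expect_true(all(abs(d[, 2] + 2) < 0.5))
  blank <- matrix(128, 150, 150)
  m3 <- match_patch(blank, blank, region)
  expect_false(m3$ok)
})
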