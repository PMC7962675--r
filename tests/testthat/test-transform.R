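test_that("similarity transforms compose, invert and act on points exactly", {
  tf <- similarity_transform(s = 1.05, theta = 10 * pi / 180, tx = 5, ty = 1)
  p <- cbind(c(0, 10, -3.5), c(0, 2, 7))
  expect_equal(st_apply(similarity_transform(), p), p)
  round_trip <- st_apply(st_inverse(tf), st_apply(tf, p))
  expect_lt(max(abs(round_trip - p)), 1e-9)
  id <- st_compose(tf, st_inverse(tf))
  expect_lt(max(abs(st_params(id) - c(1, 0, 0, 0))), 1e-9)
  a <- similarity_transform(0.9, 0.2, -1, 4)
  expect_equal(st_apply(st_compose(a, tf), p), st_apply(a, st_apply(tf, p)),
               tolerance = 1e-12)
  expect_error(similarity_transform(s = -1), "positive")
})

test_that("least-squares similarity estimation recovers forward-generated transforms", {
  pts <- cbind(c(10, 80, 45, 30), c(12, 20, 70, 55))
  # identity and pure translation
  expect_lt(max(abs(st_params(estimate_similarity(pts, pts)) - c(1, 0, 0, 0))), 1e-12)
  sh <- sweep(pts, 2, c(-3, 2), "+")
  expect_equal(unname(st_params(estimate_similarity(pts, sh))[3:4]), c(-3, 2),
               tolerance = 1e-12)
  # general 4-DOF case: parameters recovered to 1e-9
  tf <- similarity_transform(1.05, 10 * pi / 180, 5, 1)
  est <- estimate_similarity(pts, st_apply(tf, pts))
  expect_lt(max(abs(st_params(est) - st_params(tf))), 1e-9)
  # exact with the minimal two pairs
  est2 <- estimate_similarity(pts[1:2, ], st_apply(tf, pts[1:2, ]))
  expect_lt(max(abs(st_params(est2) - st_params(tf))), 1e-9)
  expect_error(estimate_similarity(pts[c(1, 1), ], pts[1:2, ]), "coincident")
  expect_error(estimate_similarity(pts[1, , drop = FALSE], pts[1, , drop = FALSE]),
               ">= 2")
})

test_that("warp_similarity agrees with the pure-R bilinear reference", {
  set.seed(5)
  img <- irisvel:::gauss_blur(matrix(runif(120 * 90, 0, 255), 90, 120), 1.5)
  tf <- similarity_transform(1.02, 0.015, 4.3, -2.6)
  a <- warp_similarity(img, tf, bg = 0)
  b <- irisvel:::warp_similarity_ref(img, tf, bg = 0)
  expect_lt(max(abs(a - b)[20:70, 20:100]), 0.5)
  # integer translation moves content exactly
  sh <- warp_similarity(img, similarity_transform(tx = 7, ty = -3), bg = 0)
  expect_equal(sh[10:60, 30:100], img[13:63, 23:93], tolerance = 1e-6)
})
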