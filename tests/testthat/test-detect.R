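test_that("the velocity mixture recovers simulated noise/microsaccade components", {
  x <- irisvel:::with_seed(31, {
    k <- stats::rbinom(5000, 1, 0.4)
    abs((1 - k) * stats::rnorm(5000, 1.5, 0.5) + k * stats::rnorm(5000, 8, 2))
  })
  gmm <- fit_velocity_gmm(x)
  mu <- sort(gmm$means)
  expect_lt(abs(mu[1] - 1.5), 0.2)
  expect_lt(abs(mu[2] - 8), 0.2)
  expect_equal(sum(gmm$weights), 1)
  expect_equal(gmm$noise, which.min(gmm$means))
  # deterministic refit
  gmm2 <- fit_velocity_gmm(x)
  expect_identical(gmm$means, gmm2$means)
  # independent EM cross-check (package oracle, not the implementation)
  if (requireNamespace("mclust", quietly = TRUE)) {
    mclustBIC <- mclust::mclustBIC  # Mclust resolves it in the caller
    mc <- mclust::Mclust(x[x < 20], G = 2, modelNames = "V", verbose = FALSE)
    expect_lt(max(abs(sort(gmm$means) - sort(mc$parameters$mean))), 0.1)
  }
  expect_error(fit_velocity_gmm(rep(2, 400)), "degenerate")
  expect_error(fit_velocity_gmm(stats::runif(30, 0, 10)), "floor-only")
})

test_that("the adaptive threshold is the 3-sigma noise bound floored at 3.84", {
  mk <- function(m, s) structure(list(means = c(m, 15), sds = c(s, 2),
                                      weights = c(0.7, 0.3), noise = 1L),
                                 class = "velocity_gmm")
  expect_equal(adaptive_threshold(mk(1, 0.5)), 3.84)    # candidate 2.5 -> floor
  expect_equal(adaptive_threshold(mk(2, 2)), 8)         # 2 + 3 x 2
  expect_equal(adaptive_threshold(mk(1.5, 0.78)), 3.84) # boundary: 3.84 exactly
  # monotone in both noise parameters, never below the floor
  th <- outer(seq(0.5, 4, 0.5), seq(0.2, 2, 0.3),
              function(m, s) mapply(function(mm, ss) adaptive_threshold(mk(mm, ss)), m, s))
  expect_true(all(diff(th) >= 0))          # rows: increasing mean
  expect_true(all(apply(th, 1, diff) >= 0)) # cols: increasing sd
  expect_true(all(th >= 3.84))
  expect_error(detection_config(threshold_floor = 25), "<")
})

test_that("event extraction thresholds, merges and labels runs correctly", {
  n <- 60
  fps <- 96
  mkpos <- function(speed) {
    # synthesise a 1-D position whose diff reproduces the speed trace
    list(cbind(cumsum(c(0, speed)) / fps, 0))
  }
  quiet <- rep(1, n)
  expect_equal(nrow(detect_events(quiet, mkpos(quiet), 3.84)), 0)
  # one 3-frame excursion peaking at 10 deg/s
  sp <- rep(0.5, n); sp[20:22] <- c(8, 10, 8)
  ev <- detect_events(sp, mkpos(sp), 3.84)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$label, "microsaccade")
  expect_equal(ev$peak_frame, 21)
  # two supra-threshold peaks 3 frames apart merge into one event
  sp2 <- rep(0.5, n); sp2[20] <- 9; sp2[23] <- 11
  ev2 <- detect_events(sp2, mkpos(sp2), 3.84)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$peak_frame, 23)
  # peaks >= min_separation stay separate events
  sp3 <- rep(0.5, n); sp3[20] <- 9; sp3[26] <- 11
  expect_equal(nrow(detect_events(sp3, mkpos(sp3), 3.84)), 2)
  # a 60 deg/s excursion is a saccade, excluded from microsaccades
  sp4 <- rep(0.5, n); sp4[30:32] <- c(40, 60, 40)
  ev4 <- detect_events(sp4, mkpos(sp4), 3.84)
  expect_equal(ev4$label, "saccade")
  # all-gap trace: empty with a warning
  expect_warning(out <- detect_events(rep(NA_real_, n), mkpos(quiet), 3.84),
                 "all gaps")
  expect_equal(nrow(out), 0)
  expect_error(detect_events(sp, mkpos(sp), 1), "floor")
})

test_that("merged events never leave peaks closer than the minimum separation", {
  set.seed(13)
  for (k in 1:20) {
    sp <- pmax(0, stats::rnorm(200, 1, 1))
    sp[sample(200, 12)] <- stats::runif(12, 6, 30)
    ev <- detect_events(sp, list(cbind(cumsum(c(0, sp)) / 96, 0)), 3.84)
    if (nrow(ev) > 1) expect_true(all(diff(ev$peak_frame) >= 5))
  }
})

test_that("event amplitude is the displacement between flanking minima", {
  # purely horizontal event: amplitude equals |dx|
  pos <- cbind(c(rep(0, 10), seq(0, 0.4, length.out = 5), rep(0.4, 10)), 0)
  sp <- sqrt(rowSums(apply(pos, 2, diff)^2)) * 96
  ev <- detect_events(sp, list(pos), 3.84)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 0.4, tolerance = 1e-9)
  # zero-displacement oscillation: position returns exactly
  osc <- cbind(c(rep(0, 10), 0.2, 0, -0.2, rep(0, 10)), 0)
  spo <- sqrt(rowSums(apply(osc, 2, diff)^2)) * 96
  evo <- detect_events(spo, list(osc), 3.84)
  amp0 <- event_amplitude(list(min_before = evo$min_before[1],
                               min_after = evo$min_after[1]), list(osc))
  expect_equal(amp0$cyclopean, 0)
})

test_that("the main-sequence fit recovers the generating slope", {
  set.seed(21)
  amps <- stats::runif(12, 0.1, 0.6)
  ev <- data.frame(peak_speed = 47 * amps * stats::rnorm(12, 1, 0.03),
                   amplitude = amps)
  ms <- main_sequence(ev)
  expect_lt(abs(ms$slope - 47) / 47, 0.1)
  # identical events: slope is exactly peak/amplitude
  same <- data.frame(peak_speed = rep(9.4, 4), amplitude = rep(0.2, 4))
  expect_equal(main_sequence(same)$slope, 47)
  withzero <- rbind(ev, data.frame(peak_speed = 5, amplitude = 0))
  expect_warning(ms2 <- main_sequence(withzero), "excluded")
  expect_equal(ms2$n, 12)
  expect_error(main_sequence(ev[1:2, ]), ">= 3")
})

test_that("detection scoring performs greedy one-to-one onset matching", {
  tru <- c(1, 2.5, 4)
  s1 <- score_detection(tru, tru, tolerance_ms = 50)
  expect_equal(c(s1$hits, s1$misses, s1$false_alarms), c(3, 0, 0))
  s2 <- score_detection(numeric(0), tru)
  expect_equal(c(s2$hits, s2$misses, s2$false_alarms), c(0, 3, 0))
  s3 <- score_detection(c(1, 2.5, 4.2), tru, tolerance_ms = 50)
  expect_equal(c(s3$hits, s3$misses, s3$false_alarms), c(2, 1, 1))
  # one-to-one: two detections cannot both claim one truth
  s4 <- score_detection(c(0.99, 1.01), c(1), tolerance_ms = 50)
  expect_equal(c(s4$hits, s4$false_alarms), c(1, 1))
  s5 <- score_detection(tru, tru, valid_time_s = 10)
  expect_equal(s5$rate_per_s, 0.3)
})
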