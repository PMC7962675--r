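# Adaptive velocity-threshold event detection (I-VT): a two-component
# Gaussian mixture on cyclopean speeds below 20 deg/s separates the noise
# and microsaccade velocity distributions; the detection threshold is the
# noise mean + 3 sigma (the 99.7% rule) with a 3.84 deg/s floor. Runs above
# threshold become events, merged when their peaks are closer than 5 frames
# (52 ms at 96 fps), extended to the flanking speed minima, labelled
# saccade at or above 50 deg/s, with amplitudes measured between the
# flanking minima.

#' Event-detection configuration
#'
#' @param gmm_input_cut Speeds at or above this (deg/s) are excluded from
#'   the mixture fit (default 20; removes larger saccades).
#' @param threshold_floor Lower bound of the adaptive threshold in deg/s
#'   (default 3.84, selected against the noise floor to minimise false
#'   alarms).
#' @param saccade_cut Peak speed (deg/s) at or above which an event is a
#'   saccade rather than a microsaccade (default 50).
#' @param min_separation Minimum frames between detected velocity peaks
#'   (default 5, i.e. 52 ms at 96 fps); closer peaks are merged.
#' @param sigma_mult Noise sigmas above the noise mean (default 3, the
#'   99.7% rule).
#' @param min_run Minimum frames above threshold for a candidate event
#'   (default 1).
#' @return List of class `detection_config`.
#' @export
detection_config <- function(gmm_input_cut = 20, threshold_floor = 3.84,
                             saccade_cut = 50, min_separation = 5L,
                             sigma_mult = 3, min_run = 1L) {
  if (!(0 < threshold_floor && threshold_floor < gmm_input_cut &&
        gmm_input_cut < saccade_cut))
    stopf("need 0 < threshold_floor < gmm_input_cut < saccade_cut")
  structure(list(gmm_input_cut = gmm_input_cut,
                 threshold_floor = threshold_floor,
                 saccade_cut = saccade_cut,
                 min_separation = as.integer(min_separation),
                 sigma_mult = sigma_mult, min_run = as.integer(min_run)),
            class = "detection_config")
}

#' Fit the two-component velocity mixture
#'
#' EM fit of a 1-D two-component Gaussian mixture to the speed samples
#' below `gmm_input_cut`, representing the noise and microsaccade velocity
#' distributions. Initialised by a deterministic two-means split (lower
#' and upper quartile centres), so the fit is reproducible.
#'
#' @param speed Numeric vector of absolute cyclopean speeds (deg/s); `NA`
#'   samples (gaps) are ignored.
#' @param config A [detection_config()].
#' @param min_samples Minimum usable samples (default 50).
#' @return A `velocity_gmm`: `means`, `sds`, `weights` (each length 2),
#'   `noise` (index of the lower-mean, noise component), `loglik`, `n`.
#' @export
fit_velocity_gmm <- function(speed, config = detection_config(),
                             min_samples = 50) {
  x <- speed[is.finite(speed) & speed < config$gmm_input_cut]
  if (length(x) < min_samples)
    stopf(paste("only %d usable samples below %g deg/s (need %d);",
                "fall back to floor-only thresholding"),
          length(x), config$gmm_input_cut, min_samples)
  if (stats::sd(x) < 1e-10)
    stopf("all speed samples identical; mixture fit is degenerate")
  km <- stats::kmeans(x, centers = matrix(stats::quantile(x, c(0.25, 0.75)), 2, 1))
  mu <- as.numeric(km$centers)
  sd2 <- vapply(1:2, function(k) {
    v <- stats::var(x[km$cluster == k])
    if (!is.finite(v) || v < 1e-8) 1e-4 else v
  }, 0)
  w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(x)
  w[w < 1e-3] <- 1e-3; w <- w / sum(w)
  ll_old <- -Inf
  for (it in seq_len(500)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sqrt(sd2[1]))
    d2 <- w[2] * stats::dnorm(x, mu[2], sqrt(sd2[2]))
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    r <- d1 / tot
    ll <- sum(log(tot))
    n1 <- sum(r); n2 <- length(x) - n1
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sd2 <- c(sum(r * (x - mu[1])^2) / n1, sum((1 - r) * (x - mu[2])^2) / n2)
    sd2 <- pmax(sd2, 1e-8)
    w <- c(n1, n2) / length(x)
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-10) break
    ll_old <- ll
  }
  structure(list(means = mu, sds = sqrt(sd2), weights = w,
                 noise = which.min(mu), loglik = ll, n = length(x)),
            class = "velocity_gmm")
}

#' @export
print.velocity_gmm <- function(x, ...) {
  cat(sprintf("velocity GMM (n = %d): noise N(%.3g, %.3g^2) w %.2f | signal N(%.3g, %.3g^2) w %.2f\n",
              x$n, x$means[x$noise], x$sds[x$noise], x$weights[x$noise],
              x$means[-x$noise][1], x$sds[-x$noise][1], x$weights[-x$noise][1]))
  invisible(x)
}

#' Adaptive detection threshold from the velocity mixture
#'
#' `max(noise_mean + sigma_mult * noise_sd, threshold_floor)` in deg/s:
#' the 99.7% bound of the noise component, never below the 3.84 deg/s
#' floor.
#'
#' @param gmm A `velocity_gmm`.
#' @param config A [detection_config()].
#' @return Threshold in deg/s.
#' @export
adaptive_threshold <- function(gmm, config = detection_config()) {
  max(gmm$means[gmm$noise] + config$sigma_mult * gmm$sds[gmm$noise],
      config$threshold_floor)
}

# parabolic refinement of the peak value from three samples around it
refine_peak <- function(speed, k) {
  if (k <= 1 || k >= length(speed)) return(speed[k])
  s <- speed[(k - 1):(k + 1)]
  if (anyNA(s)) return(speed[k])
  den <- s[1] - 2 * s[2] + s[3]
  if (abs(den) < 1e-12 || den > 0) return(speed[k])
  d <- 0.5 * (s[1] - s[3]) / den
  if (abs(d) > 1) return(speed[k])
  s[2] - 0.25 * (s[1] - s[3]) * d
}

#' Detect eye-movement events in a cyclopean speed trace
#'
#' Maximal runs of samples above the threshold become candidate events;
#' events whose peak frames are closer than `min_separation` are merged;
#' onset/offset are extended to the flanking local minima of the speed
#' trace; events with peak speed at or above `saccade_cut` are labelled
#' saccades, the rest microsaccades. Events overlapping gap frames are
#' dropped with a warning. Peak speed is refined by 3-point parabolic
#' interpolation around the peak sample.
#'
#' @param speed Absolute cyclopean speed trace (deg/s), `NA` = gap.
#' @param pos List of per-eye position traces ((n+1) x 2 matrices, deg)
#'   used for amplitudes; may be a single-element list.
#' @param threshold Detection threshold in deg/s (>= the configured
#'   floor).
#' @param config A [detection_config()].
#' @return Data frame of event records: `onset`, `offset` (frames),
#'   `peak_frame`, `peak_speed` (deg/s), `amplitude` (deg, cyclopean),
#'   `label`, `min_before`, `min_after` (flanking-minima frames),
#'   `approx` (amplitude flagged approximate at trace boundaries).
#' @export
detect_events <- function(speed, pos, threshold, config = detection_config()) {
  if (threshold < config$threshold_floor)
    stopf("threshold (%g) below the configured floor (%g)",
          threshold, config$threshold_floor)
  n <- length(speed)
  empty <- data.frame(onset = integer(0), offset = integer(0),
                      peak_frame = integer(0), peak_speed = numeric(0),
                      amplitude = numeric(0), label = character(0),
                      min_before = integer(0), min_after = integer(0),
                      approx = logical(0))
  if (all(is.na(speed))) {
    warnf("speed trace is all gaps; no events")
    return(empty)
  }
  above <- !is.na(speed) & speed > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start + 1 >= config$min_run, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  runs$peak <- vapply(seq_len(nrow(runs)), function(i) {
    seg <- runs$start[i]:runs$end[i]
    seg[which.max(speed[seg])]
  }, 0L)
  # merge runs whose peaks are closer than min_separation frames
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      if (runs$peak[i] - merged$peak[last] < config$min_separation) {
        merged$end[last] <- runs$end[i]
        if (speed[runs$peak[i]] > speed[merged$peak[last]])
          merged$peak[last] <- runs$peak[i]
      } else merged <- rbind(merged, runs[i, ])
    }
  }
  out <- NULL
  dropped <- 0
  for (i in seq_len(nrow(merged))) {
    on <- merged$start[i]; off <- merged$end[i]
    # extend to flanking local minima of the speed trace
    # strict descent only, so a flat (e.g. denoised-to-zero) stretch next
    # to the event is itself the minimum rather than a corridor to walk
    mb <- on
    while (mb > 1 && !is.na(speed[mb - 1]) && speed[mb - 1] < speed[mb]) mb <- mb - 1
    ma <- off
    while (ma < n && !is.na(speed[ma + 1]) && speed[ma + 1] < speed[ma]) ma <- ma + 1
    if (anyNA(speed[mb:ma])) { dropped <- dropped + 1; next }
    approx <- (mb == 1 && speed[1] > threshold) || (ma == n && speed[n] > threshold)
    pk <- merged$peak[i]
    amp <- event_amplitude(list(min_before = mb, min_after = ma), pos)
    out <- rbind(out, data.frame(
      onset = mb, offset = ma, peak_frame = pk,
      peak_speed = refine_peak(speed, pk),
      amplitude = amp$cyclopean,
      label = if (refine_peak(speed, pk) >= config$saccade_cut) "saccade"
              else "microsaccade",
      min_before = mb, min_after = ma, approx = approx))
  }
  if (dropped > 0) warnf("%d event(s) overlapping gap frames dropped", dropped)
  if (is.null(out)) empty else out
}

#' Event amplitude between the flanking velocity minima
#'
#' Euclidean displacement of the gaze position between the two flanking
#' speed-minimum frames, per eye and for the mean (cyclopean) position.
#' Velocity sample k spans position samples k and k+1, so an event
#' extending from minimum `mb` to `ma` displaces position from index `mb`
#' to `ma + 1`.
#'
#' @param event List or row with `min_before` and `min_after` (frames of
#'   the velocity trace).
#' @param pos List of per-eye position traces ((n+1) x 2, deg).
#' @return List with `cyclopean` (deg) and `per_eye` (numeric vector).
#' @export
event_amplitude <- function(event, pos) {
  i0 <- event$min_before; i1 <- event$min_after + 1
  per_eye <- vapply(pos, function(p) {
    d <- p[i1, ] - p[i0, ]
    sqrt(sum(d^2))
  }, 0)
  pm <- Reduce(`+`, pos) / length(pos)
  d <- pm[i1, ] - pm[i0, ]
  list(cyclopean = sqrt(sum(d^2)), per_eye = per_eye)
}

#' Main-sequence fit of peak speed against amplitude
#'
#' Least-squares regression of event peak speed (deg/s) on amplitude
#' (deg) through the origin; the slope is in 1/s. Amplitude-zero events
#' are excluded with a warning.
#'
#' @param events Event data frame from [detect_events()].
#' @return List of class `main_sequence`: `slope` (1/s), `r_squared`,
#'   `n`, and the fitted events.
#' @export
main_sequence <- function(events) {
  ev <- events
  if (any(ev$amplitude <= 0)) {
    warnf("%d amplitude-0 event(s) excluded from the main-sequence fit",
          sum(ev$amplitude <= 0))
    ev <- ev[ev$amplitude > 0, , drop = FALSE]
  }
  if (nrow(ev) < 3) stopf("main-sequence fit needs >= 3 events, got %d", nrow(ev))
  f <- stats::lm(peak_speed ~ 0 + amplitude, data = ev)
  ss_res <- sum(stats::residuals(f)^2)
  ss_tot <- sum(ev$peak_speed^2)
  structure(list(slope = unname(stats::coef(f)[1]),
                 r_squared = 1 - ss_res / ss_tot, n = nrow(ev), events = ev),
            class = "main_sequence")
}

#' @export
print.main_sequence <- function(x, ...) {
  cat(sprintf("main sequence: slope %.3g 1/s over %d events (R^2 %.4f)\n",
              x$slope, x$n, x$r_squared))
  invisible(x)
}

#' Score detected events against ground truth
#'
#' Greedy one-to-one matching of detected to true events by onset time
#' within a tolerance. Unmatched detections are false alarms; unmatched
#' truths are misses. The microsaccade rate is computed over the valid
#' (non-gap) duration.
#'
#' @param detected_onsets_s Sorted detected event onsets in s.
#' @param truth_onsets_s Sorted true event onsets in s.
#' @param tolerance_ms Matching tolerance (default 50 ms).
#' @param valid_time_s Valid observation time for the rate (optional).
#' @param dedup_interval_s Optional interval de-duplication: detections
#'   within this interval of an already-matched detection are collapsed
#'   before scoring (one unique voluntary movement per target interval).
#' @return List: `hits`, `misses`, `false_alarms`, `rate_per_s` (`NA`
#'   without `valid_time_s`), `matches` (data frame of matched pairs).
#' @export
score_detection <- function(detected_onsets_s, truth_onsets_s,
                            tolerance_ms = 50, valid_time_s = NULL,
                            dedup_interval_s = NULL) {
  det <- sort(detected_onsets_s)
  if (!is.null(dedup_interval_s) && length(det) > 1)
    det <- det[c(TRUE, diff(det) >= dedup_interval_s)]
  tru <- sort(truth_onsets_s)
  tol <- tolerance_ms / 1000
  used <- logical(length(det))
  matches <- NULL
  for (t in tru) {
    cand <- which(!used & abs(det - t) <= tol)
    if (length(cand)) {
      j <- cand[which.min(abs(det[cand] - t))]
      used[j] <- TRUE
      matches <- rbind(matches, data.frame(truth_s = t, detected_s = det[j]))
    }
  }
  hits <- if (is.null(matches)) 0L else nrow(matches)
  list(hits = hits, misses = length(tru) - hits,
       false_alarms = sum(!used),
       rate_per_s = if (is.null(valid_time_s)) NA_real_ else hits / valid_time_s,
       matches = matches)
}
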