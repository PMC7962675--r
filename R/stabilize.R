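# Head-motion compensation: per-frame similarity transforms estimated from
# geometric-median correspondences of four facial patches, cascaded across
# frames with periodic keyframe realignment (default every 480 frames, 5 s).

#' Match one facial patch between two frames
#'
#' Crops the patch rectangle from both frames and runs the feature
#' matching pipeline (blob keypoints, L2 brute-force matching, Lowe ratio
#' test, RANSAC). Coordinates in the returned match set are full-frame.
#'
#' @param frame1,frame2 Grayscale frames.
#' @param region Patch rectangle `c(x0, y0, w, h)` in reference px.
#' @param config A [feature_config()].
#' @param seed RANSAC seed.
#' @return A `match_set`; `ok = FALSE` flags low confidence (< 3 inliers,
#'   e.g. a blank patch).
#' @export
match_patch <- function(frame1, frame2, region, config = feature_config(),
                        seed = 1) {
  rows <- region[2]:(region[2] + region[4] - 1)
  cols <- region[1]:(region[1] + region[3] - 1)
  m <- match_features(frame1[rows, cols], frame2[rows, cols], config, seed = seed)
  if (m$ok) {
    off <- c(region[1] - 1, region[2] - 1)
    m$src <- sweep(m$src, 2, -off)
    m$dst <- sweep(m$dst, 2, -off)
  }
  m
}

# crop the patch rectangles of a frame and detect their keypoints once
prepare_patches <- function(frame, patches, config) {
  lapply(patches, function(rg) {
    img <- frame[rg[2]:(rg[2] + rg[4] - 1), rg[1]:(rg[1] + rg[3] - 1)]
    c(list(img = img), prepare_keypoints(img, config))
  })
}

# similarity transform frame a -> frame b from the four patch
# geometric-median correspondences, using cached per-patch keypoints;
# returns NULL when fewer than `min_patches` patches match confidently
pairwise_transform_cached <- function(pa, pb, patches, config, seed,
                                      min_patches = 3) {
  src <- NULL; dst <- NULL; n_ok <- 0
  for (p in seq_along(patches)) {
    m <- match_features(pa[[p]]$img, pb[[p]]$img, config,
                        kp1 = pa[[p]], kp2 = pb[[p]],
                        seed = derive_seed(seed, p))
    if (m$ok) {
      off <- c(patches[[p]][1] - 1, patches[[p]][2] - 1)
      co <- patch_correspondence(m)
      src <- rbind(src, co$src + off); dst <- rbind(dst, co$dst + off)
      n_ok <- n_ok + 1
    }
  }
  if (n_ok < min_patches) return(NULL)
  estimate_similarity(src, dst)
}

# uncached variant operating on full frames
pairwise_transform <- function(fa, fb, patches, config, seed,
                               min_patches = 3) {
  pairwise_transform_cached(prepare_patches(fa, patches, config),
                            prepare_patches(fb, patches, config),
                            patches, config, seed, min_patches)
}

#' Align a video to its reference frame by cascaded similarity transforms
#'
#' Within each keyframe block, frame k's transform to the block keyframe
#' is the composition of consecutive pairwise transforms; keyframes are
#' matched directly to the previous keyframe, chaining all frames to the
#' global reference (frame 1). Frames are warped into reference
#' coordinates with sub-pixel (bilinear) interpolation. If fewer than
#' three patches match confidently in a frame pair, the previous pairwise
#' transform is reused and a warning logged.
#'
#' @param video An `iris_video`.
#' @param patches List of 4 patch rectangles `c(x0, y0, w, h)`.
#' @param keyframe_interval Frames between keyframe realignments
#'   (default 480, i.e. 5 s at 96 fps); must be >= 2.
#' @param config A [feature_config()].
#' @param seed Seed for the RANSAC stages.
#' @param warp Logical; warp and return the stabilized video (default
#'   `TRUE`).
#' @return List of class `stabilization`: `transforms` (per-frame
#'   `similarity_transform` to the reference), `stabilized` (an
#'   `iris_video` or `NULL`), `keyframes` (indices), `jitter` (per-
#'   keyframe translation discontinuity, px), `warnings` (frame indices
#'   where the fallback transform was used).
#' @export
cascade_align <- function(video, patches, keyframe_interval = 480,
                          config = feature_config(), seed = 1, warp = TRUE) {
  if (keyframe_interval < 2) stopf("keyframe_interval must be >= 2")
  n <- video_length(video)
  transforms <- vector("list", n)
  transforms[[1]] <- similarity_transform()
  keyframes <- seq(1, n, by = keyframe_interval)
  jitter <- numeric(0)
  fallback_frames <- integer(0)
  A_key <- similarity_transform()  # current keyframe -> reference
  prev_pair <- similarity_transform()
  p_prev <- prepare_patches(video_get(video, 1), patches, config)
  T_block <- similarity_transform() # keyframe -> current frame (cascaded)
  p_key <- p_prev
  for (i in 2:n) {
    p_cur <- prepare_patches(video_get(video, i), patches, config)
    is_key <- i %in% keyframes
    Tp <- pairwise_transform_cached(p_prev, p_cur, patches, config,
                                    seed = derive_seed(seed, i))
    if (is.null(Tp)) {
      Tp <- prev_pair
      fallback_frames <- c(fallback_frames, i)
      warnf("frame %d: fewer than 3 confident patches; reusing previous transform", i)
    }
    prev_pair <- Tp
    T_block <- st_compose(Tp, T_block)       # keyframe -> frame i
    A_cascade <- st_compose(A_key, st_inverse(T_block))
    if (is_key) {
      # realign: match the new keyframe directly to the previous keyframe
      Tk <- pairwise_transform_cached(p_key, p_cur, patches, config,
                                      seed = derive_seed(seed, n + i))
      A_direct <- if (is.null(Tk)) A_cascade else st_compose(A_key, st_inverse(Tk))
      jitter <- c(jitter, sqrt(sum((st_params(A_direct)[3:4] -
                                    st_params(A_cascade)[3:4])^2)))
      transforms[[i]] <- A_direct
      A_key <- A_direct
      T_block <- similarity_transform()
      p_key <- p_cur
    } else {
      transforms[[i]] <- A_cascade
    }
    p_prev <- p_cur
  }
  stabilized <- NULL
  if (warp) {
    out <- vector("list", n)
    for (i in seq_len(n))
      out[[i]] <- frame_to_raw(
        warp_similarity(video_get(video, i), transforms[[i]], bg = 168))
    stabilized <- structure(list(data = out, h = video$h, w = video$w, n = n,
                                 fps = video$fps), class = "iris_video")
  }
  structure(list(transforms = transforms, stabilized = stabilized,
                 keyframes = keyframes, jitter = jitter,
                 warnings = fallback_frames),
            class = "stabilization")
}

#' @export
print.stabilization <- function(x, ...) {
  cat(sprintf("stabilization: %d frames, %d keyframes, %d fallback frames\n",
              length(x$transforms), length(x$keyframes), length(x$warnings)))
  if (length(x$jitter))
    cat(sprintf("  keyframe jitter (px): median %.3g, max %.3g\n",
                stats::median(x$jitter), max(x$jitter)))
  invisible(x)
}

#' Marker-track metrics before/after stabilization
#'
#' Per-axis mean squared displacement (MSE) from the marker's position in
#' the reference frame, and per-axis standard deviation (population, n
#' denominator), plus mean-per-class aggregates.
#'
#' @param before,after n x 2 marker tracks (px).
#' @param reference Index of the reference frame (default 1).
#' @return List of class `stabilization_metrics` with `before` and
#'   `after` data frames (`mse_x`, `mse_y`, `std_x`, `std_y`) and `mpc`
#'   (mean-per-class MSE and STD before/after).
#' @export
stabilization_metrics <- function(before, after, reference = 1) {
  if (nrow(before) != nrow(after)) stopf("tracks differ in length")
  one <- function(tr) {
    d <- sweep(tr, 2, tr[reference, ])
    sdev <- function(z) sqrt(mean((z - mean(z))^2))
    data.frame(mse_x = mean(d[, 1]^2), mse_y = mean(d[, 2]^2),
               std_x = sdev(tr[, 1]), std_y = sdev(tr[, 2]))
  }
  b <- one(before); a <- one(after)
  structure(list(before = b, after = a,
                 mpc = data.frame(
                   mse_before = mean(c(b$mse_x, b$mse_y)),
                   std_before = mean(c(b$std_x, b$std_y)),
                   mse_after = mean(c(a$mse_x, a$mse_y)),
                   std_after = mean(c(a$std_x, a$std_y)))),
            class = "stabilization_metrics")
}

#' @export
print.stabilization_metrics <- function(x, ...) {
  cat("stabilization metrics (mean per class):\n")
  print(x$mpc, row.names = FALSE)
  invisible(x)
}

#' Track a template patch through a video by normalised cross-correlation
#'
#' Takes the template around `center` in the reference frame and locates
#' it in every frame by NCC with 3-point parabolic sub-pixel refinement.
#' The first frame is searched over the full `search` radius; subsequent
#' frames over a small window around the previous position (the marker
#' motion being measured is smooth). Used to measure marker motion for
#' stabilization metrics.
#'
#' @param video An `iris_video`.
#' @param center Template centre `c(x, y)` in the reference frame.
#' @param size Template side (odd, default 15).
#' @param search Search radius in px for the first frame (default 20).
#' @param local Search radius around the previous position (default 4).
#' @param reference Reference frame index for the template (default 1).
#' @return n x 2 matrix of template positions.
#' @export
track_template <- function(video, center, size = 15, search = 20, local = 4,
                           reference = 1) {
  stopifnot(size %% 2 == 1)
  r <- (size - 1) / 2
  ref <- video_get(video, reference)
  tpl <- ref[(center[2] - r):(center[2] + r), (center[1] - r):(center[1] + r)]
  tpl0 <- as.numeric(tpl - mean(tpl))
  tn <- sqrt(sum(tpl0^2))
  npx <- size^2
  toff <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
  n <- video_length(video)
  out <- matrix(NA_real_, n, 2)
  ncc_at <- function(f, cx, cy) {
    # NCC scores at all integer candidate centres (vectorised gather)
    h <- nrow(f)
    base <- (cx - 1) * h + cy
    idx <- outer(base, toff[, "dx"] * h + toff[, "dy"], `+`)
    P <- matrix(f[idx], length(base))
    P0 <- P - rowMeans(P)
    den <- sqrt(rowSums(P0^2)) * tn
    sc <- as.numeric(P0 %*% tpl0) / den
    sc[den <= 0] <- -Inf
    sc
  }
  prev <- center
  for (i in seq_len(n)) {
    rad <- if (i == 1) search else local
    cx0 <- round(prev[1]); cy0 <- round(prev[2])
    f <- video_get(video, i)
    xs <- max(r + 2, cx0 - rad):min(ncol(f) - r - 1, cx0 + rad)
    ys <- max(r + 2, cy0 - rad):min(nrow(f) - r - 1, cy0 + rad)
    cx <- rep(xs, each = length(ys)); cy <- rep(ys, times = length(xs))
    sc <- matrix(ncc_at(f, cx, cy), length(ys), length(xs))
    best <- which(sc == max(sc), arr.ind = TRUE)[1, ]
    sub <- c(0, 0)
    par1 <- function(s) {
      den <- s[1] - 2 * s[2] + s[3]
      if (is.finite(den) && abs(den) > 1e-12)
        min(max(0.5 * (s[1] - s[3]) / den, -0.5), 0.5) else 0
    }
    if (best[2] > 1 && best[2] < ncol(sc)) sub[1] <- par1(sc[best[1], best[2] + (-1:1)])
    if (best[1] > 1 && best[1] < nrow(sc)) sub[2] <- par1(sc[best[1] + (-1:1), best[2]])
    out[i, ] <- c(xs[best[2]] + sub[1], ys[best[1]] + sub[2])
    prev <- out[i, ]
  }
  out
}
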