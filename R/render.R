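# Frame renderer: places the textured iris disks (gaze in deg times
# px_per_degree, sub-pixel bilinear placement), applies the per-frame head
# similarity to the whole scene, adds Gaussian sensor noise, and returns
# ground-truth masks and an event log. Each pixel is interpolated once:
# output pixels are inverse-mapped through the head transform into the
# canonical scene, and for iris pixels additionally through the gaze
# translation into texture coordinates.

# canonical background: skin-like low-frequency texture, bright sclera
# disks, four high-contrast stabilization patches; padded by `pad` px so
# head motion never drags an image border into the frame
render_background <- function(config, pad = 16) {
  w <- config$frame_width + 2 * pad
  h <- config$frame_height + 2 * pad
  with_seed(config$texture_seed + 101, {
    lowf <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = 6)
    bg <- pmin(pmax(168 + 10 * lowf / stats::sd(lowf), 120), 215)
    xs <- matrix(rep(seq_len(w), each = h), h) - pad
    ys <- matrix(rep(seq_len(h), times = w), h) - pad
    for (e in seq_len(config$n_eyes)) {
      ec <- config$eye_centers[e, ]
      rad <- sqrt((xs - ec[1])^2 + (ys - ec[2])^2)
      sr <- config$iris_radius + 12
      a <- pmin(pmax(sr - rad + 0.5, 0), 1)
      bg <- bg * (1 - a) + a * (228 + 3 * matrix(stats::rnorm(h * w), h, w))
    }
    for (p in seq_len(4)) {
      pc <- config$patch_centers[p, ]
      ps <- config$patch_content
      ptex <- matrix(stats::rnorm(ps^2), ps, ps)
      ptex <- EBImage::gblur(ptex, 1.1) - EBImage::gblur(ptex, 2.6)
      ptex <- 150 + 140 * ptex / stats::sd(ptex) * 0.5
      rows <- (pc[2] - ps / 2 + pad):(pc[2] + ps / 2 - 1 + pad)
      cols <- (pc[1] - ps / 2 + pad):(pc[1] + ps / 2 - 1 + pad)
      bg[rows, cols] <- pmin(pmax(ptex, 10), 245)
    }
    bg
  })
}

#' Render a synthetic eye video with ground truth
#'
#' @param config A [scene_config()].
#' @param trajectory A `gaze_trajectory` from [build_trajectory()].
#' @param head_motion List of per-frame [similarity_transform()]s (same
#'   length as the trajectory), or `NULL` for a static head.
#' @param seed Seed for the sensor noise.
#' @param noise Logical; add sensor noise (default `TRUE`).
#' @return A `ground_truth_scene`: `video` (an `iris_video`), `gaze`
#'   (deg, n x 2 x n_eyes), `head_transform` (list), `events` (data
#'   frame), plus the `config`. Ground-truth iris masks are materialised
#'   on demand with [scene_mask()].
#' @export
render_scene <- function(config, trajectory, head_motion = NULL, seed = 1,
                         noise = TRUE) {
  n <- dim(trajectory$gaze)[1]
  if (is.null(head_motion))
    head_motion <- replicate(n, similarity_transform(), simplify = FALSE)
  if (length(head_motion) != n)
    stopf("trajectory (%d frames) and head motion (%d) differ in length",
          n, length(head_motion))
  pad <- 16
  bg <- render_background(config, pad)
  tex <- generate_iris_texture(config)
  w <- config$frame_width; h <- config$frame_height
  r <- config$iris_radius
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    H <- head_motion[[i]]
    ident <- st_is_identity(H)
    if (ident) {
      frame <- bg[(pad + 1):(pad + h), (pad + 1):(pad + w)]
    } else {
      # conjugate by the pad shift so the padded background moves like H
      shp <- similarity_transform(tx = pad, ty = pad)
      Hp <- st_compose(shp, st_compose(H, st_inverse(shp)))
      wp <- warp_similarity(bg, Hp, bg = 168)
      frame <- wp[(pad + 1):(pad + h), (pad + 1):(pad + w)]
    }
    for (e in seq_len(config$n_eyes)) {
      g <- trajectory$gaze[i, , e]
      cen_can <- config$eye_centers[e, ] + g * config$px_per_degree
      cen_out <- st_apply(H, rbind(cen_can))[1, ]
      rr <- H$s * (r + 1.5)
      if (cen_out[1] - rr < 1 || cen_out[1] + rr > w ||
          cen_out[2] - rr < 1 || cen_out[2] + rr > h)
        stopf("eye %d rendered outside frame bounds at frame %d", e, i)
      cx0 <- floor(cen_out[1] - rr); cx1 <- ceiling(cen_out[1] + rr)
      cy0 <- floor(cen_out[2] - rr); cy1 <- ceiling(cen_out[2] + rr)
      bx <- rep(cx0:cx1, each = cy1 - cy0 + 1)
      by <- rep(cy0:cy1, times = cx1 - cx0 + 1)
      pc <- if (ident) cbind(bx, by) else st_apply(st_inverse(H), cbind(bx, by))
      dx <- pc[, 1] - cen_can[1]; dy <- pc[, 2] - cen_can[2]
      rad <- sqrt(dx^2 + dy^2)
      alpha <- pmin(pmax(r - rad + 0.5, 0), 1)
      if (config$eyelid_occlusion > 0) {
        lid_y <- config$eye_centers[e, 2] - r + config$eyelid_occlusion * 2 * r
        alpha[pc[, 2] < lid_y] <- 0
      }
      sel <- alpha > 0
      if (any(sel)) {
        tv <- bilinear_sample(tex, dx[sel] + r + 0.5, dy[sel] + r + 0.5, bg = 128)
        idx <- (bx[sel] - 1) * h + by[sel]
        frame[idx] <- frame[idx] * (1 - alpha[sel]) + tv * alpha[sel]
      }
    }
    if (noise && config$sensor_noise_sigma > 0) {
      frame <- frame + with_seed(derive_seed(seed, i),
                                 stats::rnorm(h * w, sd = config$sensor_noise_sigma))
    }
    # store as 8-bit immediately: a minute-long scene must not hold
    # double-precision frames
    frames[[i]] <- as.raw(pmin(pmax(round(frame), 0), 255))
  }
  video <- structure(list(data = frames, h = h, w = w, n = n, fps = config$fps),
                     class = "iris_video")
  structure(list(video = video,
                 gaze = trajectory$gaze, head_transform = head_motion,
                 events = trajectory$events, config = config,
                 trajectory = trajectory),
            class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf("ground_truth_scene: %d frames, %d eye(s), %d events\n",
              video_length(x$video), x$config$n_eyes, nrow(x$events)))
  invisible(x)
}

#' Ground-truth iris mask for one frame
#'
#' Materialises the binary iris mask (iris disk clipped by the eyelid)
#' for frame `i` and eye `eye`, aligned to the rendered frame (i.e. under
#' that frame's head transform).
#'
#' @param scene A `ground_truth_scene`.
#' @param i Frame index.
#' @param eye Eye index.
#' @param canonical Logical; if `TRUE` the mask is produced in canonical
#'   (head-stabilized) coordinates instead of rendered coordinates.
#' @return Binary matrix (0/1) of frame dimensions.
#' @export
scene_mask <- function(scene, i, eye = 1, canonical = FALSE) {
  config <- scene$config
  H <- if (canonical) similarity_transform() else scene$head_transform[[i]]
  w <- config$frame_width; h <- config$frame_height
  g <- scene$gaze[i, , eye]
  cen_can <- config$eye_centers[eye, ] + g * config$px_per_degree
  r <- config$iris_radius
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  pc <- if (st_is_identity(H)) cbind(xs, ys) else st_apply(st_inverse(H), cbind(xs, ys))
  inside <- (pc[, 1] - cen_can[1])^2 + (pc[, 2] - cen_can[2])^2 <= r^2
  if (config$eyelid_occlusion > 0) {
    lid_y <- config$eye_centers[eye, 2] - r + config$eyelid_occlusion * 2 * r
    inside <- inside & pc[, 2] >= lid_y
  }
  matrix(as.numeric(inside), h, w)
}

#' Static eye box in canonical coordinates
#'
#' Rectangle `c(x0, y0, w, h)` around one eye large enough to contain the
#' iris over a stated maximal gaze excursion.
#'
#' @param config A [scene_config()].
#' @param eye Eye index.
#' @param max_gaze_deg Maximal absolute gaze excursion to allow for (deg).
#' @param margin Extra margin in px.
#' @return Integer vector `c(x0, y0, w, h)`.
#' @export
eye_box <- function(config, eye = 1, max_gaze_deg = 1.3, margin = 8) {
  half <- ceiling(max_gaze_deg * config$px_per_degree + config$iris_radius + margin)
  ec <- round(config$eye_centers[eye, ])
  x0 <- max(1, ec[1] - half); y0 <- max(1, ec[2] - half)
  x1 <- min(config$frame_width, ec[1] + half)
  y1 <- min(config$frame_height, ec[2] + half)
  c(x0 = x0, y0 = y0, w = x1 - x0 + 1, h = y1 - y0 + 1)
}

#' Write the ground truth of a scene to plain-text artifacts
#'
#' Events as JSON; per-frame gaze (deg) and head-transform parameters as
#' CSV.
#'
#' @param scene A `ground_truth_scene`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev_path <- file.path(dir, "events.json")
  jsonlite::write_json(scene$events, ev_path, dataframe = "rows", digits = NA)
  n <- dim(scene$gaze)[1]
  tf <- t(vapply(scene$head_transform, st_params, numeric(4)))
  df <- data.frame(frame = seq_len(n))
  for (e in seq_len(scene$config$n_eyes)) {
    df[[sprintf("gaze_x_deg_eye%d", e)]] <- scene$gaze[, 1, e]
    df[[sprintf("gaze_y_deg_eye%d", e)]] <- scene$gaze[, 2, e]
  }
  df$head_s <- tf[, 1]; df$head_theta <- tf[, 2]
  df$head_tx <- tf[, 3]; df$head_ty <- tf[, 4]
  csv_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(df, csv_path, row.names = FALSE)
  invisible(c(ev_path, csv_path))
}
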