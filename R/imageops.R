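# Image conventions used throughout the package:
#  * a frame is a base R numeric matrix img[y, x] with grey values in [0, 255]
#  * pixel (row r, col c) has continuous centre coordinates (x = c, y = r), 1-based
#  * y grows downward, as in image coordinates

#' Bilinear sampling of an image at fractional coordinates
#'
#' @param img Numeric matrix `img[y, x]`.
#' @param x,y Numeric vectors of equal length, 1-based pixel-centre coordinates.
#' @param bg Value returned for samples outside the image.
#' @return Numeric vector of sampled values.
#' @export
bilinear_sample <- function(img, x, y, bg = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 <= w - 1 & y0 <= h - 1
  # clamp so index arithmetic stays in range; masked afterwards
  x0c <- pmin(pmax(x0, 1), w - 1); y0c <- pmin(pmax(y0, 1), h - 1)
  i00 <- (x0c - 1) * h + y0c
  v <- (img[i00]     * (1 - fx) + img[i00 + h]     * fx) * (1 - fy) +
       (img[i00 + 1] * (1 - fx) + img[i00 + h + 1] * fx) * fy
  v[!ok] <- bg
  v
}

#' Warp a frame by a similarity transform
#'
#' Inverse-maps every output pixel through `tf` and samples the input with
#' bilinear interpolation, i.e. image content moves forward by `tf`.
#'
#' @param img Numeric matrix.
#' @param tf A [similarity_transform()].
#' @param bg Background fill for pixels mapped from outside the input.
#' @return Warped matrix of the same dimensions.
#' @export
warp_similarity <- function(img, tf, bg = 0) {
  if (st_is_identity(tf)) return(img)
  # delegate to EBImage's C implementation; our matrices are [y, x], so
  # EBImage's first ("x") dimension is our y and the matrix is swapped
  s <- tf$s; ct <- cos(tf$theta); st <- sin(tf$theta)
  m <- rbind(c(s * ct, -s * st), c(s * st, s * ct), c(tf$ty, tf$tx))
  out <- EBImage::affine(img, m, filter = "bilinear", bg.col = bg,
                         antialias = FALSE)
  matrix(as.numeric(out), nrow(img), ncol(img))
}

# reference pure-R inverse-mapping warp (used as the interpolation oracle
# in tests and for sampling with padding offsets)
warp_similarity_ref <- function(img, tf, bg = 0) {
  if (st_is_identity(tf)) return(img)
  h <- nrow(img); w <- ncol(img)
  inv <- st_inverse(tf)
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  p <- st_apply(inv, cbind(xs, ys))
  matrix(bilinear_sample(img, p[, 1], p[, 2], bg = bg), h, w)
}

#' CLAHE-equalised grayscale representation of a frame
#'
#' Converts a frame to grayscale (standard luma weights when 3 channels are
#' given) and applies contrast-limited adaptive histogram equalisation.
#' Local contrast enhancement before feature extraction raises the number
#' of matchable iris keypoints on low-contrast recordings.
#'
#' @param frame Matrix `[y, x]` or array `[y, x, 3]` with values in [0, 255].
#' @param clip_limit CLAHE clip limit (default 2).
#' @param tiles Number of contextual tiles per dimension (default 8).
#' @return Equalised grayscale matrix in [0, 255], same spatial shape.
#' @export
clahe_gray <- function(frame, clip_limit = 2, tiles = 8) {
  if (length(dim(frame)) == 3) {
    frame <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
  }
  h <- nrow(frame); w <- ncol(frame)
  # pad to a tile multiple by edge replication (tile histograms require it)
  hp <- ceiling(h / tiles) * tiles; wp <- ceiling(w / tiles) * tiles
  img <- frame
  if (hp > h) img <- rbind(img, img[rep(h, hp - h), , drop = FALSE])
  if (wp > w) img <- cbind(img, img[, rep(w, wp - w), drop = FALSE])
  eq <- EBImage::clahe(img / 255, nx = tiles, ny = tiles, limit = clip_limit)
  m <- matrix(as.numeric(eq) * 255, hp, wp)[seq_len(h), seq_len(w)]
  pmin(pmax(m, 0), 255)
}

# ---- uint8 video container ---------------------------------------------

# quantise one frame to the 8-bit raw storage used by iris_video
frame_to_raw <- function(f) as.raw(pmin(pmax(round(f), 0), 255))

#' Create a video object from a list of frames
#'
#' Frames are stored as 8-bit raw vectors to keep minute-long sequences in
#' memory; [video_get()] returns any frame as a numeric matrix.
#'
#' @param frames List of numeric matrices in [0, 255] (all same shape).
#' @param fps Frames per second.
#' @return An object of class `iris_video`.
#' @export
video_from_frames <- function(frames, fps) {
  stopifnot(length(frames) > 0)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  data <- lapply(frames, function(f) {
    stopifnot(nrow(f) == h, ncol(f) == w)
    as.raw(pmin(pmax(round(f), 0), 255))
  })
  structure(list(data = data, h = h, w = w, n = length(frames), fps = fps),
            class = "iris_video")
}

#' Number of frames in a video
#' @param v An `iris_video`.
#' @return Integer frame count.
#' @export
video_length <- function(v) v$n

#' Extract one frame of a video as a numeric matrix
#' @param v An `iris_video`.
#' @param i Frame index (1-based).
#' @return Numeric matrix `[y, x]` in [0, 255].
#' @export
video_get <- function(v, i) matrix(as.integer(v$data[[i]]), v$h, v$w)

#' Replace one frame of a video
#' @param v An `iris_video`.
#' @param i Frame index.
#' @param frame Numeric matrix in [0, 255].
#' @return The modified video.
#' @export
video_set <- function(v, i, frame) {
  v$data[[i]] <- as.raw(pmin(pmax(round(frame), 0), 255))
  v
}

#' @export
print.iris_video <- function(x, ...) {
  cat(sprintf("iris_video: %d frames, %d x %d px, %g fps\n", x$n, x$w, x$h, x$fps))
  invisible(x)
}

#' Write a video as a numbered PNG stack
#' @param v An `iris_video`.
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return Invisibly, the file paths written.
#' @export
write_frames <- function(v, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("%s_%06d.png", prefix, seq_len(v$n)))
  for (i in seq_len(v$n)) png::writePNG(video_get(v, i) / 255, paths[i])
  invisible(paths)
}

#' Read a PNG stack back into a video
#' @param dir Directory holding the stack.
#' @param fps Frame rate to attach.
#' @param pattern Regular expression selecting the files.
#' @return An `iris_video`.
#' @export
read_frames <- function(dir, fps, pattern = "\\.png$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stopf("no PNG frames found in %s", dir)
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * 255
  })
  video_from_frames(frames, fps)
}
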