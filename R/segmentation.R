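# Iris segmentation toolkit: label construction (least-squares ellipse fit
# on clicked boundary points, eyelid clipping by second-degree polynomials),
# the IoU metric, and a classical intensity/edge fallback segmenter for
# CNN-free pipeline runs on synthetic scenes.

#' Direct least-squares ellipse fit
#'
#' Algebraic conic fit constrained to an ellipse (Fitzgibbon-style
#' generalised eigenproblem), suited to the six to ten clicked iris-border
#' points used for label construction.
#'
#' @param points n x 2 matrix of (x, y) points, n >= 5, not collinear.
#' @return List of class `ellipse_params`: `center` (x, y), `a` (semi-
#'   major), `b` (semi-minor), `angle` (rad, of the major axis).
#' @export
fit_ellipse_lsq <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 5) stopf("ellipse fit needs >= 5 points, got %d", nrow(points))
  x <- points[, 1]; y <- points[, 2]
  # centre/scale for conditioning
  mx <- mean(x); my <- mean(y)
  sc <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(sc) || sc < 1e-12) stopf("degenerate point set")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T3 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stopf("ellipse fit failed: points are collinear or degenerate"))
  M <- S1 + S2 %*% T3
  # premultiply by inv(C), C = [[0,0,2],[0,-1,0],[2,0,0]]
  M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M2)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) stopf("no ellipse solution; points may be collinear")
  a1 <- V[, ok[1]]
  coef <- c(a1, as.numeric(T3 %*% a1))
  # undo normalisation: conic in original coordinates
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4] * sc - 2 * A * mx - B * my
  E <- coef[5] * sc - 2 * C * my - B * mx
  F <- coef[6] * sc^2 + A * mx^2 + B * mx * my + C * my^2 - coef[4] * sc * mx -
       coef[5] * sc * my
  conic_to_ellipse(c(A, B, C, D, E, F))
}

conic_to_ellipse <- function(co) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stopf("conic is not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  root <- sqrt((A - C)^2 + B^2)
  aa <- -sqrt(num * (A + C + root)) / den
  bb <- -sqrt(num * (A + C - root)) / den
  ang <- atan2(-B, C - A) / 2
  if (!is.finite(aa) || !is.finite(bb)) stopf("degenerate ellipse fit")
  if (bb > aa) { tmp <- aa; aa <- bb; bb <- tmp; ang <- ang + pi / 2 }
  ang <- atan2(sin(ang), cos(ang))
  structure(list(center = c(x = x0, y = y0), a = aa, b = bb, angle = ang),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("ellipse: center (%.4g, %.4g), a %.4g, b %.4g, angle %.4g rad\n",
              x$center[1], x$center[2], x$a, x$b, x$angle))
  invisible(x)
}

# quadratic y = f(x) through >= 3 points
fit_quadratic <- function(pts) {
  pts <- rbind(pts)
  if (nrow(pts) < 3) stopf("eyelid fit needs >= 3 points, got %d", nrow(pts))
  stats::lm(pts[, 2] ~ poly(pts[, 1], 2, raw = TRUE))
}

#' Rasterise an ellipse interior clipped by eyelid quadratics
#'
#' The final label mask: the ellipse interior intersected with the region
#' below the upper-lid quadratic and above the lower-lid quadratic (image
#' coordinates, y grows downward). Either lid is optional. Clipping never
#' increases the mask area relative to the bare ellipse.
#'
#' @param ellipse An `ellipse_params`.
#' @param upper_pts,lower_pts Optional n x 2 point matrices (n >= 3 each)
#'   on the upper/lower eyelid borders.
#' @param dim Mask dimensions `c(height, width)`.
#' @return Binary matrix (0/1) of size `dim`.
#' @export
clip_eyelids <- function(ellipse, upper_pts = NULL, lower_pts = NULL,
                         dim = c(224, 224)) {
  h <- dim[1]; w <- dim[2]
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  ct <- cos(ellipse$angle); st <- sin(ellipse$angle)
  dx <- xs - ellipse$center[1]; dy <- ys - ellipse$center[2]
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  inside <- (u / ellipse$a)^2 + (v / ellipse$b)^2 <= 1
  if (!is.null(upper_pts)) {
    f <- fit_quadratic(upper_pts)
    lid <- cbind(1, xs, xs^2) %*% stats::coef(f)
    inside <- inside & (ys >= lid)
  }
  if (!is.null(lower_pts)) {
    f <- fit_quadratic(lower_pts)
    lid <- cbind(1, xs, xs^2) %*% stats::coef(f)
    inside <- inside & (ys <= lid)
  }
  matrix(as.numeric(inside), h, w)
}

#' Intersection over union of two binary masks
#'
#' @param pred,truth Binary matrices of equal shape.
#' @return IoU in [0, 1]; defined as 1 when both masks are empty.
#' @export
iou <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stopf("mask shapes differ")
  p <- pred > 0; g <- truth > 0
  u <- sum(p | g)
  if (u == 0) return(1)
  sum(p & g) / u
}

#' Classical fallback iris segmenter
#'
#' CNN-free segmentation for synthetic scenes and tests: locates the dark
#' pupil by intensity thresholding inside the approximate eye box, then
#' finds the iris radius as the strongest outward intensity step of the
#' angular-mean radial profile (iris texture to bright sclera). Documented
#' as a test/pipeline utility for rendered scenes, not a general-purpose
#' segmenter.
#'
#' @param frame Grayscale frame matrix.
#' @param box Approximate eye box `c(x0, y0, w, h)` containing one eye.
#' @param pupil_threshold Grey level below which pixels count as pupil
#'   (default 70).
#' @return Binary full-frame mask; empty (all zero) with a warning when no
#'   iris annulus is found.
#' @export
fallback_segment <- function(frame, box, pupil_threshold = 70) {
  rows <- box[2]:(box[2] + box[4] - 1)
  cols <- box[1]:(box[1] + box[3] - 1)
  crop <- frame[rows, cols]
  dark <- which(crop < pupil_threshold, arr.ind = TRUE)
  empty <- matrix(0, nrow(frame), ncol(frame))
  if (nrow(dark) < 10) {
    warnf("fallback segmenter: no pupil found in the eye box")
    return(empty)
  }
  cy <- stats::median(dark[, 1]); cx <- stats::median(dark[, 2])
  rmax <- floor(min(cx - 1, cy - 1, ncol(crop) - cx, nrow(crop) - cy))
  # search outside the pupil (radius from the dark-pixel area), so the
  # pupil-iris step cannot masquerade as the iris-sclera boundary
  r_pupil <- sqrt(nrow(dark) / pi)
  radii <- seq(ceiling(r_pupil) + 3, rmax, by = 1)
  if (length(radii) < 4) {
    warnf("fallback segmenter: eye box too small around the pupil")
    return(empty)
  }
  ang <- seq(0, 2 * pi, length.out = 49)[-49]
  # one gather for the whole polar grid (radii x angles)
  px <- outer(radii, cos(ang)); py <- outer(radii, sin(ang))
  vals <- bilinear_sample(crop, cx + px, cy + py, bg = NA)
  prof <- rowMeans(matrix(vals, length(radii)))
  # outward step of the radial profile = iris/sclera boundary
  dr <- diff(prof)
  cand <- seq_along(dr)
  if (!length(cand) || max(dr[cand], na.rm = TRUE) < 5) {
    warnf("fallback segmenter: no iris annulus found")
    return(empty)
  }
  # the boundary response is spread over ~2 px; take the centroid of the
  # step region around the strongest gradient
  pk <- cand[which.max(dr[cand])]
  w0 <- max(1, pk - 2):min(length(dr), pk + 2)
  r_edge <- sum((radii[-1][w0] - 0.5) * pmax(dr[w0], 0)) / sum(pmax(dr[w0], 0))
  xs <- rep(seq_len(ncol(frame)), each = nrow(frame))
  ys <- rep(seq_len(nrow(frame)), times = ncol(frame))
  cx_full <- cx + box[1] - 1; cy_full <- cy + box[2] - 1
  inside <- (xs - cx_full)^2 + (ys - cy_full)^2 <= r_edge^2
  matrix(as.numeric(inside), nrow(frame), ncol(frame))
}
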