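# Local feature pipeline: single-scale DoG blob detection, contrast-normalised
# intensity-patch descriptors, brute-force L2 matching with Lowe's ratio test,
# RANSAC outlier removal under a locally-translational motion model, and
# sub-pixel refinement of matched displacements. Only displacement statistics
# are consumed downstream, so the detector is interchangeable by design.

#' Feature detector / matcher configuration
#'
#' @param sigma Base Gaussian scale of the difference-of-Gaussians detector.
#' @param k Scale ratio between the two Gaussians.
#' @param response_threshold Minimum absolute DoG response at a keypoint.
#' @param max_keypoints Keep at most this many strongest keypoints.
#' @param border Pixels to exclude at the image border (must cover the
#'   descriptor patch radius).
#' @param patch Descriptor patch side (odd).
#' @param lowe_ratio Lowe ratio-test threshold (best / second-best L2).
#' @param ransac_tol RANSAC inlier radius in px for the translation model.
#' @param ransac_iters Number of RANSAC hypotheses.
#' @param min_matches Minimum surviving inliers for a confident match set.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(sigma = 1.4, k = 1.7, response_threshold = 2,
                           max_keypoints = 250, border = 7, patch = 9,
                           lowe_ratio = 0.75, ransac_tol = 1.5,
                           ransac_iters = 64, min_matches = 3) {
  stopifnot(patch %% 2 == 1, border >= (patch - 1) / 2)
  structure(list(sigma = sigma, k = k, response_threshold = response_threshold,
                 max_keypoints = max_keypoints, border = border, patch = patch,
                 lowe_ratio = lowe_ratio, ransac_tol = ransac_tol,
                 ransac_iters = ransac_iters, min_matches = min_matches),
            class = "feature_config")
}

#' Separable Gaussian blur with edge replication
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian sigma in px.
#' @return Blurred matrix of the same shape.
#' @keywords internal
gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  # vertical pass (shift-and-add over the padded rows)
  mp <- rbind(img[rep(1, r), , drop = FALSE], img,
              img[rep(h, r), , drop = FALSE])
  acc <- k[1] * mp[1:h, , drop = FALSE]
  for (j in 2:(2 * r + 1)) acc <- acc + k[j] * mp[j:(j + h - 1), , drop = FALSE]
  # horizontal pass
  ap <- cbind(acc[, rep(1, r), drop = FALSE], acc,
              acc[, rep(w, r), drop = FALSE])
  out <- k[1] * ap[, 1:w, drop = FALSE]
  for (j in 2:(2 * r + 1)) out <- out + k[j] * ap[, j:(j + w - 1), drop = FALSE]
  out
}

#' Detect blob keypoints with a difference-of-Gaussians filter
#'
#' @param img Grayscale matrix in [0, 255].
#' @param config A [feature_config()].
#' @param mask Optional logical/0-1 matrix; keypoints restricted to TRUE pixels.
#' @return Data frame with columns `x`, `y` (integer px) and `response`.
#' @export
detect_keypoints <- function(img, config = feature_config(), mask = NULL) {
  h <- nrow(img); w <- ncol(img)
  dog <- gauss_blur(img, config$sigma) -
         gauss_blur(img, config$sigma * config$k)
  r <- abs(dog)
  # strict 8-neighbour local maxima, computed by shifted comparisons
  core <- r[2:(h - 1), 2:(w - 1)]
  ismax <- core > r[1:(h - 2), 2:(w - 1)] & core >= r[3:h, 2:(w - 1)] &
           core > r[2:(h - 1), 1:(w - 2)] & core >= r[2:(h - 1), 3:w] &
           core > r[1:(h - 2), 1:(w - 2)] & core >= r[3:h, 3:w] &
           core > r[3:h, 1:(w - 2)]      & core >= r[1:(h - 2), 3:w] &
           core > config$response_threshold
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  ys <- idx[, 1] + 1L; xs <- idx[, 2] + 1L
  b <- config$border
  keep <- xs > b & xs <= w - b & ys > b & ys <= h - b
  if (!is.null(mask)) keep <- keep & (mask[cbind(ys, xs)] > 0)
  xs <- xs[keep]; ys <- ys[keep]
  resp <- core[idx][keep]
  if (length(xs) > config$max_keypoints) {
    o <- order(resp, decreasing = TRUE)[seq_len(config$max_keypoints)]
    xs <- xs[o]; ys <- ys[o]; resp <- resp[o]
  }
  data.frame(x = xs, y = ys, response = resp)
}

# gather normalised patch descriptors around integer keypoints;
# returns an n x patch^2 matrix (zero-mean, unit-L2 rows)
extract_descriptors <- function(img, kp, patch = 9) {
  if (nrow(kp) == 0) return(matrix(0, 0, patch^2))
  h <- nrow(img)
  r <- (patch - 1) / 2
  off <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
  base <- (kp$x - 1) * h + kp$y
  idx <- outer(base, off[, "dx"] * h + off[, "dy"], `+`)
  d <- matrix(img[idx], nrow = nrow(kp))
  d <- d - rowMeans(d)
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm < 1e-9] <- 1
  d / nrm
}

# brute-force L2 matching with Lowe's ratio test; returns index pairs
match_descriptors <- function(d1, d2, lowe_ratio = 0.75) {
  n1 <- nrow(d1); n2 <- nrow(d2)
  if (n1 == 0 || n2 < 2)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  # squared L2 distance via the inner-product expansion
  dist2 <- matrix(rowSums(d1^2), n1, n2) +
           matrix(rowSums(d2^2), n1, n2, byrow = TRUE) -
           2 * tcrossprod(d1, d2)
  dist2[dist2 < 0] <- 0
  best <- max.col(-dist2, ties.method = "first")
  bd <- dist2[cbind(seq_len(n1), best)]
  dist2[cbind(seq_len(n1), best)] <- Inf
  second <- dist2[cbind(seq_len(n1), max.col(-dist2, ties.method = "first"))]
  keep <- sqrt(bd) < lowe_ratio * sqrt(second)
  data.frame(i = which(keep), j = best[keep], dist = sqrt(bd[keep]))
}

# RANSAC with a 2-D translation motion model (the per-patch motion is locally
# translational); returns logical inlier vector
ransac_translation <- function(src, dst, tol = 1.5, iters = 64, seed = 1) {
  n <- nrow(src)
  if (n == 0) return(logical(0))
  shifts <- dst - src
  with_seed(seed, {
    best <- logical(n); best_n <- 0
    cand <- sample.int(n, min(iters, n), replace = iters > n)
    for (k in cand) {
      d2 <- (shifts[, 1] - shifts[k, 1])^2 + (shifts[, 2] - shifts[k, 2])^2
      inl <- d2 <= tol^2
      if (sum(inl) > best_n) { best <- inl; best_n <- sum(inl) }
    }
    # one consensus re-fit around the inlier mean shift
    if (best_n > 0) {
      mu <- colMeans(shifts[best, , drop = FALSE])
      d2 <- (shifts[, 1] - mu[1])^2 + (shifts[, 2] - mu[2])^2
      best <- d2 <= tol^2
    }
    best
  })
}

# refine matched destination locations to sub-pixel accuracy with a few
# Lucas-Kanade (inverse-compositional) translation updates: the source
# patch is the template, its gradients give the normal equations, and the
# destination patch is resampled bilinearly at each iterate. The update is
# clamped to +-1 px around the integer match.
refine_matches <- function(img1, img2, src, dst, patch = 9, iters = 3) {
  n <- nrow(src)
  if (n == 0) return(dst)
  h1 <- nrow(img1)
  ri <- (patch - 1) / 2 - 1   # inner window so template gradients exist
  off <- as.matrix(expand.grid(dy = -ri:ri, dx = -ri:ri))
  lin <- function(x, y) outer((x - 1) * h1 + y, off[, "dx"] * h1 + off[, "dy"], `+`)
  P1 <- matrix(img1[lin(src[, 1], src[, 2])], n)
  gx <- (matrix(img1[lin(src[, 1] + 1, src[, 2])], n) -
         matrix(img1[lin(src[, 1] - 1, src[, 2])], n)) / 2
  gy <- (matrix(img1[lin(src[, 1], src[, 2] + 1)], n) -
         matrix(img1[lin(src[, 1], src[, 2] - 1)], n)) / 2
  a11 <- rowSums(gx * gx); a12 <- rowSums(gx * gy); a22 <- rowSums(gy * gy)
  det <- a11 * a22 - a12^2
  det[det < 1e-9] <- Inf
  d <- dst
  for (k in seq_len(iters)) {
    cx <- outer(d[, 1], off[, "dx"], `+`)
    cy <- outer(d[, 2], off[, "dy"], `+`)
    P2 <- matrix(bilinear_sample(img2, as.numeric(cx), as.numeric(cy), bg = NA), n)
    e <- P2 - P1
    e[is.na(e)] <- 0
    bx <- rowSums(gx * e); by <- rowSums(gy * e)
    d <- cbind(d[, 1] - (a22 * bx - a12 * by) / det,
               d[, 2] - (a11 * by - a12 * bx) / det)
  }
  cbind(pmin(pmax(d[, 1], dst[, 1] - 1), dst[, 1] + 1),
        pmin(pmax(d[, 2], dst[, 2] - 1), dst[, 2] + 1))
}

#' Match features between two images
#'
#' Full matching pipeline: keypoint detection in both images, descriptor
#' extraction, brute-force L2 matching with Lowe's ratio test, RANSAC
#' outlier removal, and sub-pixel refinement of destination locations.
#'
#' @param img1,img2 Grayscale matrices (same scene, consecutive frames).
#' @param config A [feature_config()].
#' @param mask Optional mask restricting keypoints in `img1`.
#' @param kp1,kp2 Optional precomputed keypoint/descriptor sets as returned
#'   by [prepare_keypoints()] (used to avoid re-detection in frame loops).
#' @param seed RANSAC seed.
#' @return A `match_set`: list with matrices `src`, `dst` (n x 2, sub-pixel),
#'   vector `dist`, inlier count `n`, and logical `ok` (low-confidence flag
#'   is `!ok`).
#' @export
match_features <- function(img1, img2, config = feature_config(), mask = NULL,
                           kp1 = NULL, kp2 = NULL, seed = 1) {
  if (is.null(kp1)) kp1 <- prepare_keypoints(img1, config, mask)
  if (is.null(kp2)) kp2 <- prepare_keypoints(img2, config)
  m <- match_descriptors(kp1$desc, kp2$desc, config$lowe_ratio)
  empty <- function() structure(list(src = matrix(0, 0, 2), dst = matrix(0, 0, 2),
                                     dist = numeric(0), n = 0L, ok = FALSE),
                                class = "match_set")
  if (nrow(m) < config$min_matches) return(empty())
  src <- cbind(kp1$kp$x[m$i], kp1$kp$y[m$i])
  dst <- cbind(kp2$kp$x[m$j], kp2$kp$y[m$j])
  inl <- ransac_translation(src, dst, config$ransac_tol, config$ransac_iters, seed)
  if (sum(inl) < config$min_matches) return(empty())
  src <- src[inl, , drop = FALSE]; dst <- dst[inl, , drop = FALSE]
  dst <- refine_matches(img1, img2, src, dst, config$patch)
  structure(list(src = src, dst = dst, dist = m$dist[inl], n = sum(inl), ok = TRUE),
            class = "match_set")
}

#' Detect keypoints and extract their descriptors in one pass
#'
#' @inheritParams detect_keypoints
#' @return List with elements `kp` (data frame) and `desc` (matrix).
#' @export
prepare_keypoints <- function(img, config = feature_config(), mask = NULL) {
  kp <- detect_keypoints(img, config, mask)
  list(kp = kp, desc = extract_descriptors(img, kp, config$patch))
}

#' Geometric median of a 2-D point set
#'
#' The point minimising the summed Euclidean distances to the set — the
#' robust central estimate used both for per-patch correspondences in head
#' stabilization and for the per-frame iris shift. Computed by Weiszfeld
#' iteration with a perturbation restart whenever an iterate lands on a
#' data point.
#'
#' @param pts n x 2 matrix of points, n >= 1.
#' @param tol Convergence tolerance in px (default 1e-7).
#' @param max_iter Maximum iterations (default 200).
#' @return Length-2 numeric vector (x, y).
#' @export
geometric_median <- function(pts, tol = 1e-7, max_iter = 200) {
  pts <- rbind(pts)
  n <- nrow(pts)
  if (n == 0) stopf("geometric median of an empty point set")
  if (n == 1) return(as.numeric(pts[1, ]))
  x <- colMeans(pts)
  for (it in seq_len(max_iter)) {
    d <- sqrt((pts[, 1] - x[1])^2 + (pts[, 2] - x[2])^2)
    on_pt <- d < 1e-12
    if (any(on_pt)) {
      # perturb off the coincident data point and continue
      x <- x + c(tol * 10 + 1e-6, -(tol * 10 + 1e-6))
      d <- sqrt((pts[, 1] - x[1])^2 + (pts[, 2] - x[2])^2)
    }
    wts <- 1 / d
    xn <- c(sum(pts[, 1] * wts), sum(pts[, 2] * wts)) / sum(wts)
    if (sqrt(sum((xn - x)^2)) < tol) return(xn)
    x <- xn
  }
  x
}

#' Geometric-median correspondence of a match set
#'
#' Collapses a patch's matches into a single robust correspondence: the
#' geometric median of the source points paired with the geometric median
#' of the destination points (computed independently).
#'
#' @param matches A `match_set` from [match_features()].
#' @return List with `src` and `dst`, each a length-2 (x, y) vector.
#' @export
patch_correspondence <- function(matches) {
  if (is.null(matches$src) || nrow(matches$src) == 0)
    stopf("empty match set has no correspondence")
  list(src = geometric_median(matches$src), dst = geometric_median(matches$dst))
}
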