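#' Planar similarity transform
#'
#' A 4-DOF planar map acting on points as `p' = s * R(theta) %*% p + t`.
#' This is the unit of head-motion compensation: uniform scale, rotation
#' and translation, deliberately more constrained than affine or
#' homography maps whose extra degrees of freedom accumulate skew.
#'
#' @param s Uniform scale, must be positive.
#' @param theta Rotation angle in radians (counter-clockwise in x-right,
#'   y-down image coordinates).
#' @param tx,ty Translation in pixels.
#' @return An object of class `similarity_transform`.
#' @examples
#' tf <- similarity_transform(1.05, 0.1, 3, -2)
#' st_apply(st_compose(st_inverse(tf), tf), cbind(5, 7))  # identity
#' @export
similarity_transform <- function(s = 1, theta = 0, tx = 0, ty = 0) {
  if (!is.finite(s) || s <= 0) stopf("similarity scale must be positive, got %g", s)
  structure(list(s = unname(s), theta = unname(theta),
                 tx = unname(tx), ty = unname(ty)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: s = %.6g, theta = %.6g rad, t = (%.6g, %.6g)\n",
              x$s, x$theta, x$tx, x$ty))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param tf A `similarity_transform`.
#' @param pts Numeric n x 2 matrix of (x, y) points.
#' @return Transformed n x 2 matrix.
#' @export
st_apply <- function(tf, pts) {
  pts <- rbind(pts)  # accept a bare length-2 vector
  ct <- cos(tf$theta); st <- sin(tf$theta)
  x <- tf$s * (ct * pts[, 1] - st * pts[, 2]) + tf$tx
  y <- tf$s * (st * pts[, 1] + ct * pts[, 2]) + tf$ty
  cbind(x, y, deparse.level = 0)
}

#' Compose two similarity transforms
#'
#' `st_compose(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`.
#'
#' @param a,b `similarity_transform` objects.
#' @return A `similarity_transform`.
#' @export
st_compose <- function(a, b) {
  ct <- cos(a$theta); st <- sin(a$theta)
  similarity_transform(
    s = a$s * b$s,
    theta = a$theta + b$theta,
    tx = a$s * (ct * b$tx - st * b$ty) + a$tx,
    ty = a$s * (st * b$tx + ct * b$ty) + a$ty
  )
}

#' Invert a similarity transform
#'
#' @param tf A `similarity_transform`.
#' @return The inverse transform.
#' @export
st_inverse <- function(tf) {
  ct <- cos(-tf$theta); st <- sin(-tf$theta)
  si <- 1 / tf$s
  similarity_transform(
    s = si, theta = -tf$theta,
    tx = -si * (ct * tf$tx - st * tf$ty),
    ty = -si * (st * tf$tx + ct * tf$ty)
  )
}

#' Parameters of a similarity transform as a named vector
#' @param tf A `similarity_transform`.
#' @return Named numeric vector `c(s, theta, tx, ty)`.
#' @export
st_params <- function(tf) c(s = tf$s, theta = tf$theta, tx = tf$tx, ty = tf$ty)

st_is_identity <- function(tf, tol = 1e-12) {
  abs(tf$s - 1) < tol && abs(tf$theta) < tol && abs(tf$tx) < tol && abs(tf$ty) < tol
}

#' Least-squares similarity transform from point correspondences
#'
#' Closed-form 4-DOF Procrustes fit: given source points and their images,
#' finds scale, rotation and translation minimising the summed squared
#' residual. Exact when the correspondences are generated by a true
#' similarity. Two non-coincident pairs suffice.
#'
#' @param src,dst n x 2 matrices of corresponding (x, y) points, n >= 2.
#' @return A `similarity_transform` mapping `src` onto `dst`.
#' @export
estimate_similarity <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) < 2 || nrow(src) != nrow(dst))
    stopf("need >= 2 correspondences with equal counts (got %d, %d)",
          nrow(src), nrow(dst))
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  xs <- sweep(src, 2, mu_s); xd <- sweep(dst, 2, mu_d)
  var_s <- sum(xs^2)
  if (var_s < 1e-12) stopf("all source points coincident; similarity underdetermined")
  # complex-number formulation of the 2-D Procrustes problem
  zs <- complex(real = xs[, 1], imaginary = xs[, 2])
  zd <- complex(real = xd[, 1], imaginary = xd[, 2])
  a <- sum(Conj(zs) * zd) / var_s
  s <- Mod(a); theta <- Arg(a)
  ct <- cos(theta); st <- sin(theta)
  t <- mu_d - s * c(ct * mu_s[1] - st * mu_s[2], st * mu_s[1] + ct * mu_s[2])
  similarity_transform(s = s, theta = theta, tx = t[1], ty = t[2])
}
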