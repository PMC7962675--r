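# Independent oracles used across the suite.

# exact TVD via the dual: min_z ||y - D'z||^2 s.t. |z| <= lambda, solved
# with a generic box-constrained convex optimiser; x* = y - D'z*
tvd_qp_oracle <- function(y, lambda) {
  n <- length(y)
  D <- diff(diag(n))
  obj <- function(z) { r <- y - as.numeric(crossprod(D, z)); 0.5 * sum(r^2) }
  gr <- function(z) { r <- y - as.numeric(crossprod(D, z)); -as.numeric(D %*% r) }
  o <- stats::optim(rep(0, n - 1), obj, gr, method = "L-BFGS-B",
                    lower = -lambda, upper = lambda,
                    control = list(maxit = 5000, factr = 1e1))
  y - as.numeric(crossprod(D, o$par))
}

# brute-force geometric median by grid search with refinement
gm_grid_oracle <- function(pts, res = 0.01, pad = 1) {
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  step <- max((hi - lo) / 60)
  best <- colMeans(pts)
  repeat {
    gx <- seq(best[1] - 30 * step, best[1] + 30 * step, by = step)
    gy <- seq(best[2] - 30 * step, best[2] + 30 * step, by = step)
    g <- expand.grid(x = gx, y = gy)
    v <- rowSums(sapply(seq_len(nrow(pts)), function(i)
      sqrt((g$x - pts[i, 1])^2 + (g$y - pts[i, 2])^2)))
    best <- as.numeric(g[which.min(v), ])
    if (step <= res / 2) return(best)
    step <- step / 5
  }
}
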