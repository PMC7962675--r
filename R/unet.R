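# U-Net iris segmenter, implemented natively in R. Activations are stored
# as [H, W, N, C] arrays so a 3x3 convolution decomposes into nine
# offset-slice matrix multiplications (no im2col buffers). The contracting
# path is blocks of two (3x3 conv -> batch norm -> ReLU) followed by 2x2
# max pooling; the expanding path upsamples by a factor of two, concatenates
# the skip feature map, and applies two conv blocks; a final 1x1 convolution
# maps to the two class score maps. Trained with pixel-wise softmax cross
# entropy and Adam.

#' U-Net configuration
#'
#' Defaults follow the reference training recipe (224x224 RGB input, two
#' output classes, Adam with learning rate 1e-4, first/second moment decay
#' 0.55/0.99, batch size 8, 40 epochs). Depth and channel width are
#' exposed because reduced nets are appropriate for small synthetic
#' training sets.
#'
#' @param input_size Square input side; must be divisible by `2^depth`.
#' @param in_channels Input channels (3: R, G, B).
#' @param out_classes Output classes (2: iris, non-iris).
#' @param depth Number of contracting/expanding stages (default 4).
#' @param base_channels Channels of the first stage (default 64).
#' @param lr Adam learning rate (default 1e-4).
#' @param beta1,beta2 Adam moment decay rates (default 0.55, 0.99).
#' @param batch_size Samples per batch (default 8).
#' @param epochs Training epochs (default 40).
#' @param augment Horizontal-flip augmentation (default `TRUE`).
#' @return List of class `unet_config`.
#' @export
unet_config <- function(input_size = 224, in_channels = 3, out_classes = 2,
                        depth = 4, base_channels = 64, lr = 1e-4,
                        beta1 = 0.55, beta2 = 0.99, batch_size = 8,
                        epochs = 40, augment = TRUE) {
  if (input_size %% 2^depth != 0)
    stopf("input_size (%d) must be divisible by 2^depth (%d)", input_size, 2^depth)
  structure(list(input_size = input_size, in_channels = in_channels,
                 out_classes = out_classes, depth = depth,
                 base_channels = base_channels, lr = lr, beta1 = beta1,
                 beta2 = beta2, batch_size = batch_size, epochs = epochs,
                 augment = augment),
            class = "unet_config")
}

# ---- layer primitives ([H, W, N, C] activations) -----------------------

conv_init <- function(cin, cout, k = 3) {
  # He-normal initialisation
  list(W = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

bn_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                            run_mean = rep(0, c), run_var = rep(1, c))

conv_fwd <- function(X, par) {
  d <- dim(X); H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  k <- dim(par$W)[1]; Cout <- dim(par$W)[4]; p <- (k - 1) / 2
  Xp <- array(0, c(H + 2 * p, W + 2 * p, N, Cin))
  Xp[p + (1:H), p + (1:W), , ] <- X
  Ym <- matrix(rep(par$b, each = H * W * N), H * W * N, Cout)
  for (ki in 1:k) for (kj in 1:k) {
    Xs <- Xp[ki:(ki + H - 1), kj:(kj + W - 1), , , drop = FALSE]
    Ym <- Ym + matrix(Xs, H * W * N, Cin) %*% matrix(par$W[ki, kj, , ], Cin, Cout)
  }
  list(Y = array(Ym, c(H, W, N, Cout)), Xp = Xp)
}

conv_bwd <- function(dY, cache, par) {
  d <- dim(dY); H <- d[1]; W <- d[2]; N <- d[3]; Cout <- d[4]
  k <- dim(par$W)[1]; Cin <- dim(par$W)[3]; p <- (k - 1) / 2
  dYm <- matrix(dY, H * W * N, Cout)
  dW <- array(0, dim(par$W))
  dXp <- array(0, dim(cache$Xp))
  for (ki in 1:k) for (kj in 1:k) {
    Xs <- cache$Xp[ki:(ki + H - 1), kj:(kj + W - 1), , , drop = FALSE]
    dW[ki, kj, , ] <- crossprod(matrix(Xs, H * W * N, Cin), dYm)
    dXs <- dYm %*% t(matrix(par$W[ki, kj, , ], Cin, Cout))
    dXp[ki:(ki + H - 1), kj:(kj + W - 1), , ] <-
      dXp[ki:(ki + H - 1), kj:(kj + W - 1), , , drop = FALSE] +
      array(dXs, c(H, W, N, Cin))
  }
  list(dX = dXp[p + (1:H), p + (1:W), , , drop = FALSE],
       grads = list(W = dW, b = colSums(dYm)))
}

bn_fwd <- function(X, par, train = TRUE, momentum = 0.9, eps = 1e-5) {
  d <- dim(X); C <- d[4]; m <- prod(d[1:3])
  Xm <- matrix(X, m, C)
  if (train) {
    mu <- colMeans(Xm)
    va <- colMeans(sweep(Xm, 2, mu)^2)
    par$run_mean <- momentum * par$run_mean + (1 - momentum) * mu
    par$run_var <- momentum * par$run_var + (1 - momentum) * va
  } else {
    mu <- par$run_mean; va <- par$run_var
  }
  xhat <- sweep(sweep(Xm, 2, mu), 2, sqrt(va + eps), "/")
  Y <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  list(Y = array(Y, d), xhat = xhat, va = va, par = par, eps = eps)
}

bn_bwd <- function(dY, cache, par) {
  d <- dim(dY); C <- d[4]; m <- prod(d[1:3])
  dYm <- matrix(dY, m, C)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, par$gamma, "*")
  inv_sd <- 1 / sqrt(cache$va + cache$eps)
  dX <- sweep(dxhat - matrix(colMeans(dxhat), m, C, byrow = TRUE) -
              cache$xhat * matrix(colMeans(dxhat * cache$xhat), m, C, byrow = TRUE),
              2, inv_sd, "*")
  list(dX = array(dX, d), grads = list(gamma = dgamma, beta = dbeta))
}

relu_fwd <- function(X) list(Y = pmax(X, 0), mask = X > 0)
relu_bwd <- function(dY, cache) dY * cache$mask

pool_fwd <- function(X) {
  d <- dim(X); H <- d[1]; W <- d[2]
  i1 <- seq(1, H, 2); i2 <- seq(2, H, 2); j1 <- seq(1, W, 2); j2 <- seq(2, W, 2)
  s <- list(X[i1, j1, , , drop = FALSE], X[i2, j1, , , drop = FALSE],
            X[i1, j2, , , drop = FALSE], X[i2, j2, , , drop = FALSE])
  Y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(Y = Y, which = lapply(s, function(z) z == Y), dim_in = d)
}

pool_bwd <- function(dY, cache) {
  d <- cache$dim_in
  dX <- array(0, d)
  i1 <- seq(1, d[1], 2); i2 <- seq(2, d[1], 2)
  j1 <- seq(1, d[2], 2); j2 <- seq(2, d[2], 2)
  # first-max routing so ties do not double-count
  taken <- array(FALSE, dim(dY))
  route <- function(wsel) { sel <- wsel & !taken; taken <<- taken | wsel; dY * sel }
  dX[i1, j1, , ] <- route(cache$which[[1]])
  dX[i2, j1, , ] <- route(cache$which[[2]])
  dX[i1, j2, , ] <- route(cache$which[[3]])
  dX[i2, j2, , ] <- route(cache$which[[4]])
  dX
}

up_fwd <- function(X) {
  d <- dim(X)
  Y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  i1 <- seq(1, 2 * d[1], 2); j1 <- seq(1, 2 * d[2], 2)
  for (di in 0:1) for (dj in 0:1) Y[i1 + di, j1 + dj, , ] <- X
  Y
}

up_bwd <- function(dY) {
  d <- dim(dY)
  i1 <- seq(1, d[1], 2); j1 <- seq(1, d[2], 2)
  dY[i1, j1, , , drop = FALSE] + dY[i1 + 1, j1, , , drop = FALSE] +
    dY[i1, j1 + 1, , , drop = FALSE] + dY[i1 + 1, j1 + 1, , , drop = FALSE]
}

# conv -> BN -> ReLU block
block_fwd <- function(X, par, train) {
  c1 <- conv_fwd(X, par$conv)
  b1 <- bn_fwd(c1$Y, par$bn, train)
  r1 <- relu_fwd(b1$Y)
  list(Y = r1$Y, c1 = c1, b1 = b1, r1 = r1, par_bn = b1$par)
}

block_bwd <- function(dY, cache, par) {
  dr <- relu_bwd(dY, cache$r1)
  bb <- bn_bwd(dr, cache$b1, par$bn)
  cb <- conv_bwd(bb$dX, cache$c1, par$conv)
  list(dX = cb$dX, grads = list(conv = cb$grads, bn = bb$grads))
}

unet_init <- function(config, seed = 1) {
  with_seed(seed, {
    ch <- config$base_channels * 2^(0:config$depth)
    enc <- list(); cin <- config$in_channels
    for (i in seq_len(config$depth)) {
      enc[[i]] <- list(b1 = list(conv = conv_init(cin, ch[i]), bn = bn_init(ch[i])),
                       b2 = list(conv = conv_init(ch[i], ch[i]), bn = bn_init(ch[i])))
      cin <- ch[i]
    }
    bott <- list(b1 = list(conv = conv_init(cin, ch[config$depth + 1]),
                           bn = bn_init(ch[config$depth + 1])),
                 b2 = list(conv = conv_init(ch[config$depth + 1], ch[config$depth + 1]),
                           bn = bn_init(ch[config$depth + 1])))
    dec <- list()
    for (i in config$depth:1) {
      cin_d <- ch[i + 1] + ch[i]  # upsampled + skip
      dec[[i]] <- list(b1 = list(conv = conv_init(cin_d, ch[i]), bn = bn_init(ch[i])),
                       b2 = list(conv = conv_init(ch[i], ch[i]), bn = bn_init(ch[i])))
    }
    final <- conv_init(ch[1], config$out_classes, k = 1)
    list(enc = enc, bott = bott, dec = dec, final = final)
  })
}

unet_forward <- function(params, X, config, train = TRUE) {
  caches <- list(enc = list(), pool = list(), dec = list())
  skips <- list()
  A <- X
  for (i in seq_len(config$depth)) {
    c1 <- block_fwd(A, params$enc[[i]]$b1, train)
    c2 <- block_fwd(c1$Y, params$enc[[i]]$b2, train)
    params$enc[[i]]$b1$bn <- c1$par_bn; params$enc[[i]]$b2$bn <- c2$par_bn
    skips[[i]] <- c2$Y
    p <- pool_fwd(c2$Y)
    caches$enc[[i]] <- list(c1 = c1, c2 = c2)
    caches$pool[[i]] <- p
    A <- p$Y
  }
  c1 <- block_fwd(A, params$bott$b1, train)
  c2 <- block_fwd(c1$Y, params$bott$b2, train)
  params$bott$b1$bn <- c1$par_bn; params$bott$b2$bn <- c2$par_bn
  caches$bott <- list(c1 = c1, c2 = c2)
  A <- c2$Y
  for (i in config$depth:1) {
    U <- up_fwd(A)
    cat_in <- abind4(U, skips[[i]])
    c1 <- block_fwd(cat_in, params$dec[[i]]$b1, train)
    c2 <- block_fwd(c1$Y, params$dec[[i]]$b2, train)
    params$dec[[i]]$b1$bn <- c1$par_bn; params$dec[[i]]$b2$bn <- c2$par_bn
    caches$dec[[i]] <- list(c1 = c1, c2 = c2, n_up = dim(U)[4])
    A <- c2$Y
  }
  fin <- conv_fwd(A, params$final)
  caches$final <- fin
  list(logits = fin$Y, caches = caches, params = params)
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

unet_backward <- function(params, caches, dLogits, config) {
  grads <- list(enc = vector("list", config$depth),
                dec = vector("list", config$depth))
  fb <- conv_bwd(dLogits, caches$final, params$final)
  grads$final <- fb$grads
  dA <- fb$dX
  # decoder stages were applied depth..1, so backpropagate 1..depth
  for (i in 1:config$depth) {
    b2 <- block_bwd(dA, caches$dec[[i]]$c2, params$dec[[i]]$b2)
    b1 <- block_bwd(b2$dX, caches$dec[[i]]$c1, params$dec[[i]]$b1)
    n_up <- caches$dec[[i]]$n_up
    dU <- b1$dX[, , , seq_len(n_up), drop = FALSE]
    dskip <- b1$dX[, , , n_up + seq_len(dim(b1$dX)[4] - n_up), drop = FALSE]
    grads$dec[[i]] <- list(b1 = b1$grads, b2 = b2$grads, dskip = dskip)
    dA <- up_bwd(dU)  # feeds dec stage i+1, or the bottleneck at i = depth
  }
  b2 <- block_bwd(dA, caches$bott$c2, params$bott$b2)
  b1 <- block_bwd(b2$dX, caches$bott$c1, params$bott$b1)
  grads$bott <- list(b1 = b1$grads, b2 = b2$grads)
  dA <- b1$dX
  for (i in config$depth:1) {
    dpool <- pool_bwd(dA, caches$pool[[i]])
    dpool <- dpool + grads$dec[[i]]$dskip
    grads$dec[[i]]$dskip <- NULL
    b2 <- block_bwd(dpool, caches$enc[[i]]$c2, params$enc[[i]]$b2)
    b1 <- block_bwd(b2$dX, caches$enc[[i]]$c1, params$enc[[i]]$b1)
    grads$enc[[i]] <- list(b1 = b1$grads, b2 = b2$grads)
    dA <- b1$dX
  }
  grads
}

# pixel-wise softmax cross entropy; labels in {1..K} as [H, W, N]
softmax_ce <- function(logits, labels) {
  d <- dim(logits); K <- d[4]; m <- prod(d[1:3])
  L <- matrix(logits, m, K)
  L <- L - apply(L, 1, max)
  eL <- exp(L)
  P <- eL / rowSums(eL)
  idx <- cbind(seq_len(m), as.integer(labels))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dL <- P
  dL[idx] <- dL[idx] - 1
  list(loss = loss, dLogits = array(dL / m, d))
}

#' Train the U-Net iris segmenter
#'
#' @param images List of input images: `[H, W]` grayscale or `[H, W, 3]`
#'   arrays with values in [0, 255] (resized to the configured input size
#'   if needed).
#' @param masks List of binary label masks (same spatial size as the
#'   images).
#' @param config A [unet_config()].
#' @param seed Seed controlling weight initialisation, the train-order
#'   shuffle and augmentation order.
#' @return A `unet_model`: trained parameters, the config, and `loss`
#'   (mean cross-entropy per epoch).
#' @export
train_unet <- function(images, masks, config = unet_config(), seed = 1) {
  if (length(images) == 0) stopf("empty training set")
  if (length(images) != length(masks))
    stopf("images (%d) and masks (%d) differ in count", length(images), length(masks))
  prep <- prepare_unet_inputs(images, masks, config)
  X <- prep$X; Y <- prep$Y
  if (config$augment) {
    Xf <- X[, rev(seq_len(dim(X)[2])), , , drop = FALSE]
    Yf <- Y[, rev(seq_len(dim(Y)[2])), , drop = FALSE]
    X <- abind_n(X, Xf, 3); Y <- abind_y(Y, Yf)
  }
  n <- dim(X)[3]
  params <- unet_init(config, seed)
  opt <- adam_init()
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(n))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1, n)]
      Xb <- X[, , sel, , drop = FALSE]
      Yb <- Y[, , sel, drop = FALSE]
      fw <- unet_forward(params, Xb, config, train = TRUE)
      params <- fw$params  # batch-norm running stats updated
      sc <- softmax_ce(fw$logits, Yb)
      gr <- unet_backward(params, fw$caches, sc$dLogits, config)
      upd <- adam_step(params, gr, opt, config)
      params <- upd$params; opt <- upd$opt
      ep_loss <- ep_loss + sc$loss; nb <- nb + 1
    }
    losses[ep] <- ep_loss / nb
  }
  structure(list(params = params, config = config, loss = losses),
            class = "unet_model")
}

prepare_unet_inputs <- function(images, masks, config) {
  s <- config$input_size
  n <- length(images)
  X <- array(0, c(s, s, n, config$in_channels))
  Y <- array(1L, c(s, s, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    msk <- masks[[i]]
    if (is.matrix(img)) img <- array(rep(img, config$in_channels),
                                     c(dim(img), config$in_channels))
    if (!all(dim(img)[1:2] == dim(msk)))
      stopf("image %d and its mask differ in shape", i)
    if (!all(dim(img)[1:2] == c(s, s))) {
      img <- resize_img(img, s)
      msk <- round(resize_img(msk, s))
    }
    X[, , i, ] <- img / 255
    Y[, , i] <- ifelse(msk > 0, 2L, 1L)  # class 2 = iris
  }
  list(X = X, Y = Y)
}

resize_img <- function(img, s) {
  if (length(dim(img)) == 2) {
    as.matrix(EBImage::resize(img, w = s, h = s))
  } else {
    out <- array(0, c(s, s, dim(img)[3]))
    for (c in seq_len(dim(img)[3]))
      out[, , c] <- as.matrix(EBImage::resize(img[, , c], w = s, h = s))
    out
  }
}

abind_n <- function(a, b, along) {
  d <- dim(a)
  d[along] <- d[along] + dim(b)[along]
  out <- array(0, d)
  out[, , seq_len(dim(a)[3]), ] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3]), ] <- b
  out
}

abind_y <- function(a, b) {
  d <- dim(a)
  out <- array(1L, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# ---- Adam optimiser over the nested parameter list ----------------------

adam_init <- function() list(t = 0, m = NULL, v = NULL)

# flatten/apply helpers: walk params and grads in lockstep
walk_update <- function(p, g, m, v, lr, b1, b2, t, eps = 1e-8) {
  if (is.list(p)) {
    out_p <- p; out_m <- if (is.null(m)) vector("list", length(p)) else m
    out_v <- if (is.null(v)) vector("list", length(p)) else v
    keys <- if (is.null(names(p))) seq_along(p) else names(p)
    for (nm in keys) {
      if (is.character(nm) && nm %in% c("run_mean", "run_var")) next
      if (is.null(g[[nm]])) next
      r <- walk_update(p[[nm]], g[[nm]], out_m[[nm]], out_v[[nm]], lr, b1, b2, t, eps)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  } else {
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t); vhat <- v / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
}

adam_step <- function(params, grads, opt, config) {
  opt$t <- opt$t + 1
  r <- walk_update(params, grads, opt$m, opt$v,
                   config$lr, config$beta1, config$beta2, opt$t)
  list(params = r$p, opt = list(t = opt$t, m = r$m, v = r$v))
}

#' Predict an iris mask with a trained U-Net
#'
#' Argmax over the two class score maps, resized back to the frame
#' resolution.
#'
#' @param model A `unet_model` from [train_unet()].
#' @param frame `[H, W]` or `[H, W, 3]` image, values in [0, 255].
#' @return Binary mask matrix at the frame's resolution.
#' @export
predict_mask <- function(model, frame) {
  if (is.null(model$params)) stopf("uninitialized model")
  config <- model$config
  h0 <- dim(frame)[1]; w0 <- dim(frame)[2]
  img <- frame
  if (is.matrix(img)) img <- array(rep(img, config$in_channels),
                                   c(dim(img), config$in_channels))
  s <- config$input_size
  if (!all(dim(img)[1:2] == c(s, s))) img <- resize_img(img, s)
  X <- array(img / 255, c(s, s, 1, config$in_channels))
  fw <- unet_forward(model$params, X, config, train = FALSE)
  d <- dim(fw$logits)
  cls <- apply(matrix(fw$logits, s * s, d[4]), 1, which.max)
  mask <- matrix(as.numeric(cls == 2), s, s)
  if (!all(c(h0, w0) == c(s, s))) {
    mask <- as.matrix(EBImage::resize(mask, w = h0, h = w0, filter = "none"))
  }
  (mask > 0.5) * 1
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("unet_model: depth %d, base %d channels, %d epochs (final loss %.4f)\n",
              x$config$depth, x$config$base_channels, length(x$loss),
              x$loss[length(x$loss)]))
  invisible(x)
}
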