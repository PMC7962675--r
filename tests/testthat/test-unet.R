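test_that("analytic gradients match finite differences across all layer types", {
  set.seed(1)
  cfg <- unet_config(input_size = 8, in_channels = 1, depth = 1, base_channels = 2,
                     batch_size = 2, epochs = 1, augment = FALSE)
  params <- irisvel:::unet_init(cfg, seed = 2)
  X <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  Y <- array(sample(1:2, 8 * 8 * 2, TRUE), c(8, 8, 2))
  loss_of <- function(p) {
    fw <- irisvel:::unet_forward(p, X, cfg, train = TRUE)
    irisvel:::softmax_ce(fw$logits, Y)$loss
  }
  fw <- irisvel:::unet_forward(params, X, cfg, train = TRUE)
  gr <- irisvel:::unet_backward(fw$params, fw$caches,
                                irisvel:::softmax_ce(fw$logits, Y)$dLogits, cfg)
  eps <- 1e-5
  probes <- list(
    list(g = function(p) p$enc[[1]]$b1$conv$W[2, 2, 1, 1],
         s = function(p, v) { p$enc[[1]]$b1$conv$W[2, 2, 1, 1] <- v; p },
         a = gr$enc[[1]]$b1$conv$W[2, 2, 1, 1]),
    list(g = function(p) p$enc[[1]]$b2$bn$gamma[1],
         s = function(p, v) { p$enc[[1]]$b2$bn$gamma[1] <- v; p },
         a = gr$enc[[1]]$b2$bn$gamma[1]),
    list(g = function(p) p$bott$b2$conv$W[3, 1, 2, 3],
         s = function(p, v) { p$bott$b2$conv$W[3, 1, 2, 3] <- v; p },
         a = gr$bott$b2$conv$W[3, 1, 2, 3]),
    list(g = function(p) p$dec[[1]]$b1$bn$beta[2],
         s = function(p, v) { p$dec[[1]]$b1$bn$beta[2] <- v; p },
         a = gr$dec[[1]]$b1$bn$beta[2]),
    list(g = function(p) p$final$W[1, 1, 2, 2],
         s = function(p, v) { p$final$W[1, 1, 2, 2] <- v; p },
         a = gr$final$W[1, 1, 2, 2]))
  for (pr in probes) {
    num <- (loss_of(pr$s(params, pr$g(params) + eps)) -
            loss_of(pr$s(params, pr$g(params) - eps))) / (2 * eps)
    expect_equal(pr$a, num, tolerance = 1e-4)
  }
})

test_that("a short training run decreases the loss deterministically", {
  p <- unet_pairs(16, seed = 42)
  cfg <- unet_config(input_size = 32, in_channels = 3, depth = 2,
                     base_channels = 4, batch_size = 8, epochs = 3)
  mod <- train_unet(p$images, p$masks, cfg, seed = 7)
  expect_length(mod$loss, 3)
  expect_lt(mod$loss[3], mod$loss[1])
  mod2 <- train_unet(p$images, p$masks, cfg, seed = 7)
  expect_identical(mod$loss, mod2$loss)
  # predicted mask has the frame's resolution and binary values
  pr <- predict_mask(mod, p$images[[1]])
  expect_equal(dim(pr), dim(p$images[[1]]))
  expect_true(all(pr %in% c(0, 1)))
})

test_that("the trainer rejects malformed inputs", {
  expect_error(train_unet(list(), list()), "empty")
  p <- unet_pairs(2, seed = 5)
  expect_error(train_unet(p$images, p$masks[1]), "differ in count")
  bad <- p$masks
  bad[[1]] <- bad[[1]][1:16, ]
  cfg <- unet_config(input_size = 32, depth = 2, base_channels = 4, epochs = 1)
  expect_error(train_unet(p$images, bad, cfg), "shape")
  expect_error(unet_config(input_size = 30, depth = 2), "divisible")
  expect_error(predict_mask(structure(list(params = NULL), class = "unet_model"),
                            matrix(0, 8, 8)), "uninitialized")
})
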