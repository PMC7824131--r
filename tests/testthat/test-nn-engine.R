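# Engine correctness: every layer's backward pass against finite differences.

nn_loss <- function(net, X) {
  o <- msplane:::net_forward(net, X, keep_cache = FALSE)$out
  sum(o^2) / 2
}

check_net_grads <- function(net, X, n_per_param = 4L, tol = 1e-5) {
  fw <- msplane:::net_forward(net, X, keep_cache = TRUE)
  bw <- msplane:::net_backward(net, fw$out, fw$caches, need_dx = TRUE)
  for (i in seq_along(net)) {
    if (is.null(net[[i]]$W)) next
    for (nm in c("W", "b")) {
      p <- net[[i]][[nm]]
      g <- bw$grads[[i]][[nm]]
      for (j in sample(length(p), min(n_per_param, length(p)))) {
        h <- 1e-6
        n2 <- net; n2[[i]][[nm]][j] <- p[j] + h; lp <- nn_loss(n2, X)
        n2[[i]][[nm]][j] <- p[j] - h; lm <- nn_loss(n2, X)
        expect_equal(g[j], (lp - lm) / (2 * h), tolerance = tol)
      }
    }
  }
  # input gradient
  for (j in sample(length(X), 5L)) {
    h <- 1e-6
    Xp <- X; Xp[j] <- X[j] + h; lp <- nn_loss(net, Xp)
    Xp[j] <- X[j] - h; lm <- nn_loss(net, Xp)
    expect_equal(bw$dX[j], (lp - lm) / (2 * h), tolerance = tol)
  }
}

test_that("3D conv / pool / dense backward passes match finite differences", {
  set.seed(11)
  net <- list(
    msplane:::layer_conv(c(4, 4, 4), 1L, 2L, 3L, stride = 1L, pad = 1L),
    msplane:::layer_lrelu(0.2),
    msplane:::layer_maxpool(c(4, 4, 4), 2L),
    msplane:::layer_conv(c(2, 2, 2), 2L, 2L, 3L, stride = 1L, pad = 1L),
    msplane:::layer_sigmoid(),
    msplane:::layer_dense(16L, 3L),
    msplane:::layer_sigmoid())
  check_net_grads(net, matrix(rnorm(64 * 2), 64, 2))
})

test_that("strided, dilated and transposed convolutions match finite differences", {
  set.seed(12)
  net <- list(
    msplane:::layer_conv(c(8, 8, 8), 1L, 2L, 3L, stride = 2L, pad = 1L),
    msplane:::layer_lrelu(0.2),
    msplane:::layer_dense(128L, 8L), msplane:::layer_lrelu(0.2),
    msplane:::layer_dense(8L, 128L), msplane:::layer_lrelu(0.2),
    msplane:::layer_deconv(c(4, 4, 4), 2L, 1L),
    msplane:::layer_sigmoid())
  check_net_grads(net, matrix(rnorm(512 * 2), 512, 2))

  net2 <- list(
    msplane:::layer_conv(c(6, 6), 1L, 2L, 3L, pad = 2L, dilation = 2L),
    msplane:::layer_lrelu(0.2),
    msplane:::layer_upsample2(c(6, 6), 2L),
    msplane:::layer_conv(c(12, 12), 2L, 1L, 3L, pad = 1L),
    msplane:::layer_sigmoid())
  check_net_grads(net2, matrix(rnorm(36 * 2), 36, 2))
})

test_that("deconv doubles extents and conv shapes follow the arithmetic", {
  ly <- msplane:::layer_deconv(c(4, 4, 4), 3L, 2L)
  X <- matrix(rnorm(64 * 3 * 2), 64 * 3, 2)
  out <- msplane:::deconv_forward(ly, X)$out
  expect_equal(nrow(out), 8^3 * 2)

  ci <- msplane:::conv_index(c(5, 5), 3L, stride = 1L, pad = 1L)
  expect_equal(ci$out_dims, c(5L, 5L))
  ci <- msplane:::conv_index(c(8, 8, 8), 3L, stride = 2L, pad = 1L)
  expect_equal(ci$out_dims, c(4L, 4L, 4L))
})

test_that("U-Net backward pass matches finite differences", {
  set.seed(13)
  cfg <- seed_cascade_config(side = 8L, seg_channels = c(2L, 3L),
                             seg_steps = 1L, det_steps = 1L)
  net <- build_segmentation_net(cfg)
  X <- matrix(runif(64 * 2), 64, 2)
  Y <- matrix(rbinom(64 * 2, 1, 0.2), 64, 2)
  loss <- function(net) {
    p <- pmin(pmax(msplane:::unet_forward(net, X, FALSE)$out, 1e-7), 1 - 1e-7)
    mean(-Y * log(p) - (1 - Y) * log(1 - p))
  }
  fw <- msplane:::unet_forward(net, X, TRUE)
  p <- pmin(pmax(fw$out, 1e-7), 1 - 1e-7)
  dOut <- (-Y / p + (1 - Y) / (1 - p)) / length(p)
  gr <- msplane:::unet_backward(net, dOut, fw$caches)
  for (nm in msplane:::unet_param_layers) {
    pmat <- net$layers[[nm]]$W
    for (j in sample(length(pmat), min(3L, length(pmat)))) {
      h <- 1e-6
      n2 <- net; n2$layers[[nm]]$W[j] <- pmat[j] + h; lp <- loss(n2)
      n2$layers[[nm]]$W[j] <- pmat[j] - h; lm <- loss(n2)
      expect_equal(gr[[nm]]$W[j], (lp - lm) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("Adam and momentum-SGD reduce a simple regression loss", {
  set.seed(14)
  net <- list(msplane:::layer_dense(4L, 8L), msplane:::layer_lrelu(0.2),
              msplane:::layer_dense(8L, 1L))
  X <- matrix(rnorm(4 * 64), 4, 64)
  Yt <- matrix(colSums(X^2) / 4, 1, 64)
  run <- function(opt) {
    n <- net
    st <- if (opt == "adam") msplane:::adam_init(n, lr = 1e-2)
          else msplane:::sgd_init(n, lr = 1e-3)
    l0 <- lN <- NA
    for (it in 1:200) {
      fw <- msplane:::net_forward(n, X, TRUE)
      r <- fw$out - Yt
      if (it == 1) l0 <- mean(r^2)
      bw <- msplane:::net_backward(n, 2 * r / length(r), fw$caches)
      stp <- if (opt == "adam") msplane:::adam_step(n, bw$grads, st)
             else msplane:::sgd_step(n, bw$grads, st)
      n <- stp$net; st <- stp$state
      lN <- mean(r^2)
    }
    c(l0, lN)
  }
  la <- run("adam"); ls <- run("sgd")
  expect_lt(la[2], la[1] / 4)
  expect_lt(ls[2], ls[1] / 4)
})
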