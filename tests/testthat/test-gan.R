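# Combination operation, loss functions and their analytic limits.

test_that("combine builds the two-channel critic input", {
  v <- array(runif(27), c(3, 3, 3))
  ones <- array(1, c(3, 3, 3))
  cb <- combine(ones, v)
  expect_equal(dim(cb), c(3L, 3L, 3L, 2L))
  expect_equal(cb[, , , 1], cb[, , , 2])

  zeros <- array(0, c(3, 3, 3))
  cb <- combine(zeros, v)
  expect_true(all(cb[, , , 1] == 0))
  expect_equal(cb[, , , 2], v)

  m <- array(runif(27), c(3, 3, 3))
  cb <- combine(m, v)
  expect_equal(dim(cb)[4], 2L)          # two-channel output
  expect_equal(cb[, , , 1], m * v)

  expect_error(combine(array(0, c(2, 2, 2)), v), "identical")
})

test_that("cross_entropy matches closed forms and is monotone", {
  y <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  expect_lt(cross_entropy(y, y), 1e-6)
  x_half <- array(0.5, c(4, 4, 4))
  expect_equal(cross_entropy(x_half, y), log(2), tolerance = 1e-12)

  # moving predictions toward 1 - y strictly increases the loss
  x_good <- array(pmin(pmax(y, 0.2), 0.8), c(4, 4, 4))
  x_bad <- array(pmin(pmax(1 - y, 0.3), 0.7), c(4, 4, 4))
  expect_gt(cross_entropy(x_bad, y), cross_entropy(x_good, y))

  expect_error(cross_entropy(array(0.5, c(2, 2, 2)), y), "identical")
})

test_that("generator loss reduces to its limits at w = 0 and w = 1", {
  set.seed(21)
  x <- array(runif(64), c(4, 4, 4))
  y <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
  cfo <- matrix(runif(12), 3, 4)        # latent x batch critic outputs

  expect_equal(generator_loss(cfo, x, y, loss_weights(w = 1)),
               cross_entropy(x, y))
  expect_equal(generator_loss(cfo, x, y, loss_weights(w = 0)), -mean(cfo))

  m <- mean(cfo); ce <- cross_entropy(x, y)
  expect_equal(generator_loss(cfo, x, y, loss_weights(w = 0.8)),
               0.2 * (-m) + 0.8 * ce, tolerance = 1e-12)
})

test_that("gradient penalty matches analytic unit-Lipschitz and constant cases", {
  set.seed(22)
  V <- 2 * 64
  lin <- list(msplane:::layer_dense(V, 1L))
  lin[[1]]$W[] <- 1 / sqrt(V)           # sum / sqrt(n): gradient norm 1
  X <- matrix(rnorm(V * 5), V, 5)
  expect_lt(abs(gradient_penalty(lin, X)), 1e-5)

  const <- list(msplane:::layer_dense(V, 1L))
  const[[1]]$W[] <- 0
  expect_equal(gradient_penalty(const, X), 1, tolerance = 1e-5)
})

test_that("interpolation endpoints recover the fake and real masks", {
  x <- matrix(runif(16), 16, 1); y <- matrix(rbinom(16, 1, 0.5), 16, 1)
  xh0 <- 0 * y + (1 - 0) * x
  xh1 <- 1 * y + (1 - 1) * x
  expect_equal(xh0, x)
  expect_equal(xh1, y)
})

test_that("critic loss equals its three independently computed terms", {
  set.seed(23)
  cfg <- generator_config(side = 16L, channels = c(2L, 3L, 3L, 3L), latent = 6L)
  cri <- build_critic(critic_config(cfg))
  V <- 16^3; B <- 3
  vb <- matrix(runif(V * B), V, B)
  x <- matrix(runif(V * B), V, B)
  y <- matrix(rbinom(V * B, 1, 0.05), V, B)
  alpha <- runif(B)
  xh <- sweep(y, 2, alpha, "*") + sweep(x, 2, 1 - alpha, "*")
  xp <- combine(x, vb); yp <- combine(y, vb); xhp <- combine(xh, vb)

  cx <- mean(msplane:::net_forward(cri, xp, FALSE)$out)
  cy <- mean(msplane:::net_forward(cri, yp, FALSE)$out)
  gp <- gradient_penalty(cri, xhp)
  expect_equal(critic_loss(cri, xp, yp, xhp, loss_weights(0.8, 10)),
               cx - cy + 10 * gp, tolerance = 1e-12)

  # lambda = 0 reduces to the Wasserstein surrogate difference
  expect_equal(critic_loss(cri, xp, yp, xhp, loss_weights(0.8, 0)),
               cx - cy, tolerance = 1e-12)

  # fake equal to real with lambda = 0 gives exactly zero
  expect_equal(critic_loss(cri, yp, yp, yp, loss_weights(0.8, 0)), 0)
})

test_that("generator and critic shapes honour the architecture contract", {
  cfg <- generator_config(side = 16L, channels = c(2L, 3L, 3L, 3L), latent = 6L)
  gen <- build_generator(cfg)
  v <- array(runif(16^3), c(16, 16, 16))
  m <- predict_mask(gen, v)
  expect_equal(dim(m), dim(v))          # same input/output sizes
  expect_true(all(m >= 0 & m <= 1))     # sigmoid range

  # critic outputs a latent vector, not a scalar
  cri <- build_critic(critic_config(cfg, latent = 6L))
  out <- msplane:::net_forward(cri, msplane:::as_combined_batch(combine(m, v)),
                               FALSE)$out
  expect_equal(nrow(out), 6L)
  expect_true(all(out >= 0 & out <= 1))

  expect_error(generator_config(side = 20L), "divisible")
  expect_error(predict_mask(gen, array(0, c(32, 32, 32))), "size")
})

test_that("a training step is finite and seeded runs are bit-identical", {
  ds <- fixture_tiny_set()
  cfg <- generator_config(side = 16L, channels = c(2L, 3L, 3L, 3L), latent = 8L)
  g1 <- train_gan(ds, config = cfg, epochs = 2L, batch_size = 3L, seed = 9L)
  expect_true(all(is.finite(g1$history$critic_loss)))
  expect_true(all(is.finite(g1$history$gen_loss)))
  for (ly in g1$generator) if (!is.null(ly$W)) expect_true(all(is.finite(ly$W)))

  g2 <- train_gan(ds, config = cfg, epochs = 2L, batch_size = 3L, seed = 9L)
  expect_identical(g1$history, g2$history)
  expect_identical(g1$generator, g2$generator)
})

test_that("the generator can overfit a handful of phantoms", {
  ds <- fixture_tiny_set()
  cfg <- generator_config(side = 16L, channels = c(4L, 8L, 16L, 32L),
                          latent = 32L)
  gan <- train_gan(ds, config = cfg, epochs = 250L, batch_size = 6L,
                   lr = 1e-3, weights = loss_weights(w = 1, lambda = 10),
                   seed = 10L)
  expect_lt(tail(gan$history$ce, 1), 0.05)
  expect_lt(tail(gan$history$ce, 1), gan$history$ce[1])
})
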