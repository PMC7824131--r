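# Stage 2: adversarial plane-mask generation.
#
# The generator is a symmetric 3D convolutional autoencoder mapping a cropped
# head cube to a same-sized soft plane mask (sigmoid output).  The critic
# scores combined two-channel inputs (mask * volume, volume) and emits a
# latent vector rather than a scalar; expectations in the losses reduce that
# vector by its mean.  Training follows the Wasserstein objective with
# gradient penalty plus a cross-entropy term on the generator:
#
#   L_G = -(1 - w) E[C(x')] + w * L_ce
#   L_C =  E[C(x')] - E[C(y')] + lambda * E[(||grad_{xhat'} C(xhat')|| - 1)^2]
#
# with xhat = alpha y + (1 - alpha) x, alpha ~ U(0, 1) per sample, and
# x', y', xhat' the combined two-channel critic inputs.
#
# The penalty VALUE uses the exact analytic input gradient.  For the critic
# parameter update, the mixed second derivative is evaluated by a central
# finite difference of the critic along the normalized input-gradient
# direction (||g|| = g . ghat, and g . ghat ~= [C(x + eps ghat) -
# C(x - eps ghat)] / 2 eps), which needs only ordinary first-order backprop.

#' Generator architecture settings
#'
#' @param side cube side length of the cropped input (must be divisible by
#'   16: four stride-2 encoder layers).
#' @param channels encoder channel widths for the four convolution layers;
#'   the decoder mirrors them.
#' @param latent width of the two fully connected bottleneck layers.
#' @param leaky negative slope of the leaky ReLU activations.
#' @param kernel convolution kernel extent.
#' @return `msp_generator_config` list.
#' @export
generator_config <- function(side = 80L, channels = c(16L, 32L, 64L, 64L),
                             latent = 200L, leaky = 0.2, kernel = 3L) {
  side <- as.integer(side)
  if (side %% 16L != 0L)
    stop("config error: input side must be divisible by 16", call. = FALSE)
  stopifnot(length(channels) == 4L, latent >= 1L)
  structure(list(side = side, channels = as.integer(channels),
                 latent = as.integer(latent), leaky = leaky,
                 kernel = as.integer(kernel)),
            class = "msp_generator_config")
}

#' Critic architecture settings
#'
#' Four stride-1 convolutions, each followed by 2x max-pooling; the channel
#' widths equal the generator encoder's.  The output is a latent vector with
#' a final sigmoid.
#'
#' @param generator an [generator_config()] whose channels/side are mirrored.
#' @param latent critic output latent dimension.
#' @return `msp_critic_config` list.
#' @export
critic_config <- function(generator = generator_config(), latent = 32L) {
  structure(list(side = generator$side, channels = generator$channels,
                 latent = as.integer(latent), leaky = generator$leaky,
                 kernel = generator$kernel),
            class = "msp_critic_config")
}

#' Build the mask generator network
#'
#' Symmetric 3D autoencoder: four stride-2 convolutions with leaky ReLU,
#' two fully connected bottleneck layers, four transposed convolutions
#' (zero-stuffing upsample + convolution) with leaky ReLU, and a final
#' sigmoid so outputs are soft masks in `[0, 1]`.
#'
#' @param config an [generator_config()].
#' @return Layer list usable with [predict_mask()] and [train_gan()].
#' @export
build_generator <- function(config = generator_config()) {
  s <- config$side; ch <- config$channels; k <- config$kernel
  pad <- (k - 1L) %/% 2L
  lk <- config$leaky
  d1 <- rep(s, 3L); d2 <- d1 %/% 2L; d4 <- d1 %/% 4L; d8 <- d1 %/% 8L
  d16 <- d1 %/% 16L
  nfc <- prod(d16) * ch[4]
  net <- list(
    layer_conv(d1, 1L, ch[1], k, stride = 2L, pad = pad), layer_lrelu(lk),
    layer_conv(d2, ch[1], ch[2], k, stride = 2L, pad = pad), layer_lrelu(lk),
    layer_conv(d4, ch[2], ch[3], k, stride = 2L, pad = pad), layer_lrelu(lk),
    layer_conv(d8, ch[3], ch[4], k, stride = 2L, pad = pad), layer_lrelu(lk),
    layer_dense(nfc, config$latent), layer_lrelu(lk),
    layer_dense(config$latent, nfc), layer_lrelu(lk),
    layer_deconv(d16, ch[4], ch[3]), layer_lrelu(lk),
    layer_deconv(d8, ch[3], ch[2]), layer_lrelu(lk),
    layer_deconv(d4, ch[2], ch[1]), layer_lrelu(lk),
    layer_deconv(d2, ch[1], 1L),
    layer_sigmoid()
  )
  # bias the output toward the sparse-mask prior so early training is stable
  net[[length(net) - 1L]]$b[] <- -3
  structure(net, class = "msp_net", side = s)
}

#' Build the critic network
#'
#' @param config an [critic_config()].
#' @return Layer list; the forward output is a latent vector per sample.
#' @export
build_critic <- function(config = critic_config()) {
  s <- config$side; ch <- config$channels; k <- config$kernel
  pad <- (k - 1L) %/% 2L
  lk <- config$leaky
  d1 <- rep(s, 3L); d2 <- d1 %/% 2L; d4 <- d1 %/% 4L; d8 <- d1 %/% 8L
  d16 <- d1 %/% 16L
  # each block max-pools then convolves at the halved grid, which keeps the
  # im2col buffers small while retaining four conv + four pooling stages
  net <- list(
    layer_maxpool(d1, 2L),
    layer_conv(d2, 2L, ch[1], k, stride = 1L, pad = pad), layer_lrelu(lk),
    layer_maxpool(d2, ch[1]),
    layer_conv(d4, ch[1], ch[2], k, stride = 1L, pad = pad), layer_lrelu(lk),
    layer_maxpool(d4, ch[2]),
    layer_conv(d8, ch[2], ch[3], k, stride = 1L, pad = pad), layer_lrelu(lk),
    layer_maxpool(d8, ch[3]),
    layer_conv(d16, ch[3], ch[4], k, stride = 1L, pad = pad), layer_lrelu(lk),
    layer_dense(prod(d16) * ch[4], config$latent),
    layer_sigmoid()
  )
  structure(net, class = "msp_net", side = s)
}

# ---- combination operation ------------------------------------------------

#' Combine a mask and a volume into the two-channel critic input
#'
#' Channel 1 is the elementwise product `mask * volume` (the intensity plane
#' cut out of the image), channel 2 the unchanged volume.
#'
#' @param mask,volume same-shaped 3D arrays, or `(V x B)` batch matrices.
#' @return For arrays, a 4D array `c(dim(volume), 2)`; for batch matrices a
#'   `(2V x B)` matrix with channel-major rows.
#' @export
combine <- function(mask, volume) {
  if (is.matrix(mask) && is.matrix(volume)) {
    if (!identical(dim(mask), dim(volume)))
      stop("mask and volume batches must have identical shapes", call. = FALSE)
    return(rbind(mask * volume, volume))
  }
  if (!identical(dim(mask), dim(volume)))
    stop("mask and volume must have identical dimensions", call. = FALSE)
  if (!all(is.finite(mask)) || !all(is.finite(volume)))
    stop("mask and volume must be finite", call. = FALSE)
  array(c(mask * volume, volume), c(dim(volume), 2L))
}

# flatten a combined 4D array (or already-flat column) to a 2V x 1 matrix
as_combined_batch <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 4L) return(matrix(as.vector(x), ncol = 1L))
  matrix(as.vector(x), ncol = 1L)
}

# ---- losses ---------------------------------------------------------------

#' Voxelwise binary cross-entropy between a soft and a binary mask
#'
#' `mean(-y log x - (1 - y) log(1 - x))` with `x` clipped to
#' `[eps, 1 - eps]`.
#'
#' @param x soft prediction in `[0, 1]` (array or matrix).
#' @param y binary ground truth, same shape.
#' @param eps clipping constant.
#' @return Scalar loss (`log 2` for a constant `x = 0.5`).
#' @export
cross_entropy <- function(x, y, eps = 1e-7) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("prediction and target must have identical shapes", call. = FALSE)
  xc <- clamp(as.numeric(x), eps, 1 - eps)
  yv <- as.numeric(y)
  mean(-yv * log(xc) - (1 - yv) * log(1 - xc))
}

#' Loss trade-off weights
#'
#' @param w cross-entropy vs adversarial trade-off in `[0, 1]` (default 0.8).
#' @param lambda gradient-penalty weight (default 10).
#' @return `msp_loss_weights` list.
#' @export
loss_weights <- function(w = 0.8, lambda = 10) {
  stopifnot(w >= 0, w <= 1, lambda >= 0)
  structure(list(w = w, lambda = lambda), class = "msp_loss_weights")
}

# reduce critic latent outputs (L x B) to one scalar per sample
critic_scalar <- function(out) colMeans(out)

#' Generator loss
#'
#' `-(1 - w) * mean(C(x')) + w * cross_entropy(x, y)`, where the critic
#' output mean reduces over both the latent components and the batch.
#'
#' @param critic_fake_out critic latent outputs on the combined fakes
#'   (`L x B` matrix, or vector).
#' @param x soft predicted masks; `y` binary ground truth (same shape).
#' @param y binary ground-truth masks.
#' @param weights an [loss_weights()].
#' @return Scalar loss.
#' @export
generator_loss <- function(critic_fake_out, x, y, weights = loss_weights()) {
  adv <- mean(critic_fake_out)
  -(1 - weights$w) * adv + weights$w * cross_entropy(x, y)
}

# per-sample input gradients of the reduced critic scalar
critic_input_gradient <- function(critic, X) {
  fw <- net_forward(critic, X, keep_cache = TRUE)
  L <- nrow(fw$out)
  dOut <- matrix(1 / L, L, ncol(X))
  bw <- net_backward(critic, dOut, fw$caches, need_dx = TRUE,
                     need_grads = FALSE)
  list(out = fw$out, grad = bw$dX)
}

#' Gradient penalty of a critic on interpolated combined inputs
#'
#' `mean((||grad_x C(x)||_2 - 1)^2)` over the batch, where `C` is the
#' critic's latent output reduced by its mean and the gradient norm runs
#' over all voxels of both channels of each sample.  The gradient is exact
#' (one analytic backward pass per batch).
#'
#' @param critic a critic network.
#' @param x_hat_prime combined interpolate batch (`2V x B` matrix or one 4D
#'   array).
#' @return Scalar penalty (0 for a unit-Lipschitz linear critic, 1 for a
#'   constant critic).
#' @export
gradient_penalty <- function(critic, x_hat_prime) {
  X <- as_combined_batch(x_hat_prime)
  gr <- critic_input_gradient(critic, X)$grad
  if (!all(is.finite(gr)))
    stop("non-finite critic input gradient", call. = FALSE)
  gnorm <- sqrt(colSums(gr^2))
  mean((gnorm - 1)^2)
}

#' Critic loss
#'
#' `mean(C(x')) - mean(C(y')) + lambda * gradient_penalty(critic, xhat')`.
#'
#' @param critic a critic network.
#' @param x_prime,y_prime,x_hat_prime combined two-channel batches for the
#'   fake, real and interpolated masks (all from the same volumes).
#' @param weights an [loss_weights()].
#' @return Scalar loss.
#' @export
critic_loss <- function(critic, x_prime, y_prime, x_hat_prime,
                        weights = loss_weights()) {
  xp <- as_combined_batch(x_prime)
  yp <- as_combined_batch(y_prime)
  cx <- mean(net_forward(critic, xp, keep_cache = FALSE)$out)
  cy <- mean(net_forward(critic, yp, keep_cache = FALSE)$out)
  gp <- if (weights$lambda > 0) gradient_penalty(critic, x_hat_prime) else 0
  cx - cy + weights$lambda * gp
}

# parameter gradients of mean(C(X)) scaled by `scale`
critic_mean_grads <- function(critic, X, scale) {
  fw <- net_forward(critic, X, keep_cache = TRUE)
  L <- nrow(fw$out); B <- ncol(X)
  dOut <- matrix(scale / (L * B), L, B)
  net_backward(critic, dOut, fw$caches, need_dx = FALSE)$grads
}

# parameter gradients of sum_b wts[b] * C_b(X) (per-sample weights);
# also returns the per-sample critic scalars of the same forward pass
critic_weighted_grads <- function(critic, X, wts) {
  fw <- net_forward(critic, X, keep_cache = TRUE)
  L <- nrow(fw$out)
  dOut <- matrix(rep(wts / L, each = L), L, ncol(X))
  list(grads = net_backward(critic, dOut, fw$caches, need_dx = FALSE)$grads,
       scalars = colMeans(fw$out))
}

#' Train the mask-generating GAN
#'
#' Alternating optimisation (by default one critic step then one generator
#' step per iteration) with Adam at the standard settings (`lr = 1e-4`,
#' `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`), batch size 8.  Fully
#' deterministic given `seed`.
#'
#' @param volumes `(V x N)` matrix, list of 3D arrays, or list of
#'   `msp_phantom` samples (cropped to a common cube side).
#' @param masks `(V x N)` matrix or list of binary 3D arrays; ignored when
#'   `volumes` are phantoms (their ground-truth masks are used).
#' @param config an [generator_config()] matching the cube side.
#' @param weights an [loss_weights()].
#' @param epochs number of passes over the data.
#' @param batch_size minibatch size.
#' @param lr,beta1,beta2 Adam settings for both networks.
#' @param critic_steps critic updates per generator update.
#' @param seed integer RNG seed (initialisation, shuffling, interpolation).
#' @param fd_eps step of the finite-difference directional derivative used
#'   for the penalty's parameter gradient.
#' @param verbose print one line per epoch.
#' @return `msp_gan` object with `generator`, `critic`, `config`, `weights`
#'   and a per-epoch `history` tibble (mean critic loss, generator loss and
#'   cross-entropy term).
#' @export
train_gan <- function(volumes, masks = NULL, config = generator_config(),
                      weights = loss_weights(), epochs = 30L, batch_size = 8L,
                      lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      critic_steps = 1L, seed = 1L, fd_eps = 1e-4,
                      verbose = FALSE) {
  dat <- gan_training_matrices(volumes, masks, config$side)
  V <- nrow(dat$vol); N <- ncol(dat$vol)
  if (N < 1L) stop("empty training set", call. = FALSE)
  local_seed(seed, {
    gen <- build_generator(config)
    cri <- build_critic(critic_config(config))
    ost_g <- adam_init(gen, lr = lr, beta1 = beta1, beta2 = beta2)
    ost_c <- adam_init(cri, lr = lr, beta1 = beta1, beta2 = beta2)
    hist <- vector("list", epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      nb <- max(1L, N %/% batch_size)
      ep_c <- ep_g <- ep_ce <- 0
      for (ib in seq_len(nb)) {
        sel <- ord[((ib - 1L) * batch_size + 1L):min(ib * batch_size, N)]
        vb <- dat$vol[, sel, drop = FALSE]
        yb <- dat$msk[, sel, drop = FALSE]
        B <- length(sel)
        # one generator forward serves the critic step(s) and, with its
        # cache, the generator step (the critic update leaves x unchanged)
        fw <- net_forward(gen, vb, keep_cache = TRUE)
        x <- fw$out
        xp <- combine(x, vb)
        for (cs in seq_len(critic_steps)) {
          alpha <- stats::runif(B)
          xh <- sweep(yb, 2L, alpha, "*") + sweep(x, 2L, 1 - alpha, "*")
          yp <- combine(yb, vb); xhp <- combine(xh, vb)
          wg <- critic_weighted_grads(cri, cbind(xp, yp),
                                      c(rep(1 / B, B), rep(-1 / B, B)))
          g <- wg$grads
          gp_val <- 0
          if (weights$lambda > 0) {
            ig <- critic_input_gradient(cri, xhp)
            gnorm <- sqrt(colSums(ig$grad^2))
            gp_val <- mean((gnorm - 1)^2)
            u <- sweep(ig$grad, 2L, pmax(gnorm, 1e-12), "/")
            u[, gnorm < 1e-12] <- 0
            cw <- weights$lambda * 2 * (gnorm - 1) / (B * 2 * fd_eps)
            g <- grads_axpy(g, critic_weighted_grads(
              cri, cbind(xhp + fd_eps * u, xhp - fd_eps * u), c(cw, -cw))$grads)
          }
          stp <- adam_step(cri, g, ost_c)
          cri <- stp$net; ost_c <- stp$state
          ep_c <- ep_c + mean(wg$scalars[seq_len(B)]) -
            mean(wg$scalars[B + seq_len(B)]) + weights$lambda * gp_val
        }
        # generator step (against the freshly updated critic)
        cfw <- net_forward(cri, xp, keep_cache = TRUE)
        Lc <- nrow(cfw$out)
        dadv <- matrix(-(1 - weights$w) / (Lc * B), Lc, B)
        dxp <- net_backward(cri, dadv, cfw$caches, need_dx = TRUE,
                            need_grads = FALSE)$dX
        dx <- dxp[seq_len(V), , drop = FALSE] * vb   # channel 1 = x * v
        eps <- 1e-7
        xc <- clamp(x, eps, 1 - eps)
        dce <- weights$w * (-yb / xc + (1 - yb) / (1 - xc)) / (V * B)
        dce[x < eps | x > 1 - eps] <- 0
        bw <- net_backward(gen, dx + dce, fw$caches, need_dx = FALSE)
        stp <- adam_step(gen, bw$grads, ost_g)
        gen <- stp$net; ost_g <- stp$state
        ce <- cross_entropy(x, yb)
        ep_ce <- ep_ce + ce
        ep_g <- ep_g + generator_loss(cfw$out, x, yb, weights)
      }
      hist[[ep]] <- tibble::tibble(epoch = ep,
                                   critic_loss = ep_c / (nb * critic_steps),
                                   gen_loss = ep_g / nb, ce = ep_ce / nb)
      if (verbose)
        message(sprintf("epoch %d: L_C %.4f  L_G %.4f  ce %.4f",
                        ep, ep_c / (nb * critic_steps), ep_g / nb, ep_ce / nb))
    }
    structure(list(generator = gen, critic = cri, config = config,
                   weights = weights,
                   history = dplyr::bind_rows(hist)),
              class = "msp_gan")
  })
}

# normalise the many accepted input forms to (V x N) matrices
gan_training_matrices <- function(volumes, masks, side) {
  V <- side^3
  if (is.matrix(volumes)) {
    if (nrow(volumes) != V) stop("inconsistent crop size", call. = FALSE)
    stopifnot(is.matrix(masks), identical(dim(masks), dim(volumes)))
    return(list(vol = volumes, msk = masks))
  }
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  if (inherits(volumes[[1]], "msp_phantom")) {
    vol <- vapply(volumes, function(s) as.vector(s$volume), numeric(V))
    msk <- vapply(volumes, function(s) as.vector(s$gt_mask), numeric(V))
  } else {
    vol <- vapply(volumes, as.vector, numeric(V))
    msk <- vapply(masks, as.vector, numeric(V))
  }
  if (any(dim(vol) != c(V, length(volumes))))
    stop("inconsistent crop size", call. = FALSE)
  list(vol = vol, msk = msk)
}

#' @export
print.msp_gan <- function(x, ...) {
  cat(sprintf("<msp_gan> side %d, %d generator + %d critic parameters, %d epochs\n",
              x$config$side, net_n_params(x$generator), net_n_params(x$critic),
              max(x$history$epoch)))
  invisible(x)
}

#' Predict a soft plane mask for a cropped volume
#'
#' In the testing phase only the generator runs; the output is a soft mask
#' in `[0, 1]` with the same dimensions as the input.
#'
#' @param gan an `msp_gan` (or a bare generator network).
#' @param volume cropped cube (3D array at the trained side length).
#' @return Soft mask array, same dimensions as `volume`.
#' @export
predict_mask <- function(gan, volume) {
  gen <- if (inherits(gan, "msp_gan")) gan$generator else gan
  side <- attr(gen, "side")
  if (!identical(as.integer(dim(volume)), rep(as.integer(side), 3L)))
    stop("volume size does not match the trained architecture", call. = FALSE)
  out <- net_forward(gen, matrix(as.vector(volume), ncol = 1L),
                     keep_cache = FALSE)$out
  array(out, dim(volume))
}
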