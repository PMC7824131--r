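# Minimal neural-network engine.
#
# All activations live as dense matrices of shape (features x batch).  The
# feature layout is channel-major: linear index = voxel + V * (channel - 1),
# with voxels in R's column-major array order.  Convolutions are evaluated as
# one GEMM per layer over an im2col gather whose integer index map is
# precomputed once at layer-construction time, so the per-step cost is a
# single matrix product handled by BLAS.  Backward passes are hand-derived;
# a finite-difference gradient check lives in the test suite.

#' Precompute an n-dimensional im2col index map
#'
#' @param in_dims integer vector of spatial extents (length 2 or 3).
#' @param k kernel extent per dimension (scalar or vector).
#' @param stride,pad,dilation per-dimension (scalar or vector); `pad` is
#'   symmetric zero padding.
#' @return list with `idx` (K x P matrix of 1-based source voxel indices, 0
#'   for padded taps), `out_dims`, `K`, `P`.
#' @keywords internal
#' @noRd
conv_index <- function(in_dims, k, stride = 1L, pad = 0L, dilation = 1L) {
  nd <- length(in_dims)
  k <- rep_len(as.integer(k), nd)
  stride <- rep_len(as.integer(stride), nd)
  pad <- rep_len(as.integer(pad), nd)
  dilation <- rep_len(as.integer(dilation), nd)
  eff <- (k - 1L) * dilation + 1L
  out_dims <- (in_dims + 2L * pad - eff) %/% stride + 1L
  if (any(out_dims < 1L)) stop("convolution output would be empty", call. = FALSE)
  tap_list <- lapply(seq_len(nd), function(d) (0:(k[d] - 1L)) * dilation[d])
  org_list <- lapply(seq_len(nd), function(d) -pad[d] + (0:(out_dims[d] - 1L)) * stride[d])
  taps <- as.matrix(expand.grid(tap_list, KEEP.OUT.ATTRS = FALSE))
  orgs <- as.matrix(expand.grid(org_list, KEEP.OUT.ATTRS = FALSE))
  K <- nrow(taps); P <- nrow(orgs)
  lin <- matrix(1L, K, P)
  ok <- matrix(TRUE, K, P)
  mult <- 1L
  for (d in seq_len(nd)) {
    cd <- outer(taps[, d], orgs[, d], "+")
    ok <- ok & cd >= 0L & cd < in_dims[d]
    lin <- lin + cd * mult
    mult <- mult * in_dims[d]
  }
  lin[!ok] <- 0L
  list(idx = lin, out_dims = out_dims, K = K, P = P)
}

# He-style initialisation
nn_init_w <- function(nout, nin, gain = sqrt(2)) {
  matrix(stats::rnorm(nout * nin, sd = gain / sqrt(nin)), nout, nin)
}

#' Convolution layer (2D or 3D) via precomputed im2col
#' @keywords internal
#' @noRd
layer_conv <- function(in_dims, cin, cout, k, stride = 1L, pad = 0L,
                       dilation = 1L, init_gain = sqrt(2)) {
  ci <- conv_index(in_dims, k, stride, pad, dilation)
  V <- prod(in_dims)
  K <- ci$K
  # full row-index map including channels; padded taps -> augmented zero row
  I <- matrix(0L, K * cin, ci$P)
  zero_row <- V * cin + 1L
  for (c in seq_len(cin)) {
    blk <- ci$idx
    blk[blk > 0L] <- blk[blk > 0L] + V * (c - 1L)
    blk[blk == 0L] <- zero_row
    I[(c - 1L) * K + seq_len(K), ] <- blk
  }
  iv <- as.vector(I)
  list(type = "conv", in_dims = in_dims, out_dims = ci$out_dims,
       cin = cin, cout = cout, K = K, P = ci$P, V = V,
       I = I, iv = iv, ug = sort(unique(iv)),
       W = nn_init_w(cout, K * cin, init_gain), b = numeric(cout))
}

# reshape without copying (x must be un-shared, e.g. a fresh result)
reshape2 <- function(x, nr, nc) { dim(x) <- c(nr, nc); x }

# (P*C x B) <-> (C x P*B) channel permutations
perm_pc_to_cp <- function(x, P, C, B) {
  dim(x) <- c(P, C, B)
  x <- aperm(x, c(2L, 1L, 3L))
  dim(x) <- c(C, P * B)
  x
}

perm_cp_to_pc <- function(x, C, P, B) {
  dim(x) <- c(C, P, B)
  x <- aperm(x, c(2L, 1L, 3L))
  dim(x) <- c(P * C, B)
  x
}

conv_forward <- function(ly, X) {
  B <- ncol(X)
  Xaug <- rbind(X, 0)
  A <- reshape2(Xaug[ly$iv, , drop = FALSE], ly$K * ly$cin, ly$P * B)
  Y0 <- ly$W %*% A + ly$b
  out <- perm_cp_to_pc(Y0, ly$cout, ly$P, B)
  list(out = out, cache = list(A = A, B = B))
}

conv_backward <- function(ly, dY, cache, need_dx = TRUE, need_grads = TRUE) {
  B <- cache$B
  dY0 <- perm_pc_to_cp(dY + 0, ly$P, ly$cout, B)
  dW <- db <- NULL
  if (need_grads) {
    dW <- tcrossprod(dY0, cache$A)
    db <- rowSums(dY0)
  }
  dX <- NULL
  if (need_dx) {
    dA <- crossprod(ly$W, dY0)
    dA0 <- reshape2(dA, ly$K * ly$cin * ly$P, B)
    sums <- rowsum(dA0, group = ly$iv, reorder = TRUE)
    dXaug <- matrix(0, ly$V * ly$cin + 1L, B)
    dXaug[ly$ug, ] <- sums
    dX <- dXaug[-nrow(dXaug), , drop = FALSE]
  }
  list(dX = dX, grads = if (need_grads) list(W = dW, b = db))
}

#' Transposed convolution (learned upsampling), stride 2
#'
#' The adjoint of a stride-2 convolution from the doubled grid: output
#' extents are exactly `2 * in_dims` (kernel 4, padding 1).  Forward is the
#' scatter (col2im) of `t(W) %*% X`, which keeps the im2col buffers on the
#' coarse side of the layer.
#' @keywords internal
#' @noRd
layer_deconv <- function(in_dims, cin, cout, k = 4L, init_gain = sqrt(2)) {
  in_dims <- as.integer(in_dims)
  out_dims <- 2L * in_dims
  # underlying "adjoint" convolution: (cout, out_dims) -> (cin, in_dims)
  ci <- conv_index(out_dims, k, stride = 2L, pad = (k - 2L) %/% 2L)
  stopifnot(all(ci$out_dims == in_dims))
  V2 <- as.integer(prod(out_dims))
  K <- ci$K
  I <- matrix(0L, K * cout, ci$P)
  zero_row <- V2 * cout + 1L
  for (c in seq_len(cout)) {
    blk <- ci$idx
    blk[blk > 0L] <- blk[blk > 0L] + V2 * (c - 1L)
    blk[blk == 0L] <- zero_row
    I[(c - 1L) * K + seq_len(K), ] <- blk
  }
  iv <- as.vector(I)
  list(type = "deconv", in_dims = in_dims, out_dims = out_dims,
       cin = cin, cout = cout, K = K, P = ci$P, V2 = V2,
       iv = iv, ug = sort(unique(iv)),
       W = nn_init_w(cin, K * cout, init_gain), b = numeric(cout))
}

deconv_forward <- function(ly, X) {
  B <- ncol(X)
  X0 <- perm_pc_to_cp(X + 0, ly$P, ly$cin, B)      # (cin x P*B)
  dA <- crossprod(ly$W, X0)                        # (K*cout x P*B)
  dA0 <- reshape2(dA, ly$K * ly$cout * ly$P, B)
  sums <- rowsum(dA0, group = ly$iv, reorder = TRUE)
  out_aug <- matrix(0, ly$V2 * ly$cout + 1L, B)
  out_aug[ly$ug, ] <- sums
  out <- out_aug[-nrow(out_aug), , drop = FALSE]
  out <- out + rep(ly$b, each = ly$V2)
  list(out = out, cache = list(X0 = X0, B = B))
}

deconv_backward <- function(ly, dY, cache, need_dx = TRUE, need_grads = TRUE) {
  B <- cache$B
  dYaug <- rbind(dY, 0)
  A <- reshape2(dYaug[ly$iv, , drop = FALSE], ly$K * ly$cout, ly$P * B)
  dW <- db <- NULL
  if (need_grads) {
    dW <- tcrossprod(cache$X0, A)                  # (cin x K*cout)
    dYc <- reshape2(dY + 0, ly$V2, ly$cout * B)
    db <- rowSums(reshape2(colSums(dYc), ly$cout, B))
  }
  dX <- NULL
  if (need_dx) {
    dX0 <- ly$W %*% A                              # (cin x P*B)
    dX <- perm_cp_to_pc(dX0, ly$cin, ly$P, B)
  }
  list(dX = dX, grads = if (need_grads) list(W = dW, b = db))
}

#' Dense (fully connected) layer
#' @keywords internal
#' @noRd
layer_dense <- function(nin, nout, init_gain = sqrt(2)) {
  list(type = "dense", nin = nin, nout = nout,
       W = nn_init_w(nout, nin, init_gain), b = numeric(nout))
}

dense_forward <- function(ly, X) {
  list(out = ly$W %*% X + ly$b, cache = list(X = X))
}

dense_backward <- function(ly, dY, cache, need_dx = TRUE, need_grads = TRUE) {
  dW <- db <- NULL
  if (need_grads) {
    dW <- tcrossprod(dY, cache$X)
    db <- rowSums(dY)
  }
  dX <- if (need_dx) crossprod(ly$W, dY) else NULL
  list(dX = dX, grads = if (need_grads) list(W = dW, b = db))
}

#' Leaky ReLU
#' @keywords internal
#' @noRd
layer_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)

lrelu_forward <- function(ly, X) {
  scale <- ly$slope + (1 - ly$slope) * (X > 0)
  list(out = X * scale, cache = list(scale = scale))
}

lrelu_backward <- function(ly, dY, cache, need_dx = TRUE) {
  list(dX = dY * cache$scale, grads = NULL)
}

#' Logistic sigmoid
#' @keywords internal
#' @noRd
layer_sigmoid <- function() list(type = "sigmoid")

sigmoid_forward <- function(ly, X) {
  out <- 1 / (1 + exp(-X))
  list(out = out, cache = list(out = out))
}

sigmoid_backward <- function(ly, dY, cache, need_dx = TRUE) {
  list(dX = dY * cache$out * (1 - cache$out), grads = NULL)
}

#' Non-overlapping 2x max-pooling (any spatial rank)
#' @keywords internal
#' @noRd
layer_maxpool <- function(in_dims, cin) {
  if (any(in_dims %% 2L != 0L)) stop("max-pooling needs even extents", call. = FALSE)
  ci <- conv_index(in_dims, k = 2L, stride = 2L, pad = 0L)
  V <- prod(in_dims)
  K <- ci$K; P <- ci$P
  I <- matrix(0L, K, P * cin)
  for (c in seq_len(cin)) I[, (c - 1L) * P + seq_len(P)] <- ci$idx + V * (c - 1L)
  list(type = "maxpool", in_dims = in_dims, out_dims = ci$out_dims,
       cin = cin, K = K, P = P, V = V, I = I, ivt = as.vector(t(I)))
}

maxpool_forward <- function(ly, X) {
  B <- ncol(X)
  PC <- ly$P * ly$cin
  At <- reshape2(X[ly$ivt, , drop = FALSE], PC, ly$K * B)
  # columns of At are (tap, sample) pairs; regroup so each row holds the K
  # taps of one (output, sample) cell, then take the row maximum
  dim(At) <- c(PC, ly$K, B)
  At <- aperm(At, c(1L, 3L, 2L))
  dim(At) <- c(PC * B, ly$K)
  am <- max.col(At, ties.method = "first")
  m <- At[cbind(seq_len(PC * B), am)]
  out <- matrix(m, PC, B)
  list(out = out, cache = list(am = am, B = B))
}

maxpool_backward <- function(ly, dY, cache, need_dx = TRUE) {
  B <- cache$B
  PC <- ly$P * ly$cin
  # winning source voxel per (output, sample); pooling windows are disjoint
  col <- rep(seq_len(PC), times = B)
  src <- ly$I[cache$am + ly$K * (col - 1L)]
  dX <- matrix(0, ly$V * ly$cin, B)
  dX[cbind(src, rep(seq_len(B), each = PC))] <- as.vector(dY)
  list(dX = dX, grads = NULL)
}

#' Zero-stuffing 2x upsampling (transposed-convolution front half)
#'
#' Input voxels land on the odd coordinates of a doubled grid; a stride-1
#' convolution after this layer realises a learned transposed convolution.
#' @keywords internal
#' @noRd
layer_upsample2 <- function(in_dims, cin) {
  in_dims <- as.integer(in_dims)
  out_dims <- 2L * in_dims
  nd <- length(in_dims)
  coord <- lapply(seq_len(nd), function(d) (0:(in_dims[d] - 1L)) * 2L)
  grid <- as.matrix(expand.grid(coord, KEEP.OUT.ATTRS = FALSE))
  lin <- rep(1L, nrow(grid)); mult <- 1L
  for (d in seq_len(nd)) { lin <- lin + grid[, d] * mult; mult <- mult * out_dims[d] }
  Vout <- as.integer(prod(out_dims))
  pos <- as.vector(vapply(seq_len(cin), function(c) lin + Vout * (c - 1L),
                          integer(length(lin))))
  list(type = "upsample2", in_dims = in_dims, out_dims = out_dims,
       cin = cin, Vout = Vout, pos = pos)
}

upsample2_forward <- function(ly, X) {
  out <- matrix(0, ly$Vout * ly$cin, ncol(X))
  out[ly$pos, ] <- X
  list(out = out, cache = NULL)
}

upsample2_backward <- function(ly, dY, cache, need_dx = TRUE) {
  list(dX = dY[ly$pos, , drop = FALSE], grads = NULL)
}

layer_forward <- function(ly, X) {
  switch(ly$type,
         conv = conv_forward(ly, X),
         deconv = deconv_forward(ly, X),
         dense = dense_forward(ly, X),
         lrelu = lrelu_forward(ly, X),
         sigmoid = sigmoid_forward(ly, X),
         maxpool = maxpool_forward(ly, X),
         upsample2 = upsample2_forward(ly, X),
         stop("unknown layer type ", ly$type))
}

layer_backward <- function(ly, dY, cache, need_dx = TRUE, need_grads = TRUE) {
  switch(ly$type,
         conv = conv_backward(ly, dY, cache, need_dx, need_grads),
         deconv = deconv_backward(ly, dY, cache, need_dx, need_grads),
         dense = dense_backward(ly, dY, cache, need_dx, need_grads),
         lrelu = lrelu_backward(ly, dY, cache, need_dx),
         sigmoid = sigmoid_backward(ly, dY, cache, need_dx),
         maxpool = maxpool_backward(ly, dY, cache, need_dx),
         upsample2 = upsample2_backward(ly, dY, cache, need_dx),
         stop("unknown layer type ", ly$type))
}

#' Run a sequential network forward
#'
#' @param net list of layers.
#' @param X (features x batch) matrix.
#' @param keep_cache cache intermediates for a later backward pass.
#' @return list with `out` and (if requested) `caches`.
#' @keywords internal
#' @noRd
net_forward <- function(net, X, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(net)) else NULL
  for (i in seq_along(net)) {
    fw <- layer_forward(net[[i]], X)
    X <- fw$out
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

#' Backward pass through a sequential network
#'
#' @param dOut upstream gradient at the output.
#' @param need_dx also propagate to the network input (for input gradients).
#' @return list with `grads` (per layer) and `dX`.
#' @keywords internal
#' @noRd
net_backward <- function(net, dOut, caches, need_dx = FALSE,
                         need_grads = TRUE) {
  grads <- vector("list", length(net))
  dY <- dOut
  for (i in rev(seq_along(net))) {
    want_dx <- need_dx || i > 1L
    bw <- layer_backward(net[[i]], dY, caches[[i]], need_dx = want_dx,
                         need_grads = need_grads)
    grads[i] <- list(bw$grads)
    dY <- bw$dX
  }
  list(grads = grads, dX = dY)
}

# ---- parameter bookkeeping ------------------------------------------------

net_params <- function(net) {
  out <- list()
  for (i in seq_along(net)) {
    ly <- net[[i]]
    if (!is.null(ly$W)) {
      out[[length(out) + 1L]] <- list(layer = i, name = "W")
      out[[length(out) + 1L]] <- list(layer = i, name = "b")
    }
  }
  out
}

net_get_param <- function(net, ref) net[[ref$layer]][[ref$name]]

net_n_params <- function(net) {
  sum(vapply(net_params(net), function(r) length(net_get_param(net, r)), numeric(1)))
}

# Accumulate a grads structure (possibly NULL entries) into another
grads_axpy <- function(acc, g, a = 1) {
  if (is.null(acc)) acc <- g
  else for (i in seq_along(g)) {
    if (!is.null(g[[i]])) {
      acc[[i]]$W <- acc[[i]]$W + a * g[[i]]$W
      acc[[i]]$b <- acc[[i]]$b + a * g[[i]]$b
    }
  }
  acc
}

grads_scale <- function(g, a) {
  for (i in seq_along(g)) {
    if (!is.null(g[[i]])) { g[[i]]$W <- g[[i]]$W * a; g[[i]]$b <- g[[i]]$b * a }
  }
  g
}

# ---- optimizers -----------------------------------------------------------

#' Adam optimizer state for a network
#' @keywords internal
#' @noRd
adam_init <- function(net, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- list(lr = lr, b1 = beta1, b2 = beta2, eps = eps, t = 0L,
             m = vector("list", length(net)), v = vector("list", length(net)))
  for (i in seq_along(net)) {
    if (!is.null(net[[i]]$W)) {
      st$m[[i]] <- list(W = net[[i]]$W * 0, b = net[[i]]$b * 0)
      st$v[[i]] <- list(W = net[[i]]$W * 0, b = net[[i]]$b * 0)
    }
  }
  st
}

adam_step <- function(net, grads, st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(net)) {
    if (is.null(grads[[i]])) next
    for (nm in c("W", "b")) {
      g <- grads[[i]][[nm]]
      st$m[[i]][[nm]] <- st$b1 * st$m[[i]][[nm]] + (1 - st$b1) * g
      st$v[[i]][[nm]] <- st$b2 * st$v[[i]][[nm]] + (1 - st$b2) * g^2
      mhat <- st$m[[i]][[nm]] / bc1
      vhat <- st$v[[i]][[nm]] / bc2
      net[[i]][[nm]] <- net[[i]][[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
    }
  }
  list(net = net, state = st)
}

#' SGD with momentum and weight decay
#' @keywords internal
#' @noRd
sgd_init <- function(net, lr = 1e-2, momentum = 0.9, weight_decay = 5e-4) {
  st <- list(lr = lr, mu = momentum, wd = weight_decay,
             v = vector("list", length(net)))
  for (i in seq_along(net)) {
    if (!is.null(net[[i]]$W)) {
      st$v[[i]] <- list(W = net[[i]]$W * 0, b = net[[i]]$b * 0)
    }
  }
  st
}

sgd_step <- function(net, grads, st) {
  for (i in seq_along(net)) {
    if (is.null(grads[[i]])) next
    for (nm in c("W", "b")) {
      g <- grads[[i]][[nm]] + st$wd * net[[i]][[nm]]
      st$v[[i]][[nm]] <- st$mu * st$v[[i]][[nm]] + g
      net[[i]][[nm]] <- net[[i]][[nm]] - st$lr * st$v[[i]][[nm]]
    }
  }
  list(net = net, state = st)
}
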