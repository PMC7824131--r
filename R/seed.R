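# Stage 1: seed-point detection cascade.
#
# Four 2D networks locate the fetal head centre (the dark diencephalon
# landmark): a U-Net with an ASPP bottleneck segments the landmark in the
# sagittal view (in-plane coordinates), two small object-detection networks
# place the head box in the axial and coronal views (through-plane
# coordinate), and a second segmentation network refines the through-plane
# coordinate in the axial view.  Slices are indexed on the volume's axes:
# sagittal = vol[x, , ] (image over y, z), axial = vol[, , z] (over x, y),
# coronal = vol[, y, ] (over x, z).

#' Seed-cascade architecture and training settings
#'
#' @param side slice side length (square slices; must be divisible by 4,
#'   the U-Net's downsampling factor).
#' @param seg_channels two encoder channel widths of the U-Net.
#' @param aspp_rates dilation rates of the parallel ASPP branches.
#' @param det_channels three conv widths of the detection networks.
#' @param seg_batch,det_batch training batch sizes (10 for segmentation,
#'   5 for detection).
#' @param seg_lr Adam learning rate for the segmentation networks.
#' @param det_lr,det_momentum,det_weight_decay SGD settings for the
#'   detection networks.
#' @param seg_steps,det_steps training iterations per network.
#' @return `msp_seed_config` list.
#' @export
seed_cascade_config <- function(side = 80L, seg_channels = c(8L, 16L),
                                aspp_rates = c(1L, 2L, 4L),
                                det_channels = c(8L, 16L, 16L),
                                seg_batch = 10L, det_batch = 5L,
                                seg_lr = 1e-3, det_lr = 1e-2,
                                det_momentum = 0.9, det_weight_decay = 5e-4,
                                seg_steps = 400L, det_steps = 300L) {
  side <- as.integer(side)
  if (side %% 4L != 0L)
    stop("config error: slice side must be divisible by 4", call. = FALSE)
  structure(list(side = side, seg_channels = as.integer(seg_channels),
                 aspp_rates = as.integer(aspp_rates),
                 det_channels = as.integer(det_channels),
                 seg_batch = as.integer(seg_batch),
                 det_batch = as.integer(det_batch),
                 seg_lr = seg_lr, det_lr = det_lr,
                 det_momentum = det_momentum,
                 det_weight_decay = det_weight_decay,
                 seg_steps = as.integer(seg_steps),
                 det_steps = as.integer(det_steps)),
            class = "msp_seed_config")
}

#' Build the U-Net + ASPP segmentation network
#'
#' Two-level encoder-decoder with skip connections and an atrous spatial
#' pyramid pooling block (parallel dilated convolutions, summed and fused)
#' at the bottleneck.  Output is a per-pixel probability map the same size
#' as the input slice.
#'
#' @param config an [seed_cascade_config()].
#' @return An `msp_unet` object.
#' @export
build_segmentation_net <- function(config = seed_cascade_config()) {
  s <- config$side
  c1 <- config$seg_channels[1]; c2 <- config$seg_channels[2]
  d1 <- c(s, s); d2 <- d1 %/% 2L; d4 <- d1 %/% 4L
  lk <- 0.2
  rates <- config$aspp_rates
  layers <- list(
    e1 = layer_conv(d1, 1L, c1, 3L, pad = 1L), e1a = layer_lrelu(lk),
    p1 = layer_maxpool(d1, c1),
    e2 = layer_conv(d2, c1, c2, 3L, pad = 1L), e2a = layer_lrelu(lk),
    p2 = layer_maxpool(d2, c2),
    a1 = layer_conv(d4, c2, c2, 3L, pad = rates[1], dilation = rates[1]),
    a2 = layer_conv(d4, c2, c2, 3L, pad = rates[2], dilation = rates[2]),
    a3 = layer_conv(d4, c2, c2, 3L, pad = rates[3], dilation = rates[3]),
    aa = layer_lrelu(lk),
    fuse = layer_conv(d4, c2, c2, 1L), fusea = layer_lrelu(lk),
    u1 = layer_upsample2(d4, c2),
    d1 = layer_conv(d2, c2 + c2, c1, 3L, pad = 1L), d1a = layer_lrelu(lk),
    u2 = layer_upsample2(d2, c1),
    d2 = layer_conv(d1, c1 + c1, c1, 3L, pad = 1L), d2a = layer_lrelu(lk),
    head = layer_conv(d1, c1, 1L, 1L)
  )
  layers$head$b[] <- -2    # sparse-foreground prior
  structure(list(layers = layers, side = s, c1 = c1, c2 = c2),
            class = "msp_unet")
}

run_seq <- function(layers, names, X, caches = NULL) {
  cl <- list()
  for (nm in names) {
    fw <- layer_forward(layers[[nm]], X)
    X <- fw$out
    cl[[nm]] <- fw$cache
  }
  list(out = X, caches = cl)
}

unet_forward <- function(net, X, keep_cache = TRUE) {
  ly <- net$layers
  s <- net$side
  f_e1 <- run_seq(ly, c("e1", "e1a"), X)
  f_p1 <- layer_forward(ly$p1, f_e1$out)
  f_e2 <- run_seq(ly, c("e2", "e2a"), f_p1$out)
  f_p2 <- layer_forward(ly$p2, f_e2$out)
  bt <- f_p2$out
  fa1 <- layer_forward(ly$a1, bt); fa2 <- layer_forward(ly$a2, bt)
  fa3 <- layer_forward(ly$a3, bt)
  faa <- layer_forward(ly$aa, fa1$out + fa2$out + fa3$out)
  f_fu <- run_seq(ly, c("fuse", "fusea"), faa$out)
  f_u1 <- layer_forward(ly$u1, f_fu$out)
  cat1 <- rbind(f_u1$out, f_e2$out)
  f_d1 <- run_seq(ly, c("d1", "d1a"), cat1)
  f_u2 <- layer_forward(ly$u2, f_d1$out)
  cat2 <- rbind(f_u2$out, f_e1$out)
  f_d2 <- run_seq(ly, c("d2", "d2a"), cat2)
  f_h <- layer_forward(ly$head, f_d2$out)
  out <- 1 / (1 + exp(-f_h$out))
  caches <- NULL
  if (keep_cache)
    caches <- list(e1 = f_e1$caches, p1 = f_p1$cache, e2 = f_e2$caches,
                   p2 = f_p2$cache, a1 = fa1$cache, a2 = fa2$cache,
                   a3 = fa3$cache, aa = faa$cache, fu = f_fu$caches,
                   u1 = NULL, d1 = f_d1$caches, u2 = NULL,
                   d2 = f_d2$caches, head = f_h$cache, out = out,
                   n_e1 = nrow(f_e1$out), n_u1 = nrow(f_u1$out),
                   n_u2 = nrow(f_u2$out))
  list(out = out, caches = caches)
}

# backward through the U-Net; dOut is w.r.t. the sigmoid output
unet_backward <- function(net, dOut, cc) {
  ly <- net$layers
  g <- list()
  dlogit <- dOut * cc$out * (1 - cc$out)
  bh <- layer_backward(ly$head, dlogit, cc$head); g$head <- bh$grads
  b <- layer_backward(ly$d2a, bh$dX, cc$d2$d2a)
  b <- layer_backward(ly$d2, b$dX, cc$d2$d2); g$d2 <- b$grads
  d_cat2 <- b$dX
  d_u2 <- d_cat2[seq_len(cc$n_u2), , drop = FALSE]
  d_e1_skip <- d_cat2[-seq_len(cc$n_u2), , drop = FALSE]
  b <- layer_backward(ly$u2, d_u2, NULL)
  b <- layer_backward(ly$d1a, b$dX, cc$d1$d1a)
  b <- layer_backward(ly$d1, b$dX, cc$d1$d1); g$d1 <- b$grads
  d_cat1 <- b$dX
  d_u1 <- d_cat1[seq_len(cc$n_u1), , drop = FALSE]
  d_e2_skip <- d_cat1[-seq_len(cc$n_u1), , drop = FALSE]
  b <- layer_backward(ly$u1, d_u1, NULL)
  b <- layer_backward(ly$fusea, b$dX, cc$fu$fusea)
  b <- layer_backward(ly$fuse, b$dX, cc$fu$fuse); g$fuse <- b$grads
  b <- layer_backward(ly$aa, b$dX, cc$aa)
  daspp <- b$dX
  b1 <- layer_backward(ly$a1, daspp, cc$a1); g$a1 <- b1$grads
  b2 <- layer_backward(ly$a2, daspp, cc$a2); g$a2 <- b2$grads
  b3 <- layer_backward(ly$a3, daspp, cc$a3); g$a3 <- b3$grads
  dbt <- b1$dX + b2$dX + b3$dX
  b <- layer_backward(ly$p2, dbt, cc$p2)
  b <- layer_backward(ly$e2a, b$dX, cc$e2$e2a)
  b <- layer_backward(ly$e2, b$dX + 0, cc$e2$e2); g$e2 <- b$grads
  d_e2_in <- b$dX
  # skip gradient joins after e2a: recompute path through e2a backward
  b_skip <- layer_backward(ly$e2a, d_e2_skip, cc$e2$e2a)
  b_skip <- layer_backward(ly$e2, b_skip$dX, cc$e2$e2)
  g$e2$W <- g$e2$W + b_skip$grads$W; g$e2$b <- g$e2$b + b_skip$grads$b
  d_p1 <- d_e2_in + b_skip$dX
  b <- layer_backward(ly$p1, d_p1, cc$p1)
  d_e1a <- b$dX + d_e1_skip
  b <- layer_backward(ly$e1a, d_e1a, cc$e1$e1a)
  b <- layer_backward(ly$e1, b$dX, cc$e1$e1); g$e1 <- b$grads
  g
}

# flat parameter refs for the optimizer: named conv layers of the U-Net
unet_param_layers <- c("e1", "e2", "a1", "a2", "a3", "fuse", "d1", "d2", "head")

unet_adam_init <- function(net, lr) {
  st <- list(lr = lr, b1 = 0.9, b2 = 0.999, eps = 1e-8, t = 0L,
             m = list(), v = list())
  for (nm in unet_param_layers) {
    st$m[[nm]] <- list(W = net$layers[[nm]]$W * 0, b = net$layers[[nm]]$b * 0)
    st$v[[nm]] <- st$m[[nm]]
  }
  st
}

unet_adam_step <- function(net, grads, st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$b1^st$t; bc2 <- 1 - st$b2^st$t
  for (nm in unet_param_layers) {
    for (pn in c("W", "b")) {
      gr <- grads[[nm]][[pn]]
      st$m[[nm]][[pn]] <- st$b1 * st$m[[nm]][[pn]] + (1 - st$b1) * gr
      st$v[[nm]][[pn]] <- st$b2 * st$v[[nm]][[pn]] + (1 - st$b2) * gr^2
      net$layers[[nm]][[pn]] <- net$layers[[nm]][[pn]] -
        st$lr * (st$m[[nm]][[pn]] / bc1) / (sqrt(st$v[[nm]][[pn]] / bc2) + st$eps)
    }
  }
  list(net = net, state = st)
}

#' Predict a segmentation probability map for a batch of slices
#'
#' @param net an `msp_unet`.
#' @param slices matrix (side^2 x batch) of flattened slices, or one slice
#'   matrix.
#' @return Probability maps, same shape as the input.
#' @export
predict_segmentation <- function(net, slices) {
  one <- is.matrix(slices) && ncol(slices) == nrow(slices)  # a single image?
  X <- if (is.matrix(slices) && nrow(slices) == net$side^2) slices
       else matrix(as.vector(slices), ncol = 1L)
  out <- unet_forward(net, X, keep_cache = FALSE)$out
  if (ncol(out) == 1L && one) matrix(out, net$side, net$side) else out
}

#' Build an object-detection network
#'
#' Three stride-2 convolutions followed by two dense layers; the output is
#' `(objectness logit, cx, cy, w, h)` with box coordinates normalized by the
#' slice side.
#'
#' @param config an [seed_cascade_config()].
#' @return An `msp_net` sequential network.
#' @export
build_detection_net <- function(config = seed_cascade_config()) {
  s <- config$side
  ch <- config$det_channels
  if (s %% 8L != 0L)
    stop("config error: detection input must be divisible by 8", call. = FALSE)
  d1 <- c(s, s); d2 <- d1 %/% 2L; d4 <- d1 %/% 4L; d8 <- d1 %/% 8L
  net <- list(
    layer_conv(d1, 1L, ch[1], 3L, stride = 2L, pad = 1L), layer_lrelu(0.2),
    layer_conv(d2, ch[1], ch[2], 3L, stride = 2L, pad = 1L), layer_lrelu(0.2),
    layer_conv(d4, ch[2], ch[3], 3L, stride = 2L, pad = 1L), layer_lrelu(0.2),
    layer_dense(prod(d8) * ch[3], 64L), layer_lrelu(0.2),
    layer_dense(64L, 5L, init_gain = 1)
  )
  structure(net, class = "msp_net", side = s)
}

#' Predict a head bounding box on a slice
#'
#' @param net a detection network.
#' @param slice matrix (side x side) image.
#' @return List with `objectness` (probability), `center` (length-2, pixel
#'   units, clamped to the slice) and `size` (length-2, pixels).
#' @export
predict_box <- function(net, slice) {
  s <- attr(net, "side")
  out <- net_forward(net, matrix(as.vector(slice), ncol = 1L),
                     keep_cache = FALSE)$out[, 1]
  ctr <- clamp(out[2:3], 0, 1) * (s - 1)
  sz <- clamp(out[4:5], 0, 1) * s
  list(objectness = 1 / (1 + exp(-out[1])), center = ctr, size = sz)
}

huber <- function(r, delta = 1) {
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta))
}

dhuber <- function(r, delta = 1) clamp(r, -delta, delta)

# one SGD step of the detection loss: BCE(objectness) + Huber(box | positive)
detection_step <- function(net, st, X, obj, boxes) {
  B <- ncol(X)
  fw <- net_forward(net, X, keep_cache = TRUE)
  out <- fw$out
  p <- 1 / (1 + exp(-out[1, ]))
  dOut <- matrix(0, 5L, B)
  dOut[1, ] <- (p - obj) / B
  pos <- obj > 0.5
  if (any(pos)) {
    r <- out[2:5, pos, drop = FALSE] - boxes[, pos, drop = FALSE]
    dOut[2:5, pos] <- dhuber(r) / B
  }
  bw <- net_backward(net, dOut, fw$caches, need_dx = FALSE)
  stp <- sgd_step(net, bw$grads, st)
  loss <- mean(-obj * log(pmax(p, 1e-12)) - (1 - obj) * log(pmax(1 - p, 1e-12)))
  if (any(pos))
    loss <- loss + sum(huber(out[2:5, pos, drop = FALSE] -
                             boxes[, pos, drop = FALSE])) / B
  list(net = stp$net, state = stp$state, loss = loss)
}

# slice extractors (flattened column vectors)
slice_sag <- function(vol, x) as.vector(vol[x, , ])
slice_axi <- function(vol, z) as.vector(vol[, , z])
slice_cor <- function(vol, y) as.vector(vol[, y, ])

# assemble segmentation training slices (sagittal or axial view)
seg_training_set <- function(phantoms, view = c("sagittal", "axial")) {
  view <- match.arg(view)
  xs <- list(); ys <- list()
  for (s in phantoms) {
    dims <- dim(s$volume)
    if (view == "sagittal") {
      mid <- round_half_up(dims[1] / 2)
      at <- unique(clamp(c(mid, round_half_up(s$gt_seed[1]) + c(0L, -2L, 2L)),
                         1L, dims[1]))
      for (i in at) {
        xs[[length(xs) + 1L]] <- slice_sag(s$volume, i)
        ys[[length(ys) + 1L]] <- slice_sag(s$head_label, i)
      }
    } else {
      mid <- round_half_up(dims[3] / 2)
      at <- unique(clamp(c(mid, round_half_up(s$gt_seed[3]) + c(0L, -2L, 2L)),
                         1L, dims[3]))
      for (i in at) {
        xs[[length(xs) + 1L]] <- slice_axi(s$volume, i)
        ys[[length(ys) + 1L]] <- slice_axi(s$head_label, i)
      }
    }
  }
  list(x = do.call(cbind, xs), y = do.call(cbind, ys))
}

# detection training set: positive view slices with head boxes + noise-only
# negatives.  axes: which two volume axes span the slice, in image order.
det_training_set <- function(phantoms, view = c("axial", "coronal")) {
  view <- match.arg(view)
  xs <- list(); boxes <- list(); obj <- c()
  for (s in phantoms) {
    dims <- dim(s$volume)
    side <- dims[1]
    if (view == "axial") {
      at <- unique(clamp(round_half_up(s$gt_seed[3]) + c(0L, -3L, 3L), 1L, dims[3]))
      ax <- c(1L, 2L)
      sl <- lapply(at, function(i) slice_axi(s$volume, i))
    } else {
      at <- unique(clamp(round_half_up(s$gt_seed[2]) + c(0L, -3L, 3L), 1L, dims[2]))
      ax <- c(1L, 3L)
      sl <- lapply(at, function(i) slice_cor(s$volume, i))
    }
    lo <- s$head_bbox["lo", ax]; hi <- s$head_bbox["hi", ax]
    bx <- c((lo + hi) / 2 / (side - 1), (hi - lo) / side)
    for (im in sl) {
      xs[[length(xs) + 1L]] <- im
      boxes[[length(boxes) + 1L]] <- bx
      obj <- c(obj, 1)
    }
    # speckle-only negative
    xs[[length(xs) + 1L]] <- clamp(stats::rgamma(side^2, 2, 2) * 0.07, 0, 1)
    boxes[[length(boxes) + 1L]] <- rep(0, 4)
    obj <- c(obj, 0)
  }
  list(x = do.call(cbind, xs), boxes = do.call(cbind, boxes), obj = obj)
}

#' Train the seed-detection cascade
#'
#' Trains the sagittal and axial segmentation U-Nets with Adam and binary
#' cross-entropy, and the axial and coronal detection networks with
#' momentum-SGD (weight decay 5e-4, momentum 0.9) on cross-entropy plus
#' Huber loss.  Slice labels and head boxes come from the phantoms'
#' ground-truth annotations.  Deterministic given `seed`.
#'
#' @param phantoms list of `msp_phantom` samples.
#' @param config an [seed_cascade_config()] whose `side` matches the
#'   phantom extents.
#' @param seed integer RNG seed.
#' @param verbose print progress.
#' @return `msp_seed_models`: the four trained networks plus the final
#'   training losses.
#' @export
train_seed_networks <- function(phantoms, config = seed_cascade_config(),
                                seed = 1L, verbose = FALSE) {
  if (length(phantoms) < 1L) stop("empty training set", call. = FALSE)
  stopifnot(all(dim(phantoms[[1]]$volume) == config$side))
  local_seed(seed, {
    losses <- list()
    nets <- list()
    for (view in c("sagittal", "axial")) {
      ts <- seg_training_set(phantoms, view)
      net <- build_segmentation_net(config)
      st <- unet_adam_init(net, config$seg_lr)
      N <- ncol(ts$x)
      lv <- numeric(config$seg_steps)
      for (it in seq_len(config$seg_steps)) {
        sel <- sample.int(N, min(config$seg_batch, N))
        X <- ts$x[, sel, drop = FALSE]; Y <- ts$y[, sel, drop = FALSE]
        fw <- unet_forward(net, X, keep_cache = TRUE)
        p <- clamp(fw$out, 1e-7, 1 - 1e-7)
        lv[it] <- mean(-Y * log(p) - (1 - Y) * log(1 - p))
        dOut <- (-Y / p + (1 - Y) / (1 - p)) / length(p)
        gr <- unet_backward(net, dOut, fw$caches)
        stp <- unet_adam_step(net, gr, st)
        net <- stp$net; st <- stp$state
        if (verbose && it %% 100L == 0L)
          message(sprintf("seg[%s] step %d: bce %.4f", view, it, lv[it]))
      }
      nets[[paste0("seg_", view)]] <- net
      losses[[paste0("seg_", view)]] <- lv
    }
    for (view in c("axial", "coronal")) {
      ts <- det_training_set(phantoms, view)
      net <- build_detection_net(config)
      st <- sgd_init(net, lr = config$det_lr, momentum = config$det_momentum,
                     weight_decay = config$det_weight_decay)
      N <- ncol(ts$x)
      lv <- numeric(config$det_steps)
      for (it in seq_len(config$det_steps)) {
        sel <- sample.int(N, min(config$det_batch, N))
        stp <- detection_step(net, st, ts$x[, sel, drop = FALSE],
                              ts$obj[sel], ts$boxes[, sel, drop = FALSE])
        net <- stp$net; st <- stp$state; lv[it] <- stp$loss
        if (verbose && it %% 100L == 0L)
          message(sprintf("det[%s] step %d: loss %.4f", view, it, lv[it]))
      }
      nets[[paste0("det_", view)]] <- net
      losses[[paste0("det_", view)]] <- lv
    }
    structure(c(nets, list(config = config, losses = losses)),
              class = "msp_seed_models")
  })
}

detection_failure <- function(stage, msg) {
  stop(structure(class = c("msp_detection_failure", "error", "condition"),
                 list(message = sprintf("seed detection failed at stage %d: %s",
                                        stage, msg),
                      call = NULL, stage = stage)))
}

# weighted centroid of a probability map (pixels above half its maximum)
prob_centroid <- function(pmap, min_peak = 0.15) {
  mx <- max(pmap)
  if (!is.finite(mx) || mx < min_peak) return(NULL)
  sel <- which(pmap >= mx / 2)
  idx <- arrayInd(sel, dim(pmap)) - 1L
  w <- pmap[sel] / sum(pmap[sel])
  colSums(idx * w)
}

#' Detect the fetal-head seed point
#'
#' Five-step cascade: (1) sagittal segmentation at the central slice gives
#' the in-plane coordinates (y, z); (2) axial-view detection and (3)
#' coronal-view detection give the through-plane coordinate x; (4) sagittal
#' segmentation re-runs at the updated x to refine (y, z); (5) the axial
#' segmentation network refines x at the refined z.  Raises an
#' `msp_detection_failure` condition (carrying the stage index) if any
#' stage finds no head.
#'
#' @param volume 3D array (cube with side = the models' slice side).
#' @param models an `msp_seed_models` from [train_seed_networks()].
#' @param obj_threshold minimum detection objectness.
#' @return Numeric length-3 seed point (continuous voxel coordinates).
#' @export
detect_seed <- function(volume, models, obj_threshold = 0.5) {
  stopifnot(inherits(models, "msp_seed_models"))
  dims <- dim(volume)
  # step 1: sagittal segmentation at the central left-right slice
  x0 <- round_half_up(dims[1] / 2)
  pm <- matrix(predict_segmentation(models$seg_sagittal,
                                    matrix(slice_sag(volume, x0), ncol = 1L)),
               dims[2], dims[3])
  ctr <- prob_centroid(pm)
  if (is.null(ctr)) detection_failure(1L, "empty sagittal segmentation")
  y <- ctr[1]; z <- ctr[2]
  # step 2: axial detection -> x
  bx_a <- predict_box(models$det_axial,
                      matrix(slice_axi(volume, clamp(round_half_up(z) + 1L, 1L, dims[3])),
                             dims[1], dims[2]))
  if (bx_a$objectness < obj_threshold)
    detection_failure(2L, "no head box in the axial view")
  # step 3: coronal detection -> x
  bx_c <- predict_box(models$det_coronal,
                      matrix(slice_cor(volume, clamp(round_half_up(y) + 1L, 1L, dims[2])),
                             dims[1], dims[3]))
  if (bx_c$objectness < obj_threshold)
    detection_failure(3L, "no head box in the coronal view")
  x <- (bx_a$center[1] + bx_c$center[1]) / 2
  # step 4: refine (y, z) at the detected x
  pm <- matrix(predict_segmentation(models$seg_sagittal,
                                    matrix(slice_sag(volume, clamp(round_half_up(x) + 1L, 1L, dims[1])),
                                           ncol = 1L)),
               dims[2], dims[3])
  ctr <- prob_centroid(pm)
  if (is.null(ctr)) detection_failure(4L, "empty sagittal refinement")
  y <- ctr[1]; z <- ctr[2]
  # step 5: refine x with the axial segmentation at the refined z
  pm <- matrix(predict_segmentation(models$seg_axial,
                                    matrix(slice_axi(volume, clamp(round_half_up(z) + 1L, 1L, dims[3])),
                                           ncol = 1L)),
               dims[1], dims[2])
  ctr <- prob_centroid(pm)
  if (is.null(ctr)) detection_failure(5L, "empty axial refinement")
  c(x = as.numeric(ctr[1]), y = as.numeric(y), z = as.numeric(z))
}
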