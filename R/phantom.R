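# Synthetic fetal-head phantoms.
#
# Each phantom is an ellipsoidal bright shell ("skull") containing a dark
# central blob (the diencephalon landmark at the seed point), pairs of bright
# internal features placed mirror-symmetrically about a known ground-truth
# plane, and one asymmetric "nose" marker indicating which way the head
# faces.  The plane is tilted by theta_axi / theta_cor within a configurable
# envelope; degradation is a Gaussian blur followed by multiplicative
# gamma-distributed speckle.  Geometry parameters (shell at ~0.35 of the
# smallest extent, blob at ~0.07) are test fixtures, not anatomical claims.

#' Phantom generation settings
#'
#' @param dims integer length-3 volume extents in voxels (>= 16 per axis).
#' @param angle_limit maximum absolute tilt (degrees) for both labelling
#'   angles; 30 by default, matching the usual inclusion baseline.
#' @param noise_level variance of the unit-mean multiplicative speckle
#'   factor (0 disables noise).
#' @param head_side `"left"`, `"right"` or `"random"`: which half of axis 2
#'   the nose marker points to.
#' @param rng_seed integer seed; generation is fully deterministic given it.
#' @return A list of class `msp_phantom_spec`.
#' @export
phantom_spec <- function(dims = c(80L, 80L, 80L), angle_limit = 30,
                         noise_level = 0.05, head_side = "random",
                         rng_seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 16L))
    stop("invalid spec: dims must be 3 extents of at least 16 voxels", call. = FALSE)
  stopifnot(angle_limit >= 0, noise_level >= 0,
            head_side %in% c("left", "right", "random"))
  structure(list(dims = dims, angle_limit = angle_limit,
                 noise_level = noise_level, head_side = head_side,
                 rng_seed = as.integer(rng_seed)),
            class = "msp_phantom_spec")
}

#' Generate one synthetic fetal-head phantom
#'
#' Deterministic given `spec$rng_seed`.  The ground-truth plane passes
#' through the seed point; its mask is the 0.5-voxel rasterization; the
#' `head_label` mask (the dark blob region) is the segmentation target for
#' seed-point training, and `head_bbox` the detection target.
#'
#' @param spec an [phantom_spec()] object.
#' @return A list of class `msp_phantom` with elements `volume`, `gt_plane`,
#'   `gt_seed`, `gt_mask`, `theta_axi`, `theta_cor`, `head_side`,
#'   `head_label`, `head_bbox` (2 x 3 matrix of 0-based lo/hi voxel bounds),
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "msp_phantom_spec"))
  local_seed(spec$rng_seed, {
    dims <- spec$dims
    m <- min(dims)
    ctr <- (dims - 1) / 2
    seed_pt <- ctr + stats::runif(3, -0.05 * m, 0.05 * m)
    theta_axi <- stats::runif(1, -spec$angle_limit, spec$angle_limit)
    theta_cor <- stats::runif(1, -spec$angle_limit, spec$angle_limit)
    side <- if (spec$head_side == "random")
      sample(c("left", "right"), 1L) else spec$head_side
    gt_plane <- plane_from_angles(seed_pt, theta_axi, theta_cor)

    # canonical head frame: u = R^T (p - seed), with R (1,0,0) = plane normal
    un <- plane_unit_normal(gt_plane)$n
    R <- rotation_between(c(1, 0, 0), un)
    grid <- as.matrix(expand.grid(x = 0:(dims[1] - 1L), y = 0:(dims[2] - 1L),
                                  z = 0:(dims[3] - 1L)))
    U <- sweep(grid, 2L, seed_pt) %*% R   # rows: (ux, uy, uz)

    radii <- c(0.28, 0.35, 0.32) * m
    q <- sqrt((U[, 1] / radii[1])^2 + (U[, 2] / radii[2])^2 +
              (U[, 3] / radii[3])^2)
    vol <- 0.05 + 0.30 * (q < 1) + 0.55 * exp(-((q - 1) / 0.06)^2)

    # dark central blob (diencephalon) at the seed point
    rb <- 0.07 * m
    r0 <- sqrt(rowSums(U^2))
    vol <- vol - 0.30 * exp(-(r0 / rb)^2)

    # mirror-symmetric feature pairs about ux = 0
    n_feat <- 4L
    for (i in seq_len(n_feat)) {
      fpos <- c(stats::runif(1, 0.08, 0.20),
                stats::runif(1, -0.20, 0.20),
                stats::runif(1, -0.20, 0.20)) * m
      for (sgn in c(1, -1)) {
        fp <- fpos * c(sgn, 1, 1)
        d2 <- (U[, 1] - fp[1])^2 + (U[, 2] - fp[2])^2 + (U[, 3] - fp[3])^2
        vol <- vol + 0.25 * exp(-d2 / (0.05 * m)^2)
      }
    }

    # asymmetric nose marker on the head side (on the plane, off-centre in y,
    # clearly outside the skull shell so the side is salient)
    sgn_side <- if (side == "left") -1 else 1
    npos <- c(0, sgn_side * 1.15 * radii[2], 0)
    d2 <- (U[, 1] - npos[1])^2 + (U[, 2] - npos[2])^2 + (U[, 3] - npos[3])^2
    vol <- vol + 0.55 * exp(-d2 / (0.07 * m)^2)

    vol <- array(vol, dims)
    head_label <- array(as.numeric(r0 <= rb), dims)
    inside <- which(array(q <= 1.1, dims), arr.ind = TRUE) - 1L
    head_bbox <- rbind(lo = apply(inside, 2L, min), hi = apply(inside, 2L, max))

    vol <- gaussian_blur3(vol, sigma = 0.8)
    if (spec$noise_level > 0) {
      shape <- 1 / spec$noise_level
      speckle <- stats::rgamma(length(vol), shape = shape, rate = shape)
      vol <- vol * array(speckle, dims)
    }
    vol <- clamp(vol, 0, 1)

    structure(list(volume = vol, gt_plane = gt_plane, gt_seed = seed_pt,
                   gt_mask = rasterize_plane(gt_plane, dims, 0.5),
                   theta_axi = theta_axi, theta_cor = theta_cor,
                   head_side = side, head_label = head_label,
                   head_bbox = head_bbox, spec = spec),
              class = "msp_phantom")
  })
}

#' @export
print.msp_phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%dx%d, theta_axi %.1f deg, theta_cor %.1f deg, head %s\n",
              dim(x$volume)[1], dim(x$volume)[2], dim(x$volume)[3],
              x$theta_axi, x$theta_cor, x$head_side))
  invisible(x)
}

#' Generate a phantom dataset
#'
#' Draws `n` phantoms with independent per-sample seeds derived
#' deterministically from `spec$rng_seed`; tilt angles are uniform on
#' `[-angle_limit, angle_limit]`.
#'
#' @param n number of phantoms (>= 1).
#' @param spec an [phantom_spec()]; its `rng_seed` seeds the whole dataset.
#' @return List of `msp_phantom` samples.
#' @export
generate_dataset <- function(n, spec) {
  stopifnot(n >= 1L, inherits(spec, "msp_phantom_spec"))
  seeds <- local_seed(spec$rng_seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i) {
    si <- spec
    si$rng_seed <- seeds[i]
    generate_phantom(si)
  })
}
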