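# Plane geometry in voxel space.
#
# A plane is the 4-vector (a, b, c, d) of a x + b y + c z + d = 0 in 0-based
# voxel coordinates.  Axis 1 (x) is the left-right axis, so a mid-sagittal
# plane has its normal dominantly along x; axes 2-3 are the in-plane sagittal
# coordinates.  Planes are stored unit-norm over all four coefficients with
# the first nonzero component of the normal (a, b, c) positive, which makes
# coefficient-space metrics (included angle, Euclidean distance) well defined.

#' Normalize raw plane coefficients
#'
#' Scales a raw coefficient 4-vector to unit Euclidean norm and applies the
#' sign convention that the first nonzero component of the normal
#' `(a, b, c)` is positive, so every geometric plane has exactly one
#' representation.  Idempotent.
#'
#' @param coeffs numeric length-4 vector `(a, b, c, d)` of
#'   `a*x + b*y + c*z + d = 0` in voxel coordinates.
#' @return An object of class `msp_plane`: a named unit-norm 4-vector.
#' @examples
#' normalize_plane(c(2, 0, 0, 0))
#' normalize_plane(c(-1, 0, 0, 3))
#' @export
normalize_plane <- function(coeffs) {
  coeffs <- as.numeric(unclass(coeffs))
  if (length(coeffs) != 4L || !all(is.finite(coeffs)))
    stop("plane coefficients must be 4 finite numbers", call. = FALSE)
  n <- coeffs[1:3]
  if (max(abs(n)) < 1e-12)
    stop("invalid plane: degenerate normal (a = b = c = 0)", call. = FALSE)
  lead <- n[which(abs(n) > 1e-12)[1]]
  if (lead < 0) coeffs <- -coeffs
  coeffs <- coeffs / sqrt(sum(coeffs^2))
  structure(stats::setNames(coeffs, c("a", "b", "c", "d")), class = "msp_plane")
}

#' @export
print.msp_plane <- function(x, ...) {
  cat(sprintf("<plane> %.4fx + %.4fy + %.4fz + %.4f = 0\n",
              x[["a"]], x[["b"]], x[["c"]], x[["d"]]))
  invisible(x)
}

is_plane <- function(x) inherits(x, "msp_plane")

as_plane <- function(x) {
  if (is_plane(x)) x else normalize_plane(x)
}

# unit 3-normal and matching offset (a,b,c)/|n|, d/|n|
plane_unit_normal <- function(plane) {
  p <- as_plane(plane)
  nn <- sqrt(sum(p[1:3]^2))
  list(n = as.numeric(p[1:3]) / nn, d = as.numeric(p[[4]]) / nn)
}

#' Re-express a plane relative to a new origin
#'
#' Returns the same geometric plane in coordinates translated so that
#' `origin` becomes `(0, 0, 0)`.  Pair metrics on coefficient 4-vectors
#' depend on the chosen origin (the offset `d` scales with it); the labelling
#' convention used throughout places the origin at the seed point / crop
#' centre, which keeps `d` small and the 4-vector dominated by the normal.
#'
#' @param plane an [normalize_plane()] plane (or raw 4-vector).
#' @param origin numeric length-3 point in voxel coordinates.
#' @return A normalized `msp_plane` in the shifted frame.
#' @export
recenter_plane <- function(plane, origin) {
  p <- as_plane(plane)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  normalize_plane(c(p[1:3], p[[4]] + sum(p[1:3] * origin)))
}

#' Construct a plane from a seed point and two labelling angles
#'
#' Mirrors the manual labelling convention: the sagittal plane through the
#' seed point (normal along the left-right axis `x`) is tilted by
#' `theta_axi` as seen on axial planes, then by `theta_cor` as seen on
#' coronal planes.  Concretely the normal is
#' `Ry(theta_cor) %*% Rz(theta_axi) %*% c(1, 0, 0)`, which makes the yaw
#' angle of the resulting plane equal `theta_axi` exactly and its roll angle
#' approximately `theta_cor`.
#'
#' @param seed numeric length-3 seed point (voxels).
#' @param theta_axi,theta_cor tilt angles in degrees.
#' @return An `msp_plane` passing through `seed`.
#' @seealso [angles_from_plane()] for the exact inverse.
#' @export
plane_from_angles <- function(seed, theta_axi, theta_cor) {
  seed <- as.numeric(seed)
  stopifnot(length(seed) == 3L, is.finite(theta_axi), is.finite(theta_cor))
  ta <- theta_axi * pi / 180
  tc <- theta_cor * pi / 180
  n <- c(cos(tc) * cos(ta), sin(ta), -sin(tc) * cos(ta))
  normalize_plane(c(n, -sum(n * seed)))
}

#' Recover labelling angles from a plane
#'
#' Exact inverse of [plane_from_angles()] for tilt magnitudes below 90
#' degrees.
#'
#' @param plane an `msp_plane` (or raw 4-vector).
#' @return Named numeric vector `c(theta_axi =, theta_cor =)` in degrees.
#' @export
angles_from_plane <- function(plane) {
  un <- plane_unit_normal(plane)
  n <- un$n
  if (n[1] < 0) n <- -n
  c(theta_axi = asin(pmin(1, pmax(-1, n[2]))) * 180 / pi,
    theta_cor = atan2(-n[3], n[1]) * 180 / pi)
}

#' Rasterize a plane into a binary 3D mask
#'
#' A voxel is set to one iff the perpendicular distance from its centre
#' (0-based integer coordinates) to the plane is at most `half_thickness`,
#' giving a one-voxel-thick digital plane at the default.
#'
#' @param plane an `msp_plane` (or raw 4-vector).
#' @param dims integer length-3 volume extents.
#' @param half_thickness positive scalar, voxels.
#' @return A 3D 0/1 array of dimension `dims`.  If the plane misses the
#'   volume box entirely the mask is all zero and a warning is raised.
#' @export
rasterize_plane <- function(plane, dims, half_thickness = 0.5) {
  p <- as_plane(plane)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), half_thickness > 0)
  un <- plane_unit_normal(p)
  ax <- un$n[1] * (0:(dims[1] - 1L))
  by <- un$n[2] * (0:(dims[2] - 1L))
  cz <- un$n[3] * (0:(dims[3] - 1L))
  sg <- outer(outer(ax, by, "+"), cz, "+") + un$d
  mask <- array(0, dims)
  mask[abs(sg) <= half_thickness] <- 1
  if (sum(mask) == 0)
    warning("plane does not intersect the volume; mask is all zero", call. = FALSE)
  mask
}

#' Fit a plane to a (soft) 3D mask by weighted total least squares
#'
#' Voxels above `threshold` are treated as a weighted point cloud (weights =
#' mask values); the plane normal is the singular vector of the centred,
#' weight-scaled scatter with the smallest singular value, and the plane
#' passes through the weighted centroid.
#'
#' @param mask 3D numeric array (soft values in `[0, 1]` or binary).
#' @param threshold support threshold (default 0.5).
#' @return A normalized `msp_plane`.
#' @export
fit_plane_from_mask <- function(mask, threshold = 0.5) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  sel <- which(mask > threshold)
  if (length(sel) < 3L)
    stop("insufficient support: fewer than 3 voxels above threshold", call. = FALSE)
  idx <- arrayInd(sel, dim(mask)) - 1L   # 0-based voxel centres
  w <- as.numeric(mask[sel])
  w <- w / sum(w)
  ctr <- colSums(idx * w)
  X <- sweep(idx, 2L, ctr) * sqrt(w)
  sv <- svd(X, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate fit: mask support is collinear", call. = FALSE)
  n <- sv$v[, 3]
  normalize_plane(c(n, -sum(n * ctr)))
}

#' Rigid transform mapping one plane onto another
#'
#' Decomposes the plane-to-plane map as `M = T R`: `R` is the minimal
#' rotation taking the initial plane's unit normal onto the target's, and
#' `T` translates the rotated plane onto the target along the target normal.
#' Points on the initial plane land on the target plane.
#'
#' @param initial,target planes (`msp_plane` or raw 4-vectors).
#' @return An object of class `msp_rigid_transform` with elements `R`
#'   (3x3 rotation) and `T` (length-3 translation, voxels).
#' @export
transform_between_planes <- function(initial, target) {
  u1 <- plane_unit_normal(initial)
  u2 <- plane_unit_normal(target)
  R <- rotation_between(u1$n, u2$n)
  Tt <- (u1$d - u2$d) * u2$n
  structure(list(R = R, T = Tt), class = "msp_rigid_transform")
}

# minimal rotation taking unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(cr^2))
  cth <- sum(u * v)
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    # antiparallel: 180 degrees about any axis perpendicular to u
    axis <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * u) * u
    axis <- axis / sqrt(sum(axis^2))
    return(2 * tcrossprod(axis) - diag(3))
  }
  k <- cr / s
  Kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + s * Kx + (1 - cth) * (Kx %*% Kx)
}

#' Apply a rigid transform to points
#'
#' @param transform an `msp_rigid_transform`.
#' @param points numeric matrix (n x 3) or length-3 vector, voxel coordinates.
#' @return Transformed points, same shape as the input.
#' @export
apply_rigid_transform <- function(transform, points) {
  stopifnot(inherits(transform, "msp_rigid_transform"))
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, 1L, 3L) else as.matrix(points)
  out <- pts %*% t(transform$R)
  out <- sweep(out, 2L, transform$T, "+")
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#' @param transform an `msp_rigid_transform`.
#' @return The inverse `msp_rigid_transform`.
#' @export
invert_rigid_transform <- function(transform) {
  Rinv <- t(transform$R)
  structure(list(R = Rinv, T = -as.numeric(Rinv %*% transform$T)),
            class = "msp_rigid_transform")
}

# signed perpendicular distances of points (n x 3) to a plane
plane_point_distance <- function(plane, points) {
  un <- plane_unit_normal(plane)
  pts <- if (is.null(dim(points))) matrix(points, 1L, 3L) else as.matrix(points)
  as.numeric(pts %*% un$n + un$d)
}

plane_intersects_box <- function(plane, dims) {
  crn <- as.matrix(expand.grid(c(0, dims[1] - 1), c(0, dims[2] - 1),
                               c(0, dims[3] - 1)))
  d <- plane_point_distance(plane, crn)
  min(d) <= 0 && max(d) >= 0
}

#' Trilinear (or nearest-neighbour) sampling of a volume
#'
#' @param volume 3D numeric array.
#' @param points n x 3 matrix of 0-based voxel coordinates.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return Numeric vector of sampled intensities; points outside the volume
#'   sample as 0.
#' @export
sample_volume <- function(volume, points, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dims <- dim(volume)
  pts <- as.matrix(points)
  ok <- pts[, 1] >= 0 & pts[, 1] <= dims[1] - 1 &
        pts[, 2] >= 0 & pts[, 2] <= dims[2] - 1 &
        pts[, 3] >= 0 & pts[, 3] <= dims[3] - 1
  out <- numeric(nrow(pts))
  if (!any(ok)) return(out)
  p <- pts[ok, , drop = FALSE]
  if (interpolation == "nearest") {
    ii <- pmin(pmax(round(p), 0), matrix(dims - 1, nrow(p), 3, byrow = TRUE))
    out[ok] <- volume[ii + 1L]
    return(out)
  }
  f0 <- floor(p)
  fr <- p - f0
  acc <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    ii <- cbind(pmin(f0[, 1] + dx, dims[1] - 1),
                pmin(f0[, 2] + dy, dims[2] - 1),
                pmin(f0[, 3] + dz, dims[3] - 1)) + 1L
    acc <- acc + w * volume[ii]
  }
  out[ok] <- acc
  out
}

#' Extract the 2D MSP image along a plane
#'
#' Resamples the volume on a regular pixel grid of the detected plane.  The
#' grid is the pixel lattice of the initial sagittal plane (normal along the
#' left-right axis, through the volume centre) carried onto the target plane
#' by the rigid map `M = T R` of [transform_between_planes()], with trilinear
#' interpolation by default.  Samples falling outside the volume are 0.
#'
#' @param volume 3D numeric array with intensities in `[0, 1]`.
#' @param plane target plane (`msp_plane` or raw 4-vector; normalized first,
#'   so the result is invariant to coefficient rescaling).
#' @param out_dims integer length-2 `(H, W)` output size; defaults to the
#'   in-plane extents `dim(volume)[2:3]`.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return `H x W` numeric matrix.
#' @export
extract_msp_image <- function(volume, plane, out_dims = NULL,
                              interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  p <- as_plane(plane)
  dims <- dim(volume)
  stopifnot(length(dims) == 3L)
  if (!plane_intersects_box(p, dims))
    stop("empty slice: plane does not intersect the volume", call. = FALSE)
  if (is.null(out_dims)) out_dims <- dims[2:3]
  xc <- (dims[1] - 1) / 2
  initial <- normalize_plane(c(1, 0, 0, -xc))
  M <- transform_between_planes(initial, p)
  grid <- as.matrix(expand.grid(p = 0:(out_dims[1] - 1L),
                                q = 0:(out_dims[2] - 1L)))
  pts3 <- cbind(xc, grid[, 1], grid[, 2])
  mapped <- apply_rigid_transform(M, pts3)
  vals <- sample_volume(volume, mapped, interpolation)
  matrix(vals, out_dims[1], out_dims[2])
}

#' Reflect a volume across a plane
#'
#' Resamples each voxel at its mirror image across the plane (trilinear).
#' Useful for measuring mirror symmetry: for a volume symmetric about the
#' plane, the reflection correlates strongly with the original.
#'
#' @param volume 3D numeric array.
#' @param plane the mirror plane.
#' @return A 3D array of the same dimensions.
#' @export
reflect_volume <- function(volume, plane) {
  dims <- dim(volume)
  un <- plane_unit_normal(plane)
  grid <- as.matrix(expand.grid(x = 0:(dims[1] - 1L), y = 0:(dims[2] - 1L),
                                z = 0:(dims[3] - 1L)))
  sg <- as.numeric(grid %*% un$n + un$d)
  refl <- grid - 2 * sg %o% un$n
  array(sample_volume(volume, refl), dims)
}
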