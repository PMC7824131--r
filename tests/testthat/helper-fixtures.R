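# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small noiseless phantom (32^3)
fixture_phantom_clean <- function() {
  cached("ph_clean", generate_phantom(
    phantom_spec(dims = c(32L, 32L, 32L), noise_level = 0,
                 head_side = "left", rng_seed = 101L)))
}

# a small noisy phantom (32^3, default speckle)
fixture_phantom_noisy <- function() {
  cached("ph_noisy", generate_phantom(
    phantom_spec(dims = c(32L, 32L, 32L), noise_level = 0.05,
                 head_side = "right", rng_seed = 102L)))
}

# tiny 16^3 phantom set for fast training smoke tests
fixture_tiny_set <- function(n = 6L) {
  cached("tiny_set", generate_dataset(
    n, phantom_spec(dims = c(16L, 16L, 16L), noise_level = 0.02,
                    rng_seed = 103L)))
}

# centre of a 32^3 crop, for seed-origin metric comparisons
crop_center32 <- rep(15.5, 3)

# angle between the two planes' unit normals, degrees
normal_angle_test <- function(p1, p2) {
  n1 <- plane_unit_normal_test(p1)
  n2 <- plane_unit_normal_test(p2)
  acos(pmin(1, abs(sum(n1 * n2)))) * 180 / pi
}

plane_unit_normal_test <- function(p) {
  v <- as.numeric(p)
  v[1:3] / sqrt(sum(v[1:3]^2))
}

# signed distances of points to a plane (unit-normal form)
plane_point_distance <- function(plane, points) {
  v <- as.numeric(plane)
  n <- sqrt(sum(v[1:3]^2))
  pts <- if (is.null(dim(points))) matrix(points, 1L, 3L) else as.matrix(points)
  as.numeric(pts %*% (v[1:3] / n) + v[4] / n)
}

expect_plane_close <- function(p1, p2, tol_deg = 0.1, origin = crop_center32) {
  expect_lt(included_angle(recenter_plane(p1, origin),
                           recenter_plane(p2, origin)), tol_deg)
}
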