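# Synthetic phantom generator: determinism, symmetry, consistency.

test_that("phantom generation is deterministic and internally consistent", {
  sp <- phantom_spec(dims = c(32L, 32L, 32L), noise_level = 0.05, rng_seed = 7L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume, b$volume)
  expect_identical(a$gt_plane, b$gt_plane)

  # ground-truth fields are mutually consistent
  expect_lt(abs(plane_point_distance(a$gt_plane, a$gt_seed)), 0.5)
  expect_equal(a$gt_mask, rasterize_plane(a$gt_plane, dim(a$volume), 0.5))
  expect_lte(abs(a$theta_axi), 30)
  expect_lte(abs(a$theta_cor), 30)
  expect_true(all(a$volume >= 0 & a$volume <= 1))

  expect_error(phantom_spec(dims = c(8L, 32L, 32L)), "invalid spec")
})

test_that("noiseless phantoms are mirror-symmetric about the true plane only", {
  ph <- fixture_phantom_clean()
  refl <- reflect_volume(ph$volume, ph$gt_plane)
  expect_gt(cor(as.vector(ph$volume), as.vector(refl)), 0.95)

  # the true plane is the maximal-symmetry plane against tilted competitors
  r_true <- cor(as.vector(ph$volume), as.vector(refl))
  for (d in c(-10, 10)) {
    p_off <- plane_from_angles(ph$gt_seed, ph$theta_axi + d, ph$theta_cor)
    r_off <- cor(as.vector(ph$volume),
                 as.vector(reflect_volume(ph$volume, p_off)))
    expect_gt(r_true, r_off)
  }
})

test_that("the nose marker encodes the head side and flip-alignment moves it", {
  sp <- phantom_spec(dims = c(32L, 32L, 32L), noise_level = 0,
                     head_side = "right", rng_seed = 33L)
  ph <- generate_phantom(sp)
  ny <- dim(ph$volume)[2]
  # mass outside the skull shell concentrates on the nose side
  outer_mass <- function(vol, seed) {
    dims <- dim(vol)
    grid <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                                  0:(dims[3] - 1)))
    r <- sqrt(rowSums(sweep(grid, 2, seed)^2))
    out <- r > 0.37 * min(dims)          # beyond the largest shell radius
    hi <- sum(vol[out & grid[, 2] > seed[2]])
    lo <- sum(vol[out & grid[, 2] < seed[2]])
    c(lo = lo, hi = hi)
  }
  m <- outer_mass(ph$volume, ph$gt_seed)
  expect_gt(m["hi"], m["lo"])            # right-facing: nose at high y

  fl <- align_flip(ph)
  expect_equal(fl$head_side, "left")
  mf <- outer_mass(fl$volume, fl$gt_seed)
  expect_gt(mf["lo"], mf["hi"])          # after alignment: nose at low y

  # flipped ground truth stays consistent
  expect_lt(abs(plane_point_distance(fl$gt_plane, fl$gt_seed)), 0.5)
  # double flip is the identity on the volume
  fl$head_side <- "right"
  fl2 <- align_flip(fl)
  expect_equal(fl2$volume, ph$volume)
})

test_that("dataset draws are independent, bounded and centred", {
  sp <- phantom_spec(dims = c(16L, 16L, 16L), angle_limit = 30,
                     noise_level = 0, rng_seed = 5L)
  ds <- generate_dataset(40, sp)
  ta <- vapply(ds, `[[`, numeric(1), "theta_axi")
  tc <- vapply(ds, `[[`, numeric(1), "theta_cor")
  expect_true(all(abs(ta) <= 30) && all(abs(tc) <= 30))
  expect_gt(max(abs(ta)), 10)            # actually spreads over the envelope
  expect_false(identical(ds[[1]]$volume, ds[[2]]$volume))

  # zero angle limit gives axis-aligned planes
  ds0 <- generate_dataset(5, phantom_spec(dims = c(16L, 16L, 16L),
                                          angle_limit = 0, rng_seed = 6L))
  for (s in ds0) {
    expect_equal(s$theta_axi, 0)
    n <- plane_unit_normal_test(s$gt_plane)
    expect_equal(abs(n), c(1, 0, 0), tolerance = 1e-12)
  }

  # a larger draw has mean near zero (Monte-Carlo sanity)
  ds2 <- generate_dataset(250, phantom_spec(dims = c(16L, 16L, 16L),
                                            noise_level = 0, rng_seed = 8L))
  ta2 <- vapply(ds2, `[[`, numeric(1), "theta_axi")
  expect_lt(abs(mean(ta2)), 2)
})
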