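# Pair metrics and cohort/agreement statistics.

test_that("included_angle matches analytic values and is a metric", {
  expect_equal(included_angle(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(included_angle(c(1, 0, 0, 0), c(0, 1, 0, 0)), 90)
  expect_equal(included_angle(c(1, 0, 0, 0), c(1, 1, 0, 0) / sqrt(2)), 45,
               tolerance = 1e-9)

  # symmetry, nonnegativity, scale invariance after normalization
  set.seed(1)
  for (i in 1:25) {
    v1 <- normalize_plane(rnorm(4) + c(1.5, 0, 0, 0))
    v2 <- normalize_plane(rnorm(4) + c(1.5, 0, 0, 0))
    th <- included_angle(v1, v2)
    expect_gte(th, 0)
    expect_equal(th, included_angle(v2, v1))
    expect_equal(th, included_angle(normalize_plane(2.3 * as.numeric(v1)), v2))
  }

  # antipodal representations of the same plane give zero
  expect_equal(included_angle(normalize_plane(c(0, 1, 0, -3)),
                              normalize_plane(c(0, -1, 0, 3))), 0)

  expect_warning(included_angle(c(2, 0, 0, 0), c(1, 0, 0, 0)), "normaliz")
})

test_that("coeff_distance matches analytic values and the angle identity", {
  expect_equal(coeff_distance(c(1, 0, 0, 0), c(1, 0, 0, 0)), 0)
  expect_equal(coeff_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), sqrt(2),
               tolerance = 1e-9)

  # d^2 = 2 (1 - cos theta) for unit 4-vectors with nonnegative dot
  set.seed(2)
  for (i in 1:200) {
    p1 <- normalize_plane(rnorm(4) + c(1, 0, 0, 0))
    p2 <- normalize_plane(rnorm(4) + c(1, 0, 0, 0))
    d <- coeff_distance(p1, p2)
    th <- included_angle(p1, p2) * pi / 180
    expect_equal(d^2, 2 * (1 - cos(th)), tolerance = 1e-9)
  }
})

test_that("yaw and roll follow the arctangent definitions", {
  expect_equal(yaw(normalize_plane(c(1, 0, 0, 0.3))), 0)
  expect_equal(roll(normalize_plane(c(1, 0, 0, 0.3))), 0)
  expect_equal(yaw(normalize_plane(c(1, 1, 0, 0))), 45, tolerance = 1e-9)
  expect_equal(roll(normalize_plane(c(1, 0, -1, 0))), 45, tolerance = 1e-9)
  # a = 0: two-argument form gives 90 rather than an error
  expect_equal(abs(yaw(normalize_plane(c(0, 1, 0, 0)))), 90)
  # reported range
  set.seed(3)
  for (i in 1:20) {
    p <- normalize_plane(rnorm(4))
    expect_lte(abs(yaw(p)), 90)
    expect_lte(abs(roll(p)), 90)
  }
})

test_that("evaluate_cohort aggregates per-pair metrics and threshold fractions", {
  p0 <- normalize_plane(c(1, 0, 0, -5))
  same <- lapply(1:10, function(i) list(predicted = p0, reference = p0))
  ev <- evaluate_cohort(same)
  expect_equal(ev$summary$mean_theta, 0)
  expect_equal(ev$summary$frac_dist_below, 1)
  expect_equal(ev$summary$frac_angle_below, 1)

  # one pair at 2 degrees among nine identical: angle fraction 90%
  q0 <- normalize_plane(c(1, 0, 0, 0))
  q2 <- normalize_plane(c(cos(2 * pi / 180), sin(2 * pi / 180), 0, 0))
  expect_equal(included_angle(q2, q0), 2, tolerance = 1e-9)
  same0 <- lapply(1:9, function(i) list(predicted = q0, reference = q0))
  pairs <- c(same0, list(list(predicted = q2, reference = q0)))
  ev <- evaluate_cohort(pairs)
  expect_equal(ev$summary$frac_angle_below, 0.9)

  # cohort means equal brute-force averages; permutation invariant
  set.seed(4)
  pl <- lapply(1:12, function(i)
    list(predicted = normalize_plane(rnorm(4) + c(2, 0, 0, 0)),
         reference = normalize_plane(rnorm(4) + c(2, 0, 0, 0))))
  ev <- evaluate_cohort(pl)
  brute <- sapply(pl, function(pr) included_angle(pr$predicted, pr$reference))
  expect_equal(ev$summary$mean_theta, mean(brute))
  ev_perm <- evaluate_cohort(pl[sample(12)])
  expect_equal(ev_perm$summary, ev$summary)

  expect_error(evaluate_cohort(list()), "empty")
  # tidy/glance round trip
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1L)
})

test_that("agreement reproduces paired statistics and handles degeneracy", {
  set.seed(5)
  a <- rnorm(20)
  ag <- agreement(a, a + 0.1)
  expect_equal(ag$bias, 0.1, tolerance = 1e-12)
  expect_equal(ag$r, 1)
  expect_equal(ag$ci_high - ag$ci_low, 0, tolerance = 1e-9)
  expect_false(ag$p_applicable)

  ag <- agreement(a, a)
  expect_equal(ag$bias, 0)
  expect_equal(ag$loa_low, 0)
  expect_true(is.na(ag$p))

  # cross-implementation oracle: t.test / cor on random paired data
  x <- rnorm(50); y <- x + rnorm(50, 0.2, 0.3)
  ag <- agreement(x, y)
  tt <- t.test(y - x)
  expect_equal(ag$p, t.test(y, x, paired = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(c(ag$ci_low, ag$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ag$r, cor(x, y), tolerance = 1e-12)
  expect_equal(ag$loa_high, mean(y - x) + 1.96 * sd(y - x), tolerance = 1e-12)

  plt <- ggplot2::autoplot(ag)
  expect_s3_class(plt, "ggplot")
})
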