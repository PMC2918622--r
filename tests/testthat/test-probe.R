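test_that("hemisphere radius inverts the volume exactly", {
  expect_equal(hemisphere_radius(2 * pi / 3), 1)
  r <- hemisphere_radius(0.8e-6)
  expect_equal(r, 7.2558e-3, tolerance = 1e-4)
  expect_equal(2 / 3 * pi * r^3, 0.8e-6)          # round trip
  expect_equal(hemisphere_radius(8 * 0.8e-6), 2 * r)  # cube-root scaling
  expect_error(hemisphere_radius(0), "positive")
})

test_that("slab partition has exact cap-slab volumes and centroids", {
  s <- slab_partition(1, 5)
  expect_equal(s$volume / pi,
               c(0.19733, 0.18133, 0.14933, 0.10133, 0.03733),
               tolerance = 1e-4)
  expect_equal(sum(s$volume), 2 * pi / 3, tolerance = 1e-14)
  expect_true(all(diff(s$volume) < 0))            # shrinking cross-section
  # n = 1: the whole hemisphere, centroid at 3r/8
  s1 <- slab_partition(2, 1)
  expect_equal(s1$volume, 2 / 3 * pi * 8)
  expect_equal(s1$centroid_height, 3 * 2 / 8)
  # volume conservation up to n = 1e4 slabs
  s4 <- slab_partition(0.00726, 1e4)
  expect_equal(sum(s4$volume), 2 / 3 * pi * 0.00726^3, tolerance = 1e-12)
  # centroids against numerical quadrature of the cap-slab integrals
  for (k in c(1, 3, 5)) {
    z0 <- (k - 1) / 5; z1 <- k / 5
    vnum <- stats::integrate(function(z) pi * (1 - z^2), z0, z1,
                             rel.tol = 1e-12)$value
    znum <- stats::integrate(function(z) pi * z * (1 - z^2), z0, z1,
                             rel.tol = 1e-12)$value / vnum
    expect_equal(s$volume[k], vnum, tolerance = 1e-10)
    expect_equal(s$centroid_height[k], znum, tolerance = 1e-10)
  }
})

test_that("probe sampling returns exact values for uniform and linear fields", {
  m <- generate_mesh(aneurysm_geometry(), 60, 24)
  pr <- probe_spec()
  # uniform field: weighted mean of constants
  expect_equal(sample_concentration(matrix(0.37, 60, 24), m, pr), 0.37)
  # linear-in-depth field: closed form sum(Vk alpha zbar_k) / sum(Vk);
  # constant-radius geometry so bilinear interpolation is exact for the
  # linear profile
  mt <- generate_mesh(tube_geometry(0.0251, 0.15), 60, 24)
  rw <- 0.0251
  alpha <- 10
  f <- alpha * (rw - mt$cr)         # depth measured from the probe wall point
  slabs <- slab_partition(pr$radius, pr$n_slabs)
  closed <- alpha * sum(slabs$volume * slabs$centroid_height) / sum(slabs$volume)
  expect_equal(sample_concentration(f, mt, pr), closed, tolerance = 1e-10)
  # monotone field: probe value between field extremes over the hemisphere
  expect_true(sample_concentration(f, mt, pr) > 0 &&
              sample_concentration(f, mt, pr) < alpha * pr$radius)
})

test_that("probe refinement is Richardson-consistent on a smooth field", {
  m <- generate_mesh(aneurysm_geometry(), 60, 24)
  rw <- wall_radius(m$geometry, m$geometry$sac_length / 2)
  f <- sin(40 * (rw - m$cr)) * 0.5 + 0.5
  v5 <- sample_concentration(f, m, probe_spec(n_slabs = 5))
  v50 <- sample_concentration(f, m, probe_spec(n_slabs = 50))
  v500 <- sample_concentration(f, m, probe_spec(n_slabs = 500))
  expect_lt(abs(v500 - v50), abs(v50 - v5))
})

test_that("oversized probe and out-of-domain centroids are rejected", {
  m <- generate_mesh(aneurysm_geometry(), 30, 10)
  expect_error(sample_concentration(matrix(1, 30, 10), m,
                                    probe_spec(radius_override = 0.03)),
               "does not fit")
})

test_that("probe series validates and round-trips through CSV", {
  expect_error(probe_time_series(c(0, 0), c(1, 2)), "increasing")
  expect_error(probe_time_series(c(0, 1), c(1, NaN)), "finite")
  s <- probe_time_series(c(0, 120, 240, 360), c(0, 0.3, 0.55, 0.7),
                         "pseudo_experiment")
  f <- tempfile(fileext = ".csv")
  write_probe_csv(s, f)
  s2 <- read_probe_csv(f)
  expect_equal(s2$times, s$times)
  expect_equal(s2$values, s$values)
  expect_equal(s2$provenance, "pseudo_experiment")
  unlink(f)
})

test_that("default schedule reports samples at the nominal times", {
  pr <- probe_spec()
  expect_equal(pr$schedule, c(0, 120, 240, 360))
  expect_equal(pipeline_snapshot_times(pr), c(30, 150, 270, 390))
})
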