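test_that("pseudo-experiment follows the compartment fill model", {
  s <- generate_pseudo_experiment(tau = 240, noise_sd = 0,
                                  schedule = c(0, 120, 240, 360))
  expect_equal(s$values[1], 0)                       # empty sac at time zero
  expect_equal(s$values[3], 1 - exp(-1), tolerance = 1e-12)
  expect_true(all(diff(s$values) > 0))               # exactly monotone
  expect_equal(s$provenance, "pseudo_experiment")
})

test_that("pseudo-experiment is seed-deterministic and clipped", {
  a <- generate_pseudo_experiment(noise_sd = 0.05, seed = 11)
  b <- generate_pseudo_experiment(noise_sd = 0.05, seed = 11)
  expect_identical(a$values, b$values)
  d <- generate_pseudo_experiment(noise_sd = 0.05, seed = 12)
  expect_false(identical(a$values, d$values))
  big <- generate_pseudo_experiment(tau = 1, noise_sd = 2, seed = 1,
                                    schedule = c(0, 60, 120))
  expect_true(all(big$values >= 0 & big$values <= 1.05))
})

test_that("1-D benchmark exposes the exact profile and scheme errors order correctly", {
  b <- generate_1d_benchmark(0, 16)
  expect_equal(b$exact(b$x), b$x)                    # Pe = 0: linear
  expect_error(generate_1d_benchmark(10, 3), ">= 4")
  b10 <- generate_1d_benchmark(10, 160)
  efou <- sqrt(mean((solve_1d_scheme(10, 160, "fou")$phi - b10$exact(b10$x))^2))
  equick <- sqrt(mean((solve_1d_scheme(10, 160, "quick")$phi - b10$exact(b10$x))^2))
  expect_lt(equick, efou)
  # Richardson: FOU error halves, QUICK error quarters, under N doubling
  e2 <- function(sc, N) {
    b <- generate_1d_benchmark(10, N)
    sqrt(mean((solve_1d_scheme(10, N, sc)$phi - b$exact(b$x))^2))
  }
  expect_equal(e2("fou", 80) / e2("fou", 160), 2, tolerance = 0.25)
  expect_equal(e2("quick", 80) / e2("quick", 160), 4, tolerance = 0.6)
})

test_that("deferred correction reduces the high-order residual monotonically", {
  sol <- solve_1d_scheme(10, 40, "quick", tol = 1e-13, max_outer = 200)
  r <- sol$residuals
  tail_r <- r[4:length(r)]
  expect_true(all(diff(tail_r) <= 1e-14))
})

test_that("1-D FOU solutions stay bounded by the end values at any Pe", {
  for (Pe in c(-500, -5, 0.5, 30, 5000)) {
    sol <- solve_1d_scheme(Pe, 25, "fou")
    expect_true(all(sol$phi >= -1e-12 & sol$phi <= 1 + 1e-12))
  }
})

test_that("oblique-step fixture reproduces known false-diffusion behaviour", {
  fx <- generate_oblique_step(45, 32)
  expect_error(generate_oblique_step(95, 32), "strictly")
  sols <- lapply(c(fou = "fou", sou = "sou", quick = "quick"),
                 function(s) solve_oblique_step(fx, s))
  w <- vapply(sols, transition_width, numeric(1))
  h <- fx$h
  expect_gt(w[["fou"]], 2 * h)             # first-order smearing
  expect_gt(w[["fou"]], w[["sou"]])
  expect_gt(w[["fou"]], w[["quick"]])
  # nearly grid-aligned flow: upwinding convects the step almost exactly
  fx0 <- generate_oblique_step(0.5, 32)
  w0 <- transition_width(solve_oblique_step(fx0, "fou"))
  expect_lt(w0, 1.5 * fx0$h)
  # with zero diffusion the power-law scheme reduces to upwinding
  expect_equal(solve_oblique_step(fx, "power_law")$field,
               solve_oblique_step(fx, "fou")$field, tolerance = 1e-12)
})

test_that("Stokes-Einstein diffusivity scales as k_B T / (6 pi mu a)", {
  d1 <- stokes_einstein_diffusivity(298, 0.001, 1e-9)
  expect_equal(stokes_einstein_diffusivity(298, 0.002, 1e-9), d1 / 2)
  expect_equal(stokes_einstein_diffusivity(0, 0.001, 1e-9), 0)
  # radius that reproduces the dye diffusivity 3.125e-10 m^2/s at 298 K
  a <- 1.380649e-23 * 298 / (6 * pi * 0.001 * 3.125e-10)
  expect_equal(a, 6.99e-10, tolerance = 0.01)
  expect_equal(stokes_einstein_diffusivity(298, 0.001, a), 3.125e-10)
  expect_error(stokes_einstein_diffusivity(298, -1, 1e-9), "positive")
})
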