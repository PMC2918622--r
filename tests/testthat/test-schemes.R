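test_that("exact 1-D profile hits its anchors and stays stable at extreme Pe", {
  expect_equal(exact_1d_solution(0, 1, 5, 2, 7), 2)
  expect_equal(exact_1d_solution(1, 1, 5, 2, 7), 7)
  expect_equal(exact_1d_solution(0.5, 1, 5, 0, 1),
               (exp(2.5) - 1) / (exp(5) - 1), tolerance = 1e-12)
  expect_equal(exact_1d_solution(0.5, 1, 5, 0, 1), 0.07586, tolerance = 1e-4)
  # diffusion limit
  expect_equal(exact_1d_solution(0.3, 1, 0, 0, 1), 0.3)
  # convection-dominated: midpoint takes the upstream value; no overflow
  expect_equal(exact_1d_solution(0.5, 1, 1e6, 0, 1), 0)
  expect_true(is.finite(exact_1d_solution(0.99, 2, 1e7, 0, 1)))
  expect_equal(exact_1d_solution(0.5, 1, -1e6, 0, 1), 1)
  expect_error(exact_1d_solution(0.5, -1, 5, 0, 1), "positive")
  expect_error(exact_1d_solution(2, 1, 5, 0, 1), "within")
})

test_that("first-order upwind returns the upstream cell value", {
  expect_equal(fou_face(face_stencil(1.2, 3.7, -4)), 3.7)
  expect_equal(fou_face(face_stencil(5, 5, 5)), 5)      # uniform field
  # reversed face-normal velocity swaps which neighbour is upstream
  s_fwd <- upwind_stencil(0.1, 0.4, 0.9, 1.6, v_n = 1)
  s_rev <- upwind_stencil(0.1, 0.4, 0.9, 1.6, v_n = -1)
  expect_equal(fou_face(s_fwd), 0.4)
  expect_equal(fou_face(s_rev), 0.9)
})

test_that("power-law face value interpolates the exact exponential profile", {
  st <- face_stencil(0, 0, 1)
  expect_equal(power_law_face(st, 0), 0.5)              # linear limit, midway
  expect_equal(power_law_face(st, 5),
               exact_1d_solution(0.5, 1, 5, 0, 1), tolerance = 1e-12)
  # high-Pe equivalence with first-order upwinding
  st2 <- face_stencil(0, 0.37, 1)
  expect_equal(power_law_face(st2, 1e4), fou_face(st2), tolerance = 1e-6)
  set.seed(42)
  for (i in 1:50) {
    st3 <- face_stencil(0, runif(1), runif(1))
    pe <- runif(1, 1e3, 1e7)
    expect_equal(power_law_face(st3, pe), fou_face(st3), tolerance = 1e-6)
  }
  # zero diffusivity falls back to pure upwinding
  expect_equal(power_law_face(st2, NaN), 0.37)
  expect_equal(power_law_face(st2, Inf), 0.37)
})

test_that("Patankar power-law variant has the right limits and symmetry", {
  # arithmetic mean at Pe = 0, upwinding at high Pe
  expect_equal(power_law_weight(0, method = "patankar"), 0.5)
  expect_equal(power_law_weight(1e4, method = "patankar"), 0, tolerance = 1e-3)
  expect_equal(power_law_weight(-1e4, method = "patankar"), 1, tolerance = 1e-3)
  # A(|Pe|) cuts off exactly at |Pe| = 10: pure upwind weight 1/Pe beyond
  expect_equal(power_law_weight(20, method = "patankar"), 1 / 20)
  # upwind/downwind symmetry w(-Pe) = 1 - w(Pe)
  pe <- seq(0.5, 15, by = 0.5)
  expect_equal(power_law_weight(-pe, method = "patankar"),
               1 - power_law_weight(pe, method = "patankar"),
               tolerance = 1e-12)
  # monotone decreasing with Pe (more upwinding as convection grows)
  expect_true(all(diff(power_law_weight(seq(0, 30, 0.5),
                                        method = "patankar")) <= 0))
  # both variants solve the 1-D benchmark to a similar profile
  b <- generate_1d_benchmark(10, 80)
  pe_exact <- solve_1d_scheme(10, 80, "power_law")$phi
  pe_pat <- solve_1d_scheme(10, 80, "power_law",
                            power_law_method = "patankar")$phi
  expect_equal(pe_pat, pe_exact, tolerance = 0.05)
  expect_lt(sqrt(mean((pe_pat - b$exact(b$x))^2)), 0.01)
})

test_that("second-order upwind extrapolates along the displacement vector", {
  st <- face_stencil(0, 1, 2, delta_s = c(0.1, 0.2))
  expect_equal(sou_face(st, c(0, 0)), 1)                 # zero gradient
  expect_equal(sou_face(st, c(2, -1)), 1)                # 1 + 0.2 - 0.2
  # exact on linear fields: phi = a z, face half a cell downstream
  a <- 3.2; dz <- 0.05
  st2 <- face_stencil(NA, a * 1, NA, delta_s = c(dz / 2, 0))
  expect_equal(sou_face(st2, c(a, 0)), a * (1 + dz / 2))
})

test_that("QUICK reproduces Leonard's coefficients and preserves constants", {
  # uniform spacing, psi = 3/4: (6/8) phiP + (3/8) phiE - (1/8) phiW
  st <- face_stencil(1, 2, 3)
  expect_equal(quick_face(st, 0.75), 6 / 8 * 2 + 3 / 8 * 3 - 1 / 8 * 1)
  # psi = 1/8 printed variant
  expect_equal(quick_face(face_stencil(0, 1, 2), 1 / 8), 1.5)
  expect_error(quick_face(st, 1.2), "psi")
  # constancy: coefficients sum to one for random blends and spacings
  set.seed(7)
  n <- 1e6
  S_u <- runif(n, 0.1, 10); S_c <- runif(n, 0.1, 10); S_d <- runif(n, 0.1, 10)
  psi <- runif(n)
  cP <- psi * S_d / (S_c + S_d) + (1 - psi) * (S_u + 2 * S_c) / (S_u + S_c)
  cE <- psi * S_c / (S_c + S_d)
  cW <- -(1 - psi) * S_c / (S_u + S_c)
  expect_lt(max(abs(cP + cE + cW - 1)), 1e-12)
  # same property through the face function on a constant field
  stc <- face_stencil(4.2, 4.2, 4.2, S_u = 0.3, S_c = 1.7, S_d = 0.9)
  for (p in c(0, 1 / 8, 0.5, 0.75, 1))
    expect_equal(quick_face(stc, p), 4.2)
})

test_that("Green-Gauss gradient is exact for constant and linear fields", {
  m <- tube_mesh_small(20, 10)
  expect_equal(max(abs(green_gauss_gradient(matrix(1, 20, 10), m)$gz)), 0)
  expect_lt(max(abs(green_gauss_gradient(matrix(5, 20, 10), m)$gr)), 1e-9)
  a <- 2; b <- -1.5
  f <- a * m$cz + b * m$cr
  G <- green_gauss_gradient(f, m)
  expect_equal(G$gz[2:19, 2:9], matrix(a, 18, 8), tolerance = 1e-9)
  expect_equal(G$gr[2:19, 2:9], matrix(b, 18, 8), tolerance = 1e-9)
})

test_that("single-cell Green-Gauss equals the hand-evaluated surface sum", {
  m <- generate_mesh(tube_geometry(1, 1), 1, 1)
  f <- matrix(2, 1, 1)
  bc <- list(inlet = 1, outlet = 3, wall = 5, axis = 2)
  G <- green_gauss_gradient(f, m, bc)
  # u-face per-radian areas are 1/2 each; gz = (3*0.5 - 1*0.5) / 0.5 = 2
  expect_equal(G$gz[1, 1], 2)
  # wall face Ar = 1, wedge correction subtracts f * parea = 2 * 1
  expect_equal(G$gr[1, 1], (5 * 1 - 2 * 1) / 0.5)
})
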