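test_that("wall radius matches the printed model dimensions", {
  g <- aneurysm_geometry()
  expect_equal(wall_radius(g, 0), 0.01255)
  expect_equal(wall_radius(g, g$sac_length / 2), 0.0251)
  expect_equal(wall_radius(g, g$sac_length), 0.01255)
  # continuous and symmetric about the sac midpoint
  z <- seq(0, g$sac_length, length.out = 101)
  expect_equal(wall_radius(g, z), rev(wall_radius(g, rev(z))))
  expect_true(all(wall_radius(g, z) >= g$inlet_radius))
  expect_error(wall_radius(g, g$sac_length + g$exit_length + 1), "domain")
  expect_error(wall_radius(g, -g$entrance_length - 0.01), "domain")
})

test_that("geometry constructor enforces its invariants", {
  expect_error(aneurysm_geometry(inlet_radius = -1), "positive")
  expect_error(aneurysm_geometry(max_radius = 0.001), "inlet_radius")
  expect_error(aneurysm_geometry(sac_length = 0), "positive")
  expect_error(aneurysm_geometry(entrance_diameters = -1), "non-negative")
})

test_that("single-cell unit tube has the exact per-radian swept volume", {
  m <- generate_mesh(tube_geometry(1, 1), 1, 1)
  expect_equal(m$vol[1, 1], 0.5)        # integral of r dr dz over unit square
  expect_equal(mesh_quality(m)$cell_count, 1L)
})

test_that("mesh volume matches the analytic volume of revolution and converges", {
  g <- aneurysm_geometry()
  analytic <- stats::integrate(function(z) wall_radius(g, z)^2 / 2,
                               -g$entrance_length,
                               g$sac_length + g$exit_length,
                               rel.tol = 1e-12, subdivisions = 400L)$value
  errs <- vapply(list(c(60, 15), c(120, 30), c(240, 60)), function(gr) {
    m <- generate_mesh(g, gr[1], gr[2])
    abs(sum(m$vol) - analytic) / analytic
  }, numeric(1))
  expect_lt(errs[3], 0.005)
  expect_true(all(diff(errs) < 0))      # monotone decrease under refinement
})

test_that("per-cell face-area vectors close the control volume", {
  m <- generate_mesh(aneurysm_geometry(), 40, 12)
  ni <- m$ni; nj <- m$nj
  # axial closure: u- and v-face z-components cancel exactly
  sz <- m$uf_Az[2:(ni + 1), ] - m$uf_Az[1:ni, ] +
    m$vf_Az[, 2:(nj + 1)] - m$vf_Az[, 1:nj]
  expect_lt(max(abs(sz)), 1e-15)
  # radial closure includes the two wedge side faces (area = planar area)
  sr <- m$vf_Ar[, 2:(nj + 1)] - m$vf_Ar[, 1:nj] - m$parea
  expect_lt(max(abs(sr)) / max(m$parea), 1e-12)
})

test_that("mesh generation is deterministic and respects cell counts", {
  g <- aneurysm_geometry()
  m1 <- generate_mesh(g, 30, 8, wall_stretch = 5)
  m2 <- generate_mesh(g, 30, 8, wall_stretch = 5)
  expect_identical(m1$z_node, m2$z_node)
  expect_identical(m1$r_node, m2$r_node)
  expect_equal(mesh_quality(m1)$cell_count, 240L)
  expect_true(all(m1$r_node[, 1] == 0))  # axis nodes exactly on r = 0
  expect_true(all(m1$vol > 0))
})

test_that("equiangle skew follows its defining formula", {
  expect_equal(equiangle_skew(c(90, 90, 90, 90)), 0)
  expect_equal(equiangle_skew(c(45, 135, 45, 135)), 0.5)
  expect_equal(equiangle_skew(c(30, 150, 30, 150)), 2 / 3)
  expect_error(equiangle_skew(c(0, 90, 90, 180)), "non-simple")
  expect_error(equiangle_skew(c(90, 90)), "four")
})

test_that("mesh quality report is exact on rectangles", {
  # square cells: tube radius/length chosen so cells are 1 x 1 aspect
  m <- generate_mesh(tube_geometry(0.01, 0.1), 10, 1)
  q <- mesh_quality(m)
  expect_equal(q$max_equiangle_skew, 0, tolerance = 1e-12)
  expect_equal(q$max_aspect_ratio, 1, tolerance = 1e-12)
  # 5:1 rectangles
  m5 <- generate_mesh(tube_geometry(0.01, 0.5), 10, 1)
  expect_equal(mesh_quality(m5)$max_aspect_ratio, 5, tolerance = 1e-12)
})

test_that("interpolation reproduces linear fields and rejects outside points", {
  m <- tube_mesh_small(30, 8)
  f <- 2 * m$cz + 3 * m$cr
  z <- c(0.02, 0.07, 0.11); r <- c(0.002, 0.005, 0.009)
  expect_equal(interp_field(m, f, z, r), 2 * z + 3 * r, tolerance = 1e-10)
  expect_error(interp_field(m, f, 0.5, 0.001), "axial")
  expect_error(interp_field(m, f, 0.05, 0.02), "fluid")
})

test_that("mesh writers emit readable files", {
  m <- generate_mesh(aneurysm_geometry(), 12, 6)
  vtk <- tempfile(fileext = ".vtk"); csv <- tempfile(fileext = ".csv")
  write_vtk_structured(m, vtk, cell_data = list(test = m$vol))
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET STRUCTURED_GRID")
  expect_true(any(grepl("SCALARS boundary", lines)))
  write_mesh_csv(m, csv)
  d <- utils::read.csv(csv)
  expect_equal(nrow(d), 13 * 7)
  expect_equal(max(d$i), 12)
  unlink(c(vtk, csv))
})
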