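test_that("average percentage difference follows its definition", {
  tgrid <- c(0, 120, 240)
  a <- probe_time_series(tgrid, c(0.2, 0.4, 0.6))
  b <- probe_time_series(tgrid, c(0.1, 0.2, 0.3))
  expect_equal(average_percentage_difference(a, b), 100)
  expect_equal(average_percentage_difference(a, a), 0)
  # constant relative offset of 15%
  c15 <- probe_time_series(tgrid, c(0.1, 0.2, 0.3) * 1.15)
  expect_equal(average_percentage_difference(c15, b), 15, tolerance = 1e-10)
  expect_equal(average_percentage_difference(c15, b, method = "signed"), 15,
               tolerance = 1e-10)
  expect_equal(average_percentage_difference(c15, b, method = "rms"), 15,
               tolerance = 1e-10)
  # zero-reference timepoints are excluded (the t = 0 sample)
  z <- probe_time_series(tgrid, c(0, 0.2, 0.3))
  az <- probe_time_series(tgrid, c(0.5, 0.4, 0.6))
  expect_equal(average_percentage_difference(az, z), 100)
  allz <- probe_time_series(tgrid, c(0, 0, 0))
  expect_error(average_percentage_difference(a, allz), "no usable")
  expect_error(average_percentage_difference(a,
    probe_time_series(c(0, 100, 200), c(0.1, 0.2, 0.3))), "time grid")
})

test_that("pairwise matrix is symmetric with zero diagonal", {
  tgrid <- c(0, 60, 120)
  sl <- list(a = probe_time_series(tgrid, c(0, 0.3, 0.5)),
             b = probe_time_series(tgrid, c(0, 0.35, 0.6)),
             c = probe_time_series(tgrid, c(0, 0.1, 0.2)))
  m <- comparison_matrix(sl)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_true(all(m >= 0))
  expect_gt(m["a", "c"], m["a", "b"])
})

test_that("configuration round-trips through YAML with defaults preserved", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("mesh:", "  ni: 24", "  nj: 8",
               "species:", "  schmidt: 50"), f)
  cfg <- read_config(f)
  expect_equal(cfg$mesh$ni, 24)
  expect_equal(cfg$mesh$nj, 8)
  expect_equal(cfg$species$schmidt, 50)
  expect_equal(cfg$geometry$inlet_diameter_mm, 25.1)   # default kept
  expect_equal(cfg$schemes$quick_psi, 0.75)
  unlink(f)
})

test_that("pipeline self-comparison is zero and the run is deterministic", {
  cfg <- default_config()
  cfg$mesh <- list(ni = 36, nj = 10, wall_stretch = 1)
  cfg$schemes$names <- c("fou", "quick")
  cfg$probe$schedule_s <- c(0, 40, 80)
  cfg$probe$withdrawal_s <- 20
  cfg$reference <- list(type = "scheme", scheme = "quick")
  cfg$species$schmidt <- 50
  rep1 <- run_pipeline(cfg)
  expect_equal(unname(rep1$reference_pct["quick"]), 0)
  expect_true(all(rep1$pairwise_pct >= 0))
  # determinism: identical config gives identical numbers
  rep2 <- run_pipeline(cfg)
  expect_identical(rep1$pairwise_pct, rep2$pairwise_pct)
  expect_identical(rep1$series$fou$values, rep2$series$fou$values)
  # report metadata reproduces the run (round-trip)
  rep3 <- run_pipeline(rep1$metadata$config)
  expect_identical(rep1$pairwise_pct, rep3$pairwise_pct)
  # writer outputs
  d <- tempfile()
  write_report(rep1, d)
  expect_true(file.exists(file.path(d, "report.json")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(js$metadata$cells, 360)
  pcsv <- utils::read.csv(file.path(d, "probe_series.csv"))
  expect_setequal(unique(pcsv$scheme), c("fou", "quick", "reference"))
  unlink(d, recursive = TRUE)
})
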