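#' Average percentage difference between two probe series
#'
#' Time-mean relative difference of series `a` against the reference
#' series `b`, in percent:
#' `mean over usable t of |a_t - b_t| / b_t * 100`.  Timepoints where the
#' reference is zero (the t = 0 sample of a fill-in experiment) are
#' excluded as a division guard.  `method = "signed"` keeps the sign of
#' `a_t - b_t`; `method = "rms"` returns the root-mean-square relative
#' difference.
#'
#' @param series_a A [probe_time_series()] (the candidate).
#' @param series_b A [probe_time_series()] (the reference).
#' @param method `"absolute"` (default), `"signed"` or `"rms"`.
#' @return Percentage difference (scalar).
#' @examples
#' a <- probe_time_series(c(0, 120, 240), c(0.2, 0.4, 0.6))
#' b <- probe_time_series(c(0, 120, 240), c(0.1, 0.2, 0.3))
#' average_percentage_difference(a, b)  # 100
#' @export
average_percentage_difference <- function(series_a, series_b,
                                          method = c("absolute", "signed",
                                                     "rms")) {
  method <- match.arg(method)
  stopifnot(inherits(series_a, "probe_series"),
            inherits(series_b, "probe_series"))
  if (length(series_a$times) != length(series_b$times) ||
      any(abs(series_a$times - series_b$times) > 1e-9))
    stop("series must share an identical time grid")
  use <- series_b$values != 0
  if (!any(use)) stop("no usable timepoints: reference is zero everywhere")
  r <- (series_a$values[use] - series_b$values[use]) / series_b$values[use]
  100 * switch(method,
               absolute = mean(abs(r)),
               signed = mean(r),
               rms = sqrt(mean(r^2)))
}

#' Pairwise scheme-difference matrix
#'
#' Symmetric matrix of time-mean percentage differences between probe
#' series, using the pointwise mean of the two series as the local
#' reference (`|a_t - b_t| / ((a_t + b_t)/2)`), which makes the measure
#' symmetric with a zero diagonal; timepoints where both series are zero
#' are excluded.
#'
#' @param series_list Named list of [probe_time_series()] on a common time
#'   grid.
#' @return A symmetric numeric matrix of percentages.
#' @export
comparison_matrix <- function(series_list) {
  nm <- names(series_list)
  m <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    a <- series_list[[i]]$values; b <- series_list[[j]]$values
    mid <- (a + b) / 2
    use <- mid != 0
    if (!any(use)) stop("no usable timepoints for pair ", nm[i], "/", nm[j])
    m[i, j] <- m[j, i] <- 100 * mean(abs(a[use] - b[use]) / mid[use])
  }
  m
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: the default aneurysm dimensions, fluid and
#' Re = 800 boundary condition, a reduced 96 x 28 grid and a reduced
#' Schmidt number of 100 so the grid resolves the concentration boundary
#' layers, all four convection schemes at matched settings, the 0.8 ml /
#' 5-slab probe on the every-second-minute schedule, and a seeded
#' pseudo-experimental reference series.  Any entry can be overridden; set
#' `species$schmidt = 3200` for the full dye Schmidt number.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(inlet_diameter_mm = 25.1, max_diameter_mm = 50.2,
                    sac_length_mm = 75.3,
                    entrance_diameters = 2, exit_diameters = 4),
    mesh = list(ni = 96, nj = 28, wall_stretch = 1),
    fluid = list(density = 1000, dynamic_viscosity = 0.001),
    flow_bc = list(reynolds = 800, flow_rate_m3s = NULL),
    flow = list(momentum_scheme = "quick", tol = 1e-3, max_iter = 3000,
                relax_u = 0.7, relax_p = 0.3),
    species = list(schmidt = 100, dt = 1, tol = 1e-3,
                   power_law_method = "exact"),
    schemes = list(names = c("fou", "power_law", "sou", "quick"),
                   quick_psi = 0.75),
    probe = list(extraction_volume_ml = 0.8, n_slabs = 5,
                 schedule_s = c(0, 120, 240, 360), withdrawal_s = 60),
    reference = list(type = "pseudo_experiment", tau = 240,
                     noise_sd = 0.02, seed = 1, path = NULL, scheme = NULL),
    output = list(dir = NULL, write_vtk = FALSE)
  )
}

#' Read a pipeline configuration file
#'
#' YAML configuration merged over [default_config()]; any key not present
#' keeps its default.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && sec %in% names(cfg))
      cfg[[sec]] <- utils::modifyList(cfg[[sec]], user[[sec]])
    else cfg[[sec]] <- user[[sec]]
  }
  cfg
}

.config_objects <- function(config) {
  g <- config$geometry
  geometry <- aneurysm_geometry(inlet_radius = g$inlet_diameter_mm / 2000,
                                max_radius = g$max_diameter_mm / 2000,
                                sac_length = g$sac_length_mm / 1000,
                                entrance_diameters = g$entrance_diameters,
                                exit_diameters = g$exit_diameters)
  fluid <- fluid_properties(config$fluid$density,
                            config$fluid$dynamic_viscosity)
  bcs <- if (!is.null(config$flow_bc$flow_rate_m3s))
    flow_bcs(flow_rate = config$flow_bc$flow_rate_m3s)
  else flow_bcs(reynolds = config$flow_bc$reynolds)
  probe <- probe_spec(extraction_volume = config$probe$extraction_volume_ml * 1e-6,
                      n_slabs = config$probe$n_slabs,
                      schedule = config$probe$schedule_s,
                      withdrawal_s = config$probe$withdrawal_s)
  list(geometry = geometry, fluid = fluid, bcs = bcs, probe = probe)
}

#' Run the full scheme-comparison pipeline
#'
#' Orchestrates mesh generation, one steady flow solve, one transient
#' species run per configured scheme (identical settings otherwise), probe
#' extraction per scheme, the pairwise scheme-difference matrix and the
#' comparison of every scheme against the configured reference series.
#' The run is fully deterministic for a fixed configuration (the only
#' random element, the pseudo-experimental reference noise, is seeded from
#' the configuration).
#'
#' @param config A configuration list ([default_config()] form) or a path
#'   to a YAML file.
#' @param verbose Print stage progress.
#' @return An object of class `comparison_report`: per-scheme probe series,
#'   the pairwise matrix, reference differences, per-scheme sac-average
#'   series, and the run metadata (including the exact configuration, which
#'   reproduces the report).
#' @export
run_pipeline <- function(config = default_config(), verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  ob <- .config_objects(config)
  mesh <- generate_mesh(ob$geometry, config$mesh$ni, config$mesh$nj,
                        wall_stretch = config$mesh$wall_stretch)
  if (verbose) message("solving steady flow ...")
  flow <- solve_steady_flow(mesh, ob$fluid, ob$bcs,
                            momentum_scheme = config$flow$momentum_scheme,
                            psi = config$schemes$quick_psi,
                            tol = config$flow$tol,
                            max_iter = config$flow$max_iter,
                            relax_u = config$flow$relax_u,
                            relax_p = config$flow$relax_p,
                            verbose = verbose)
  diffusivity <- ob$fluid$dynamic_viscosity /
    (ob$fluid$density * config$species$schmidt)
  snap <- pipeline_snapshot_times(ob$probe)
  t_end <- max(snap)
  series <- list(); sacs <- list(); results <- list()
  for (sc in config$schemes$names) {
    if (verbose) message("transient species transport: ", sc)
    run <- transport_run(scheme = sc, psi = config$schemes$quick_psi,
                         dt = config$species$dt, t_end = t_end,
                         diffusivity = diffusivity,
                         snapshot_times = snap,
                         tol = config$species$tol,
                         power_law_method = config$species$power_law_method)
    res <- run_transient(mesh, flow, run, ob$fluid, verbose = verbose)
    series[[sc]] <- probe_transient(res, mesh, ob$probe)
    sacs[[sc]] <- res$sac_series
    results[[sc]] <- res
  }
  ref <- config$reference
  reference <- switch(ref$type,
    pseudo_experiment = generate_pseudo_experiment(
      tau = ref$tau, noise_sd = ref$noise_sd, seed = ref$seed,
      schedule = ob$probe$schedule),
    csv = read_probe_csv(ref$path),
    scheme = series[[ref$scheme]],
    stop("unknown reference type: ", ref$type))
  pair <- comparison_matrix(series)
  refdiff <- vapply(series, average_percentage_difference,
                    numeric(1), series_b = reference)
  report <- structure(list(
    series = series, reference = reference,
    pairwise_pct = pair, reference_pct = refdiff,
    sac_series = sacs,
    metadata = list(config = config,
                    cells = mesh$ni * mesh$nj,
                    Re = dimensionless_numbers(ob$geometry, ob$fluid, ob$bcs,
                                               diffusivity)$Re,
                    Sc = config$species$schmidt,
                    quick_psi = config$schemes$quick_psi,
                    flow_tol = config$flow$tol,
                    species_tol = config$species$tol,
                    reference_seed = ref$seed,
                    flow_iterations = flow$iterations)),
    class = "comparison_report")
  outdir <- config$output$dir
  if (!is.null(outdir)) {
    write_report(report, outdir)
    if (isTRUE(config$output$write_vtk)) {
      for (sc in names(results)) {
        snaps <- results[[sc]]$snapshots
        for (tm in names(snaps))
          write_vtk_structured(mesh, file.path(outdir,
            sprintf("conc_%s_t%s.vtk", sc, tm)),
            cell_data = list(c_norm = snaps[[tm]]))
      }
      write_vtk_structured(mesh, file.path(outdir, "flow.vtk"),
                           cell_data = list(u = flow$u, v = flow$v,
                                            p = flow$p))
    }
  }
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Scheme comparison report\n")
  cat(sprintf("  grid: %d cells, Re = %.4g, Sc = %.4g\n",
              x$metadata$cells, x$metadata$Re, x$metadata$Sc))
  cat("  probe series (normalised concentration):\n")
  tab <- do.call(rbind, lapply(x$series, function(s) s$values))
  colnames(tab) <- paste0("t=", x$reference$times, "s")
  print(round(tab, 4))
  cat("  reference series (", x$reference$provenance, "): ",
      paste(signif(x$reference$values, 4), collapse = ", "), "\n", sep = "")
  cat("  pairwise percentage differences:\n")
  print(round(x$pairwise_pct, 2))
  cat("  average percentage difference vs reference:\n")
  print(round(x$reference_pct, 2))
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `report.json` (metrics + metadata), `probe_series.csv` (one row
#' per scheme per timepoint, plus the reference) and
#' `sac_average.csv` (per-scheme sac-mean concentration per step).
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    pairwise_pct = report$pairwise_pct,
    reference_pct = as.list(report$reference_pct),
    probe = lapply(report$series, function(s)
      list(times = s$times, values = s$values)),
    reference = list(times = report$reference$times,
                     values = report$reference$values,
                     provenance = report$reference$provenance),
    metadata = report$metadata
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
     pretty = TRUE)
  rows <- do.call(rbind, c(
    lapply(names(report$series), function(sc)
      data.frame(scheme = sc, time_s = report$series[[sc]]$times,
                 c_norm = report$series[[sc]]$values)),
    list(data.frame(scheme = "reference",
                    time_s = report$reference$times,
                    c_norm = report$reference$values))))
  utils::write.csv(rows, file.path(dir, "probe_series.csv"),
                   row.names = FALSE)
  sac <- do.call(rbind, lapply(names(report$sac_series), function(sc)
    cbind(scheme = sc, report$sac_series[[sc]])))
  utils::write.csv(sac, file.path(dir, "sac_average.csv"), row.names = FALSE)
  invisible(dir)
}
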