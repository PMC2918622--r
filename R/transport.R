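#' Species boundary conditions
#'
#' Inlet: constant normalised mass fraction (default 1).  Outlet:
#' zero-gradient outflow.  Axis: symmetry.  Wall: inert by default (zero
#' diffusive mass flux, the glass-wall condition), or a Dirichlet wall with
#' fixed concentration — the latter exists for wall mass-transfer
#' (Sherwood-number) studies, since an inert wall transfers nothing.
#'
#' @param inlet_value Inlet mass fraction in (0, 1].
#' @param wall `"inert"` (zero flux) or `"dirichlet"`.
#' @param wall_value Wall concentration for the Dirichlet variant.
#' @return A list of class `species_bcs`.
#' @export
species_bcs <- function(inlet_value = 1, wall = c("inert", "dirichlet"),
                        wall_value = 0) {
  wall <- match.arg(wall)
  if (!(inlet_value > 0 && inlet_value <= 1))
    stop("inlet mass fraction must lie in (0, 1]")
  structure(list(
    inlet = list(type = "dirichlet", value = inlet_value),
    outlet = list(type = "outflow"),
    wall = if (wall == "inert") list(type = "zero_flux")
           else list(type = "dirichlet", value = wall_value),
    axis = list(type = "zero_flux")
  ), class = "species_bcs")
}

#' Transient transport run settings
#'
#' @param scheme Convection scheme: `"fou"`, `"power_law"`, `"sou"` or
#'   `"quick"`.
#' @param psi QUICK blend weight.
#' @param dt Time-step size in seconds (default 1 s).
#' @param t_end End of the run in seconds of *sac time* (time zero = tracer
#'   arrival at the sac inlet; see [run_transient()]).
#' @param diffusivity Species diffusivity, m^2/s (default 3.125e-10, i.e.
#'   Sc = 3200 in the default fluid).
#' @param snapshot_times Times (sac time, s) at which full fields are
#'   stored; must lie in `[0, t_end]`.
#' @param tol Scaled-residual tolerance of each implicit step.
#' @param max_outer Outer (deferred-correction) iteration cap per step.
#' @param dc_relax Under-relaxation of the deferred-correction source.
#' @param power_law_method `"exact"` or `"patankar"`.
#' @return A list of class `transport_run`.
#' @export
transport_run <- function(scheme = "quick", psi = 0.75, dt = 1, t_end = 360,
                          diffusivity = 3.125e-10, snapshot_times = NULL,
                          tol = 1e-3, max_outer = 50, dc_relax = 1,
                          power_law_method = "exact") {
  scheme <- match.arg(scheme, c("fou", "power_law", "sou", "quick"))
  if (!(dt > 0)) stop("dt must be positive")
  if (t_end < dt) stop("t_end must be at least one time step")
  if (!is.null(snapshot_times) &&
      (any(snapshot_times < 0) || any(snapshot_times > t_end)))
    stop("snapshot times must lie within [0, t_end]")
  structure(list(scheme = scheme, psi = psi, dt = dt, t_end = t_end,
                 diffusivity = diffusivity,
                 snapshot_times = sort(unique(snapshot_times)),
                 tol = tol, max_outer = max_outer, dc_relax = dc_relax,
                 power_law_method = power_law_method),
            class = "transport_run")
}

#' Build the cached implicit transport operator
#'
#' Assembles and factorises the implicit part of the unsteady transport
#' equation (first-order upwind convection, central diffusion, implicit
#' Euler).  The matrix is constant over time steps for a frozen flow and
#' fixed `dt`, so the sparse LU factorisation is reused by every call to
#' [advance_step()].
#'
#' @param mesh A [generate_mesh()] result.
#' @param flow A `flow_solution` (or list with `Fu`, `Fv`).
#' @param run A [transport_run()].
#' @param fluid A [fluid_properties()].
#' @param bc A [species_bcs()].
#' @return An opaque operator object for [advance_step()].
#' @export
transport_operator <- function(mesh, flow, run, fluid = fluid_properties(),
                               bc = species_bcs()) {
  gamma <- fluid$density * run$diffusivity
  op <- .make_scalar_operator(mesh, flow$Fu, flow$Fv, gamma, bc,
                              dt = run$dt, rho = fluid$density)
  op$run <- run
  op
}

#' Advance the species field by one implicit time step
#'
#' One first-order implicit Euler step with deferred-correction outer
#' iterations until the scaled residual drops below `run$tol`.  Errors with
#' the residual trace attached if the outer-iteration cap is exceeded.
#'
#' @param field `ni x nj` mass-fraction field at time t.
#' @param flow A `flow_solution` (used only when `operator` is missing).
#' @param run A [transport_run()].
#' @param mesh A [generate_mesh()] result.
#' @param fluid A [fluid_properties()].
#' @param bc A [species_bcs()].
#' @param operator Optional cached [transport_operator()].
#' @return List with the new `field`, the outer `residuals` trace and the
#'   iteration count.
#' @export
advance_step <- function(field, flow, run, mesh, fluid = fluid_properties(),
                         bc = species_bcs(), operator = NULL) {
  if (is.null(operator)) operator <- transport_operator(mesh, flow, run, fluid, bc)
  rhs_time <- operator$extra * as.vector(field)
  out <- .scalar_outer_solve(operator, mesh, field, rhs_time,
                             run$scheme, run$psi, tol = run$tol,
                             max_outer = run$max_outer,
                             dc_relax = run$dc_relax,
                             power_law_method = run$power_law_method,
                             on_fail = "error")
  list(field = out$phi, residuals = out$residuals,
       iterations = out$iterations)
}

#' Run the unsteady species transport on a frozen flow
#'
#' Marches the passive mass-fraction field from zero initial concentration
#' with the inlet held at the boundary value.  "Sac time" zero is the
#' instant the tracer front first reaches the sac inlet, computed from the
#' mean-velocity transit of the entrance extension
#' (`entrance_length / U`); simulation steps before that instant carry the
#' front through the entrance.  Snapshots and the sac-average series are
#' reported in sac time.
#'
#' A global mass balance (inflow - outflow - accumulation, relative to the
#' inflow) is audited every step.
#'
#' @param mesh A [generate_mesh()] result.
#' @param flow A `flow_solution` from [solve_steady_flow()].
#' @param run A [transport_run()].
#' @param fluid A [fluid_properties()].
#' @param bc A [species_bcs()].
#' @param verbose Print progress every 60 steps.
#' @return An object of class `transport_result`: `snapshots` (named list
#'   of fields), `snapshot_times`, `sac_series` (data.frame of sac-averaged
#'   normalised concentration per step), `balance` (per-step audit),
#'   `offset` (entrance transit time, s) and the run settings.
#' @export
run_transient <- function(mesh, flow, run, fluid = fluid_properties(),
                          bc = species_bcs(), verbose = FALSE) {
  stopifnot(inherits(mesh, "structured_mesh"), inherits(run, "transport_run"))
  op <- transport_operator(mesh, flow, run, fluid, bc)
  offset <- mesh$geometry$entrance_length / flow$U
  t_end_sim <- run$t_end + offset
  nsteps <- ceiling(t_end_sim / run$dt - 1e-9)
  snap_want <- run$snapshot_times
  snapshots <- list(); snap_taken <- rep(FALSE, length(snap_want))
  sac <- mesh$cz >= 0 & mesh$cz <= mesh$geometry$sac_length
  sacv <- mesh$vol[sac]; sacvt <- sum(sacv)
  gamma <- fluid$density * run$diffusivity
  phi <- matrix(0, mesh$ni, mesh$nj)
  inval <- rep_len(bc$inlet$value, mesh$nj)
  Fin <- flow$Fu[1L, ]; Fout <- flow$Fu[mesh$ni + 1L, ]
  nbal <- nsteps
  bal <- data.frame(time = numeric(nbal), mass_in = numeric(nbal),
                    mass_out = numeric(nbal), accumulation = numeric(nbal),
                    rel_imbalance = numeric(nbal))
  sac_t <- numeric(nsteps); sac_c <- numeric(nsteps)
  if (length(snap_want) && any(snap_want == 0))
    snapshots[["0"]] <- phi
  for (s in seq_len(nsteps)) {
    phi_old <- phi
    st <- advance_step(phi_old, flow, run, mesh, fluid, bc, operator = op)
    phi <- st$field
    t_sim <- s * run$dt
    t_sac <- t_sim - offset
    m_in <- sum(Fin * inval + gamma * mesh$gdb_in * (inval - phi[1L, ])) * run$dt
    m_out <- sum(Fout * phi[mesh$ni, ]) * run$dt
    acc <- sum(fluid$density * mesh$vol * (phi - phi_old))
    bal[s, ] <- list(t_sac, m_in, m_out, acc,
                     (m_in - m_out - acc) / max(m_in, 1e-300))
    sac_t[s] <- t_sac
    sac_c[s] <- sum(phi[sac] * sacv) / sacvt
    if (length(snap_want)) {
      due <- !snap_taken & (snap_want <= t_sac + 1e-9)
      for (w in which(due)) snapshots[[as.character(snap_want[w])]] <- phi
      snap_taken <- snap_taken | due
    }
    if (verbose && s %% 60L == 0L)
      message(sprintf("step %d / %d (sac time %.0f s), sac mean %.4f",
                      s, nsteps, t_sac, sac_c[s]))
  }
  structure(list(snapshots = snapshots,
                 snapshot_times = snap_want,
                 sac_series = data.frame(time = sac_t, c_norm = sac_c),
                 balance = bal, offset = offset, run = run,
                 final_field = phi),
            class = "transport_result")
}

#' Steady species transport solution
#'
#' Solves the steady scalar transport equation on a frozen flow with the
#' selected scheme by deferred-correction outer iterations (used for the
#' Dirichlet-wall Sherwood-number studies, where a steady state exists).
#'
#' @param mesh A [generate_mesh()] result.
#' @param flow A `flow_solution`.
#' @param diffusivity Species diffusivity, m^2/s.
#' @param scheme,psi Convection scheme and QUICK blend.
#' @param bc A [species_bcs()].
#' @param fluid A [fluid_properties()].
#' @param tol Scaled-residual tolerance.
#' @param max_outer Outer iteration cap.
#' @param dc_relax Deferred-correction under-relaxation.
#' @return List of class `species_steady` with the `field`, residual trace
#'   and the boundary conditions used.
#' @export
solve_steady_species <- function(mesh, flow, diffusivity = 3.125e-10,
                                 scheme = "quick", psi = 0.75,
                                 bc = species_bcs(), fluid = fluid_properties(),
                                 tol = 1e-6, max_outer = 400, dc_relax = 1) {
  gamma <- fluid$density * diffusivity
  op <- .make_scalar_operator(mesh, flow$Fu, flow$Fv, gamma, bc,
                              dt = Inf, rho = fluid$density)
  init <- matrix(rep_len(bc$inlet$value, 1), mesh$ni, mesh$nj)
  out <- .scalar_outer_solve(op, mesh, init, numeric(mesh$ni * mesh$nj),
                             scheme, psi, tol = tol, max_outer = max_outer,
                             dc_relax = dc_relax, on_fail = "warn")
  structure(list(field = out$phi, residuals = out$residuals,
                 converged = out$converged, bc = bc,
                 diffusivity = diffusivity, scheme = scheme),
            class = "species_steady")
}

#' Area-averaged sac-wall Sherwood number
#'
#' `Sh = (wall-normal concentration gradient x inlet diameter) /
#' (inlet concentration - wall concentration)`, area-averaged over the wall
#' faces of the sac section.  Requires a field solved with the
#' Dirichlet-wall variant of [species_bcs()]: the inert wall of the
#' headline runs has identically zero transfer, so a Sherwood number is
#' undefined for it.
#'
#' @param solution A `species_steady` from [solve_steady_species()].
#' @param mesh The mesh the field lives on.
#' @return The area-averaged Sherwood number (dimensionless).
#' @export
sherwood_number <- function(solution, mesh) {
  stopifnot(inherits(solution, "species_steady"),
            inherits(mesh, "structured_mesh"))
  bc <- solution$bc
  if (!identical(bc$wall$type, "dirichlet"))
    stop("Sherwood number requires the Dirichlet-wall transport variant; ",
         "the inert (zero-flux) wall has no mass transfer")
  dphi <- bc$inlet$value - bc$wall$value
  if (abs(dphi) < 1e-300)
    stop("degenerate: inlet and wall concentrations are equal (0/0 Sherwood)")
  ni <- mesh$ni; nj <- mesh$nj
  wA <- sqrt(mesh$vf_Az[, nj + 1L]^2 + mesh$vf_Ar[, nj + 1L]^2)
  grad_n <- (solution$field[, nj] - bc$wall$value) * mesh$gdb_wall / wA
  insac <- mesh$vf_cz[, nj + 1L] >= 0 &
    mesh$vf_cz[, nj + 1L] <= mesh$geometry$sac_length
  D <- mesh$geometry$inlet_diameter
  sum(abs(grad_n[insac]) * wA[insac]) / sum(wA[insac]) * D / abs(dphi)
}

#' Sherwood-number grid-independence study
#'
#' Runs the steady flow + Dirichlet-wall steady species transport on a
#' refinement sequence of wall-graded meshes and reports the sac-wall
#' area-averaged Sherwood number per grid together with the relative change
#' between successive grids.  Each finer flow solve is initialised from the
#' interpolated coarser solution.
#'
#' @param geometry An [aneurysm_geometry()].
#' @param grids List of `c(ni, nj)` pairs, coarse to fine.
#' @param reynolds Inlet Reynolds number.
#' @param schmidt Schmidt number of the transported species.
#' @param fluid A [fluid_properties()].
#' @param wall_stretch Radial grading (axis-cell / wall-cell height ratio)
#'   used on every grid so the sequence is geometrically similar.
#' @param scheme,psi Convection scheme for both momentum and species.
#' @param flow_tol,species_tol Convergence tolerances.
#' @param max_iter Flow iteration cap per grid.
#' @param verbose Print per-grid progress.
#' @return A data.frame with one row per grid: `ni`, `nj`, `cells`,
#'   `sherwood` and `change_pct` (relative change from the previous grid,
#'   in percent; `NA` for the first).
#' @export
grid_independence_study <- function(geometry = aneurysm_geometry(),
                                    grids = list(c(60, 20), c(120, 40), c(240, 80)),
                                    reynolds = 800, schmidt = 100,
                                    fluid = fluid_properties(),
                                    wall_stretch = 20,
                                    scheme = "quick", psi = 0.75,
                                    flow_tol = 1e-3, species_tol = 1e-6,
                                    max_iter = 3000, verbose = FALSE) {
  bcs <- flow_bcs(reynolds = reynolds)
  diffusivity <- fluid$dynamic_viscosity / (fluid$density * schmidt)
  sh <- numeric(length(grids))
  prev <- NULL; prev_mesh <- NULL
  res <- data.frame(ni = integer(0), nj = integer(0), cells = integer(0),
                    sherwood = numeric(0), change_pct = numeric(0))
  for (g in seq_along(grids)) {
    ni <- grids[[g]][1]; nj <- grids[[g]][2]
    mesh <- generate_mesh(geometry, ni, nj, wall_stretch = wall_stretch)
    init <- NULL
    if (!is.null(prev)) {
      zq <- as.vector(mesh$cz); rq <- as.vector(mesh$cr)
      rq <- pmin(rq, wall_radius(geometry, zq) * 0.999999)
      init <- list(u = matrix(interp_field(prev_mesh, prev$u, zq, rq), ni, nj),
                   v = matrix(interp_field(prev_mesh, prev$v, zq, rq), ni, nj),
                   p = matrix(interp_field(prev_mesh, prev$p, zq, rq), ni, nj))
    }
    flow <- solve_steady_flow(mesh, fluid, bcs, momentum_scheme = scheme,
                              psi = psi, tol = flow_tol, max_iter = max_iter,
                              init = init, verbose = verbose)
    sol <- solve_steady_species(mesh, flow, diffusivity = diffusivity,
                                scheme = scheme, psi = psi,
                                bc = species_bcs(wall = "dirichlet"),
                                fluid = fluid, tol = species_tol)
    sh[g] <- sherwood_number(sol, mesh)
    res[g, ] <- list(ni, nj, ni * nj, sh[g],
                     if (g == 1) NA_real_
                     else abs(sh[g] - sh[g - 1]) / sh[g] * 100)
    if (verbose)
      message(sprintf("grid %dx%d: Sh = %.5g (change %.3g%%)",
                      ni, nj, sh[g], res$change_pct[g]))
    prev <- flow; prev_mesh <- mesh
  }
  res
}
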