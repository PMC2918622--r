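#' Fluid properties
#'
#' Newtonian, isothermal, incompressible carrier fluid.  Defaults are the
#' water-like values used throughout: density 1000 kg/m^3 and dynamic
#' viscosity 0.001 Pa s.
#'
#' @param density kg/m^3 (> 0).
#' @param dynamic_viscosity Pa s (> 0).
#' @return A list of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, dynamic_viscosity = 0.001) {
  if (!(density > 0) || !(dynamic_viscosity > 0))
    stop("density and dynamic_viscosity must be positive")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Flow boundary conditions
#'
#' Exactly one of the volumetric flow rate or the Reynolds number must be
#' given; with the geometry and fluid the other follows.  The outlet is an
#' outflow (zero streamwise gradient with global mass correction), the axis
#' is a symmetry boundary and the wall is rigid no-slip.
#'
#' @param flow_rate Volumetric flow rate, m^3/s.
#' @param reynolds Reynolds number based on inlet diameter and mean inlet
#'   velocity.
#' @return A list of class `flow_bcs`.
#' @export
flow_bcs <- function(flow_rate = NULL, reynolds = NULL) {
  if (is.null(flow_rate) == is.null(reynolds))
    stop("specify exactly one of flow_rate and reynolds")
  if (!is.null(flow_rate) && !(flow_rate > 0)) stop("flow_rate must be positive")
  if (!is.null(reynolds) && !(reynolds > 0)) stop("reynolds must be positive")
  structure(list(flow_rate = flow_rate, reynolds = reynolds),
            class = "flow_bcs")
}

#' Dimensionless numbers of the transport problem
#'
#' `Re = rho U D / mu` with `D` the inlet diameter and `U` the mean inlet
#' velocity, `Sc = mu / (rho D_AB)`, `Pe = Re * Sc`.  With the default
#' fluid and a species diffusivity of 3.125e-10 m^2/s this gives Sc = 3200,
#' and Re = 800 then yields Pe = 2,560,000 (strongly convection-dominated).
#'
#' @param geometry An [aneurysm_geometry()].
#' @param fluid A [fluid_properties()].
#' @param bcs A [flow_bcs()].
#' @param diffusivity Species diffusivity `D_AB`, m^2/s.
#' @return List with `Re`, `Sc`, `Pe`, `mean_velocity` (m/s) and
#'   `flow_rate` (m^3/s).
#' @export
dimensionless_numbers <- function(geometry, fluid = fluid_properties(),
                                  bcs = flow_bcs(reynolds = 800),
                                  diffusivity = 3.125e-10) {
  stopifnot(inherits(geometry, "aneurysm_geometry"))
  D <- geometry$inlet_diameter
  area <- pi * geometry$inlet_radius^2
  nu <- fluid$dynamic_viscosity / fluid$density
  if (!is.null(bcs$reynolds)) {
    U <- bcs$reynolds * nu / D
    Q <- U * area
  } else {
    Q <- bcs$flow_rate
    U <- Q / area
  }
  Re <- U * D / nu
  Sc <- fluid$dynamic_viscosity / (fluid$density * diffusivity)
  list(Re = Re, Sc = Sc, Pe = Re * Sc, mean_velocity = U, flow_rate = Q)
}

#' Fully developed inlet velocity profile and face fluxes
#'
#' Hagen-Poiseuille profile `u(r) = 2 U (1 - (r/R)^2)` evaluated exactly on
#' the inlet faces: each face carries the closed-form flux integral of the
#' parabola over its radial extent, then the set is normalised so the
#' discrete flux sum equals the requested flow rate to round-off.
#'
#' @param mesh A [generate_mesh()] result.
#' @param bcs A [flow_bcs()].
#' @param fluid A [fluid_properties()].
#' @return List with `flux` (volumetric per-radian face fluxes, length
#'   `nj`), `u_face` (area-mean face velocities used as Dirichlet values),
#'   `U` (mean velocity), `Q` (flow rate) and `R` (inlet radius).
#' @export
inlet_profile <- function(mesh, bcs, fluid = fluid_properties()) {
  stopifnot(inherits(mesh, "structured_mesh"))
  dn <- dimensionless_numbers(mesh$geometry, fluid, bcs)
  U <- dn$mean_velocity; Q <- dn$flow_rate
  R <- mesh$rw[1L]
  r1 <- mesh$r_node[1L, 1:mesh$nj]
  r2 <- mesh$r_node[1L, 2:(mesh$nj + 1L)]
  # exact integral of 2U(1-(r/R)^2) r dr over [r1, r2], per radian
  flux <- U * ((r2^2 - r1^2) - (r2^4 - r1^4) / (2 * R^2))
  flux <- flux * (Q / (2 * pi)) / sum(flux)
  u_face <- flux / mesh$uf_Az[1L, ]
  list(flux = flux, u_face = u_face, U = U, Q = Q, R = R)
}

# conservative initial face fluxes from a cell axial-velocity field:
# face-average u, per-station scaling to the inlet flow, then radial fluxes
# from exact per-cell continuity.
.init_fluxes <- function(mesh, u, rho, Fin) {
  ni <- mesh$ni; nj <- mesh$nj
  Fu <- matrix(0, ni + 1L, nj)
  Fu[1L, ] <- Fin
  if (ni >= 2L)
    Fu[2:ni, ] <- rho * (u[1:(ni - 1L), , drop = FALSE] +
                         u[2:ni, , drop = FALSE]) / 2 *
      mesh$uf_Az[2:ni, , drop = FALSE]
  Fu[ni + 1L, ] <- rho * u[ni, ] * mesh$uf_Az[ni + 1L, ]
  tot <- sum(Fin)
  for (i in 2:(ni + 1L)) {
    s <- sum(Fu[i, ])
    Fu[i, ] <- if (s > 1e-12 * tot) Fu[i, ] * tot / s
               else tot * mesh$uf_Az[i, ] / sum(mesh$uf_Az[i, ])
  }
  net_u <- Fu[1:ni, , drop = FALSE] - Fu[2:(ni + 1L), , drop = FALSE]
  Fv <- matrix(0, ni, nj + 1L)
  Fv[, 2:(nj + 1L)] <- t(apply(net_u, 1L, cumsum))
  Fv[, nj + 1L] <- 0
  list(Fu = Fu, Fv = Fv)
}

#' Steady laminar axisymmetric flow by SIMPLE-type segregated iteration
#'
#' Solves the steady incompressible axisymmetric Navier-Stokes equations on
#' the collocated structured mesh.  Momentum convection uses an implicit
#' first-order upwind base with the selected scheme (default QUICK, blend
#' `psi`) as a deferred-correction source; pressure-velocity coupling is a
#' SIMPLE loop with momentum-weighted (Rhie-Chow-type) face-velocity
#' interpolation to suppress pressure checker-boarding.  The radial momentum
#' equation carries the axisymmetric `-mu v / r^2` sink and the wedge
#' pressure term.  After the last iteration a final exact pressure-correction
#' projection is applied to the face fluxes so that every cell satisfies
#' continuity to linear-solver precision.
#'
#' Convergence is declared when the scaled continuity and momentum residuals
#' all drop below `tol` (default 1e-3); a stricter tolerance is recommended
#' for validation studies.  If the total residual grows over 200 consecutive
#' iterations the solver aborts with the residual trace attached.
#'
#' @param mesh A [generate_mesh()] result.
#' @param fluid A [fluid_properties()].
#' @param bcs A [flow_bcs()].
#' @param momentum_scheme Convection scheme for momentum: `"quick"`
#'   (default), `"sou"`, `"power_law"` or `"fou"`.
#' @param psi QUICK blend weight.
#' @param tol Scaled-residual convergence criterion (default 1e-3).
#' @param max_iter Iteration cap.
#' @param relax_u,relax_p Under-relaxation factors for momentum and
#'   pressure.
#' @param init Optional initial state: list with `ni x nj` matrices `u`,
#'   `v`, `p` (e.g. interpolated from a coarser solution).
#' @param verbose Print residuals every 50 iterations.
#' @return An object of class `flow_solution`: cell velocities `u`, `v`
#'   (m/s), pressure `p` (Pa), conservative face mass fluxes `Fu`, `Fv`
#'   (kg/s per radian), residual history, and run metadata.
#' @export
solve_steady_flow <- function(mesh, fluid = fluid_properties(),
                              bcs = flow_bcs(reynolds = 800),
                              momentum_scheme = "quick", psi = 0.75,
                              tol = 1e-3, max_iter = 3000,
                              relax_u = 0.7, relax_p = 0.3,
                              init = NULL, verbose = FALSE) {
  stopifnot(inherits(mesh, "structured_mesh"))
  momentum_scheme <- match.arg(momentum_scheme,
                               c("quick", "sou", "power_law", "fou"))
  ni <- mesh$ni; nj <- mesh$nj; n <- ni * nj
  rho <- fluid$density; mu <- fluid$dynamic_viscosity
  inp <- inlet_profile(mesh, bcs, fluid)
  Fin <- rho * inp$flux
  Fin_tot <- sum(Fin)
  vol <- as.vector(mesh$vol)

  if (is.null(init)) {
    rwc <- wall_radius(mesh$geometry, as.vector(mesh$cz))
    rwc <- matrix(rwc, ni, nj)
    Uc <- (Fin_tot / rho) / (rwc^2 / 2)
    u <- 2 * Uc * (1 - (mesh$cr / rwc)^2)
    v <- matrix(0, ni, nj)
    p <- matrix(0, ni, nj)
  } else {
    u <- init$u; v <- init$v; p <- init$p
  }
  fl <- .init_fluxes(mesh, u, rho, Fin)
  Fu <- fl$Fu; Fv <- fl$Fv

  bc_u <- list(inlet = list(type = "dirichlet", value = inp$u_face),
               outlet = list(type = "outflow"),
               wall = list(type = "dirichlet", value = 0),
               axis = list(type = "zero_flux"))
  bc_v <- list(inlet = list(type = "dirichlet", value = 0),
               outlet = list(type = "outflow"),
               wall = list(type = "dirichlet", value = 0),
               axis = list(type = "zero_flux"))
  sink_v <- as.vector(mu * mesh$vol / mesh$cr^2)

  ip <- if (ni >= 2L) 1:(ni - 1L) else integer(0)
  ie <- if (ni >= 2L) 2:ni else integer(0)
  jp <- if (nj >= 2L) 1:(nj - 1L) else integer(0)
  je <- if (nj >= 2L) 2:nj else integer(0)
  k <- mesh$kmat
  Pu <- as.vector(k[ip, ]); Eu <- as.vector(k[ie, ])
  Pv <- as.vector(k[, jp]); Ev <- as.vector(k[, je])
  dz_u <- mesh$cz[ie, , drop = FALSE] - mesh$cz[ip, , drop = FALSE]
  ddz_v <- mesh$cz[, je, drop = FALSE] - mesh$cz[, jp, drop = FALSE]
  ddr_v <- mesh$cr[, je, drop = FALSE] - mesh$cr[, jp, drop = FALSE]
  Az_v <- mesh$vf_Az[, je, drop = FALSE]; Ar_v <- mesh$vf_Ar[, je, drop = FALSE]
  Am2_v <- Az_v^2 + Ar_v^2
  Az_u <- mesh$uf_Az[ie, , drop = FALSE]
  mom_floor <- Fin_tot * max(inp$U, 1e-12)

  res_hist <- data.frame(iter = integer(0), continuity = numeric(0),
                         umom = numeric(0), vmom = numeric(0))
  grow <- 0L; prev_tot <- Inf
  converged <- FALSE

  solve_pcor <- function(bfu, bfv, net) {
    dia_p <- numeric(n)
    ti <- c(Pu, Eu, Pv, Ev); tj <- c(Eu, Pu, Ev, Pv)
    tx <- c(-bfu, -bfu, -bfv, -bfv)
    dia_p[Pu] <- dia_p[Pu] + bfu; dia_p[Eu] <- dia_p[Eu] + bfu
    dia_p[Pv] <- dia_p[Pv] + bfv; dia_p[Ev] <- dia_p[Ev] + bfv
    keep <- ti != 1L
    Ap <- Matrix::sparseMatrix(i = c(seq_len(n), ti[keep]),
                               j = c(seq_len(n), tj[keep]),
                               x = c(replace(dia_p, 1L, 1), tx[keep]),
                               dims = c(n, n))
    rhs_p <- -as.vector(net); rhs_p[1L] <- 0
    as.vector(Matrix::solve(Ap, rhs_p))
  }

  for (it in seq_len(max_iter)) {
    Gp <- green_gauss_gradient(p, mesh)

    asm_u <- .assemble_conv_diff(mesh, Fu, Fv, mu, bc_u)
    dcu <- .dc_source(mesh, Fu, Fv, u, momentum_scheme, psi, mu, bc_u)
    rhs_u0 <- asm_u$rhs + dcu - as.vector(Gp$gz) * vol
    res_u <- sum(abs(rhs_u0 - as.vector(asm_u$A %*% as.vector(u)))) /
      max(sum(abs(asm_u$dia * as.vector(u))), mom_floor)
    dia_ur <- asm_u$dia / relax_u
    Au <- asm_u$A + Matrix::Diagonal(n, dia_ur - asm_u$dia)
    u_star <- as.vector(Matrix::solve(Au, rhs_u0 + (dia_ur - asm_u$dia) * as.vector(u)))

    asm_v <- .assemble_conv_diff(mesh, Fu, Fv, mu, bc_v, extra_diag = sink_v)
    dcv <- .dc_source(mesh, Fu, Fv, v, momentum_scheme, psi, mu, bc_v)
    rhs_v0 <- asm_v$rhs + dcv - as.vector(Gp$gr) * vol
    res_v <- sum(abs(rhs_v0 - as.vector(asm_v$A %*% as.vector(v)))) /
      max(sum(abs(asm_v$dia * as.vector(v))), mom_floor)
    dia_vr <- asm_v$dia / relax_u
    Av <- asm_v$A + Matrix::Diagonal(n, dia_vr - asm_v$dia)
    v_star <- as.vector(Matrix::solve(Av, rhs_v0 + (dia_vr - asm_v$dia) * as.vector(v)))

    du <- vol / dia_ur; dv <- vol / dia_vr

    # Rhie-Chow face fluxes
    if (ni >= 2L) {
      ubar <- (u_star[Pu] + u_star[Eu]) / 2
      dcoef <- (du[Pu] + du[Eu]) / 2
      bfu <- rho * dcoef * as.vector(mesh$gdu)
      gpb <- (as.vector(Gp$gz)[Pu] + as.vector(Gp$gz)[Eu]) / 2
      Fu[2:ni, ] <- matrix(rho * ubar * as.vector(Az_u) +
                           bfu * ((p[Pu] - p[Eu]) + gpb * as.vector(dz_u)),
                           ni - 1L, nj)
    } else bfu <- numeric(0)
    if (nj >= 2L) {
      vbarA <- rho * ((u_star[Pv] + u_star[Ev]) / 2 * as.vector(Az_v) +
                      (v_star[Pv] + v_star[Ev]) / 2 * as.vector(Ar_v))
      dn <- (as.vector(Az_v)^2 * (du[Pv] + du[Ev]) / 2 +
             as.vector(Ar_v)^2 * (dv[Pv] + dv[Ev]) / 2) / as.vector(Am2_v)
      bfv <- rho * dn * as.vector(mesh$gdv)
      gpd <- ((as.vector(Gp$gz)[Pv] + as.vector(Gp$gz)[Ev]) / 2 * as.vector(ddz_v) +
              (as.vector(Gp$gr)[Pv] + as.vector(Gp$gr)[Ev]) / 2 * as.vector(ddr_v))
      Fv[, 2:nj] <- matrix(vbarA + bfv * ((p[Pv] - p[Ev]) + gpd), ni, nj - 1L)
    } else bfv <- numeric(0)
    Fu[1L, ] <- Fin
    fo <- rho * u_star[k[ni, ]] * mesh$uf_Az[ni + 1L, ]
    so <- sum(fo)
    Fu[ni + 1L, ] <- if (so > 1e-12 * Fin_tot) fo * Fin_tot / so
                     else Fin_tot * mesh$uf_Az[ni + 1L, ] / sum(mesh$uf_Az[ni + 1L, ])
    Fv[, 1L] <- 0; Fv[, nj + 1L] <- 0

    net <- .flux_div(mesh, Fu, Fv)
    res_c <- sum(abs(net)) / Fin_tot
    res_hist[it, ] <- list(it, res_c, res_u, res_v)
    if (verbose && it %% 50L == 0L)
      message(sprintf("iter %4d: continuity %.3e  u %.3e  v %.3e",
                      it, res_c, res_u, res_v))

    if (it > 2L && res_c <= tol && res_u <= tol && res_v <= tol) {
      u <- matrix(u_star, ni, nj); v <- matrix(v_star, ni, nj)
      converged <- TRUE
      break
    }

    pc <- solve_pcor(bfu, bfv, net)
    p <- p + relax_p * matrix(pc, ni, nj)
    if (ni >= 2L) Fu[2:ni, ] <- Fu[2:ni, ] + matrix(bfu * (pc[Pu] - pc[Eu]), ni - 1L, nj)
    if (nj >= 2L) Fv[, 2:nj] <- Fv[, 2:nj] + matrix(bfv * (pc[Pv] - pc[Ev]), ni, nj - 1L)
    Gpc <- green_gauss_gradient(matrix(pc, ni, nj), mesh)
    u <- matrix(u_star - du * as.vector(Gpc$gz), ni, nj)
    v <- matrix(v_star - dv * as.vector(Gpc$gr), ni, nj)

    tot <- res_c + res_u + res_v
    grow <- if (tot > prev_tot) grow + 1L else 0L
    prev_tot <- tot
    if (grow >= 200L) {
      cond <- simpleError("flow solver diverging: residuals grew over 200 consecutive iterations")
      cond$residual_trace <- res_hist
      stop(cond)
    }
  }
  if (!converged)
    warning(sprintf("flow solver did not reach tol=%.1e in %d iterations (continuity %.3e)",
                    tol, max_iter, res_hist$continuity[nrow(res_hist)]))

  # final projection: make the face fluxes conservative to solver precision
  if (ni >= 2L || nj >= 2L) {
    net <- .flux_div(mesh, Fu, Fv)
    pc <- solve_pcor(bfu, bfv, net)
    if (ni >= 2L) Fu[2:ni, ] <- Fu[2:ni, ] + matrix(bfu * (pc[Pu] - pc[Eu]), ni - 1L, nj)
    if (nj >= 2L) Fv[, 2:nj] <- Fv[, 2:nj] + matrix(bfv * (pc[Pv] - pc[Ev]), ni, nj - 1L)
  }

  structure(list(u = u, v = v, p = p, Fu = Fu, Fv = Fv,
                 residuals = res_hist, converged = converged,
                 iterations = nrow(res_hist),
                 U = inp$U, Q = inp$Q, inlet_flux = Fin,
                 fluid = fluid, bcs = bcs,
                 momentum_scheme = momentum_scheme, psi = psi),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Steady axisymmetric flow solution (%s momentum)\n", x$momentum_scheme))
  cat(sprintf("  mean inlet velocity %.5g m/s, flow rate %.5g m^3/s\n", x$U, x$Q))
  last <- x$residuals[nrow(x$residuals), ]
  cat(sprintf("  %d iterations, %s; residuals: continuity %.2e, u %.2e, v %.2e\n",
              x$iterations, if (x$converged) "converged" else "NOT converged",
              last$continuity, last$umom, last$vmom))
  invisible(x)
}
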