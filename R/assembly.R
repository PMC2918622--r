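# Core finite-volume assembly for the axisymmetric scalar transport
# equation: implicit first-order-upwind convection + central diffusion,
# with higher-order schemes applied as an explicit deferred-correction
# source.  Shared by the species solver and the momentum equations.

# net outward mass flux per cell (per radian)
.flux_div <- function(mesh, Fu, Fv) {
  ni <- mesh$ni; nj <- mesh$nj
  Fu[2:(ni + 1L), , drop = FALSE] - Fu[1:ni, , drop = FALSE] +
    Fv[, 2:(nj + 1L), drop = FALSE] - Fv[, 1:nj, drop = FALSE]
}

# boundary-condition list -> face values for Green-Gauss gradients
.bc_face_values <- function(bc) {
  list(inlet = if (identical(bc$inlet$type, "dirichlet")) bc$inlet$value,
       outlet = NULL,
       wall = if (identical(bc$wall$type, "dirichlet")) bc$wall$value,
       axis = NULL)
}

# Implicit part: FOU convection + central diffusion (+ Euler time term via
# extra_diag supplied by the caller).  Returns the sparse matrix, its
# diagonal and the boundary contribution to the right-hand side.
.assemble_conv_diff <- function(mesh, Fu, Fv, gamma, bc, extra_diag = NULL) {
  ni <- mesh$ni; nj <- mesh$nj; n <- ni * nj
  k <- mesh$kmat
  dia <- numeric(n); rhs <- numeric(n)
  oi <- list(); oj <- list(); ox <- list(); nt <- 0L
  add_face_set <- function(P, E, F, D) {
    # flux F positive from P to E; D = diffusion conductance
    aP_out <- pmax(F, 0) + D
    aE_out <- pmax(-F, 0) + D
    dia[P] <<- dia[P] + aP_out
    dia[E] <<- dia[E] + aE_out
    nt <<- nt + 1L
    oi[[nt]] <<- c(P, E); oj[[nt]] <<- c(E, P)
    ox[[nt]] <<- c(-aE_out, -aP_out)
  }
  if (ni >= 2L)
    add_face_set(as.vector(k[1:(ni - 1L), ]), as.vector(k[2:ni, ]),
                 as.vector(Fu[2:ni, , drop = FALSE]),
                 as.vector(gamma * mesh$gdu))
  if (nj >= 2L)
    add_face_set(as.vector(k[, 1:(nj - 1L)]), as.vector(k[, 2:nj]),
                 as.vector(Fv[, 2:nj, drop = FALSE]),
                 as.vector(gamma * mesh$gdv))
  # inlet (Dirichlet value carried by inflow + diffusion to the face)
  kc <- k[1L, ]; Fb <- Fu[1L, ]
  if (identical(bc$inlet$type, "dirichlet")) {
    vin <- rep_len(bc$inlet$value, nj)
    Db <- gamma * mesh$gdb_in
    dia[kc] <- dia[kc] + Db + pmax(-Fb, 0)
    rhs[kc] <- rhs[kc] + (Db + pmax(Fb, 0)) * vin
  } else {
    dia[kc] <- dia[kc] + pmax(-Fb, 0)       # outflow-style at the inlet tag
  }
  # outlet: zero-gradient convective outflow
  ko <- k[ni, ]; Fo <- Fu[ni + 1L, ]
  dia[ko] <- dia[ko] + pmax(Fo, 0)
  # wall: inert (zero flux) or Dirichlet
  if (identical(bc$wall$type, "dirichlet")) {
    kw <- k[, nj]
    wv <- rep_len(bc$wall$value, ni)
    Dw <- gamma * mesh$gdb_wall
    dia[kw] <- dia[kw] + Dw
    rhs[kw] <- rhs[kw] + Dw * wv
  }
  # axis: swept face area is identically zero; no terms
  if (!is.null(extra_diag)) dia <- dia + extra_diag
  A <- Matrix::sparseMatrix(i = c(seq_len(n), unlist(oi)),
                            j = c(seq_len(n), unlist(oj)),
                            x = c(dia, unlist(ox)), dims = c(n, n))
  list(A = A, dia = dia, rhs = rhs)
}

# Deferred-correction source: F * (phi_f^high-order - phi_f^upwind) summed
# into the two cells sharing each interior face.
.dc_source <- function(mesh, Fu, Fv, phi, scheme, psi, gamma, bc,
                       power_law_method = "exact") {
  ni <- mesh$ni; nj <- mesh$nj; n <- ni * nj
  rhs <- numeric(n)
  if (scheme == "fou") return(rhs)
  k <- mesh$kmat
  G <- NULL
  if (scheme %in% c("sou", "quick"))
    G <- green_gauss_gradient(phi, mesh, bc = .bc_face_values(bc))
  quick_val <- function(pos, phiU, phiD, phiW, S_c, S_d, S_u) {
    psi * (S_d / (S_c + S_d) * phiU + S_c / (S_c + S_d) * phiD) +
      (1 - psi) * ((S_u + 2 * S_c) / (S_u + S_c) * phiU -
                   S_c / (S_u + S_c) * phiW)
  }

  if (ni >= 2L) {
    {
      ip <- 1:(ni - 1L); ie <- 2:ni
      F <- Fu[2:ni, , drop = FALSE]
      pos <- F >= 0
      phiP <- phi[ip, , drop = FALSE]; phiE <- phi[ie, , drop = FALSE]
      up <- ifelse(pos, phiP, phiE)
      zf <- mesh$uf_cz[2:ni, , drop = FALSE]; rf <- mesh$uf_cr[2:ni, , drop = FALSE]
      if (scheme == "power_law") {
        dz <- mesh$cz[ie, , drop = FALSE] - mesh$cz[ip, , drop = FALSE]
        pe <- F * dz / (gamma * mesh$uf_Az[2:ni, , drop = FALSE])
        tf <- (zf - mesh$cz[ip, , drop = FALSE]) / dz
        w <- power_law_weight(as.vector(pe), as.vector(tf), power_law_method)
        ho <- phiP + matrix(w, ni - 1L, nj) * (phiE - phiP)
      } else {
        hoP <- phiP + G$gz[ip, , drop = FALSE] * (zf - mesh$cz[ip, , drop = FALSE]) +
          G$gr[ip, , drop = FALSE] * (rf - mesh$cr[ip, , drop = FALSE])
        hoE <- phiE + G$gz[ie, , drop = FALSE] * (zf - mesh$cz[ie, , drop = FALSE]) +
          G$gr[ie, , drop = FALSE] * (rf - mesh$cr[ie, , drop = FALSE])
        ho <- ifelse(pos, hoP, hoE)
        if (scheme == "quick" && ni >= 3L) {
          Sz <- matrix(mesh$wz, ni, nj)
          phiWpos <- rbind(rep(NA_real_, nj), phi[1:(ni - 2L), , drop = FALSE])
          phiWneg <- rbind(phi[3:ni, , drop = FALSE], rep(NA_real_, nj))
          SWpos <- rbind(rep(NA_real_, nj), Sz[1:(ni - 2L), , drop = FALSE])
          SWneg <- rbind(Sz[3:ni, , drop = FALSE], rep(NA_real_, nj))
          phiW <- ifelse(pos, phiWpos, phiWneg)
          S_u <- ifelse(pos, SWpos, SWneg)
          S_c <- ifelse(pos, Sz[ip, , drop = FALSE], Sz[ie, , drop = FALSE])
          S_d <- ifelse(pos, Sz[ie, , drop = FALSE], Sz[ip, , drop = FALSE])
          phiD <- ifelse(pos, phiE, phiP)
          qv <- quick_val(pos, up, phiD, phiW, S_c, S_d, S_u)
          ho <- ifelse(is.na(phiW), ho, qv)   # near-boundary fallback to SOU
        }
      }
      corr <- F * (ho - up)
      P <- as.vector(k[ip, ]); E <- as.vector(k[ie, ])
      rhs[P] <- rhs[P] - as.vector(corr)
      rhs[E] <- rhs[E] + as.vector(corr)
    }
  }

  if (nj >= 2L) {
    jp <- 1:(nj - 1L); je <- 2:nj
    F <- Fv[, 2:nj, drop = FALSE]
    pos <- F >= 0
    phiP <- phi[, jp, drop = FALSE]; phiE <- phi[, je, drop = FALSE]
    up <- ifelse(pos, phiP, phiE)
    zf <- mesh$vf_cz[, 2:nj, drop = FALSE]; rf <- mesh$vf_cr[, 2:nj, drop = FALSE]
    if (scheme == "power_law") {
      ddz <- mesh$cz[, je, drop = FALSE] - mesh$cz[, jp, drop = FALSE]
      ddr <- mesh$cr[, je, drop = FALSE] - mesh$cr[, jp, drop = FALSE]
      dd <- sqrt(ddz^2 + ddr^2)
      Am <- sqrt(mesh$vf_Az[, 2:nj, drop = FALSE]^2 +
                 mesh$vf_Ar[, 2:nj, drop = FALSE]^2)
      pe <- F * dd / (gamma * Am)
      tf <- ((zf - mesh$cz[, jp, drop = FALSE]) * ddz +
             (rf - mesh$cr[, jp, drop = FALSE]) * ddr) / dd^2
      w <- power_law_weight(as.vector(pe), as.vector(tf), power_law_method)
      ho <- phiP + matrix(w, ni, nj - 1L) * (phiE - phiP)
    } else {
      hoP <- phiP + G$gz[, jp, drop = FALSE] * (zf - mesh$cz[, jp, drop = FALSE]) +
        G$gr[, jp, drop = FALSE] * (rf - mesh$cr[, jp, drop = FALSE])
      hoE <- phiE + G$gz[, je, drop = FALSE] * (zf - mesh$cz[, je, drop = FALSE]) +
        G$gr[, je, drop = FALSE] * (rf - mesh$cr[, je, drop = FALSE])
      ho <- ifelse(pos, hoP, hoE)
      if (scheme == "quick" && nj >= 3L) {
        Sr <- mesh$hr
        phiWpos <- cbind(rep(NA_real_, ni), phi[, 1:(nj - 2L), drop = FALSE])
        phiWneg <- cbind(phi[, 3:nj, drop = FALSE], rep(NA_real_, ni))
        SWpos <- cbind(rep(NA_real_, ni), Sr[, 1:(nj - 2L), drop = FALSE])
        SWneg <- cbind(Sr[, 3:nj, drop = FALSE], rep(NA_real_, ni))
        phiW <- ifelse(pos, phiWpos, phiWneg)
        S_u <- ifelse(pos, SWpos, SWneg)
        S_c <- ifelse(pos, Sr[, jp, drop = FALSE], Sr[, je, drop = FALSE])
        S_d <- ifelse(pos, Sr[, je, drop = FALSE], Sr[, jp, drop = FALSE])
        phiD <- ifelse(pos, phiE, phiP)
        qv <- quick_val(pos, up, phiD, phiW, S_c, S_d, S_u)
        ho <- ifelse(is.na(phiW), ho, qv)
      }
    }
    corr <- F * (ho - up)
    P <- as.vector(k[, jp]); E <- as.vector(k[, je])
    rhs[P] <- rhs[P] - as.vector(corr)
    rhs[E] <- rhs[E] + as.vector(corr)
  }
  rhs
}

# Fluent-style scaled residual of A phi = rhs
.scaled_residual <- function(A, dia, rhs, phi, floor = 1e-30) {
  sum(abs(rhs - as.vector(A %*% phi))) / max(sum(abs(dia * phi)), floor)
}

#' Assemble the discretised scalar-transport system
#'
#' Builds the linear system of the finite-volume scalar transport equation
#' on a frozen flow field: implicit first-order-upwind convection plus
#' central diffusion (two-point face-normal gradient), with the selected
#' higher-order scheme entering the right-hand side as an explicit
#' deferred-correction source evaluated at `phi_old`, and an optional
#' first-order implicit Euler time term.  This implicit/explicit split
#' keeps the matrix diagonally dominant for any scheme.
#'
#' @param mesh A [generate_mesh()] result.
#' @param flow A `flow_solution` from [solve_steady_flow()], or a list with
#'   conservative face mass-flux matrices `Fu` (`(ni+1) x nj`) and `Fv`
#'   (`ni x (nj+1)`), in kg/s per radian.
#' @param gamma Diffusion coefficient of the scalar (`rho * D_AB` for
#'   mass-fraction transport), kg/(m s).
#' @param bc Boundary conditions from [species_bcs()].
#' @param scheme One of `"fou"`, `"power_law"`, `"sou"`, `"quick"`.
#' @param psi QUICK blend weight in `[0, 1]`.
#' @param dt Time-step size in seconds (`Inf` for a steady assembly).
#' @param phi_old `ni x nj` field at the previous time level / outer
#'   iteration (defaults to zero).
#' @param rho Fluid density, kg/m^3.
#' @param power_law_method `"exact"` or `"patankar"` (see
#'   [power_law_face()]).
#' @return A list with the sparse matrix `A`, right-hand side `rhs`, matrix
#'   diagonal `dia`, the reported per-cell mass imbalance `imbalance`, and a
#'   `residual(phi)` accessor returning the scaled residual.
#' @export
assemble_scalar_system <- function(mesh, flow, gamma, bc = species_bcs(),
                                   scheme = "fou", psi = 0.75, dt = Inf,
                                   phi_old = NULL, rho = 1000,
                                   power_law_method = "exact") {
  stopifnot(inherits(mesh, "structured_mesh"))
  scheme <- match.arg(scheme, c("fou", "power_law", "sou", "quick"))
  Fu <- flow$Fu; Fv <- flow$Fv
  if (is.null(phi_old)) phi_old <- matrix(0, mesh$ni, mesh$nj)
  imb <- .flux_div(mesh, Fu, Fv)
  fin <- max(sum(abs(Fu[1L, ])), 1e-300)
  if (max(abs(imb)) > 1e-6 * fin)
    warning(sprintf("non-conservative flux field: max cell imbalance %.3g x inlet flux",
                    max(abs(imb)) / fin))
  extra <- if (is.finite(dt)) as.vector(rho * mesh$vol / dt) else NULL
  asm <- .assemble_conv_diff(mesh, Fu, Fv, gamma, bc, extra_diag = extra)
  rhs <- asm$rhs + .dc_source(mesh, Fu, Fv, phi_old, scheme, psi, gamma, bc,
                              power_law_method)
  if (is.finite(dt)) rhs <- rhs + extra * as.vector(phi_old)
  A <- asm$A; dia <- asm$dia
  list(A = A, rhs = rhs, dia = dia, imbalance = imb,
       residual = function(phi) .scaled_residual(A, dia, rhs, as.vector(phi)))
}

# Outer deferred-correction loop around a fixed implicit operator.
# op: list(asm, lu) from .make_scalar_operator; rhs_time added each call.
.make_scalar_operator <- function(mesh, Fu, Fv, gamma, bc, dt = Inf,
                                  rho = 1000) {
  extra <- if (is.finite(dt)) as.vector(rho * mesh$vol / dt) else NULL
  asm <- .assemble_conv_diff(mesh, Fu, Fv, gamma, bc, extra_diag = extra)
  list(asm = asm, lu = Matrix::lu(asm$A), extra = extra,
       Fu = Fu, Fv = Fv, gamma = gamma, bc = bc, dt = dt, rho = rho)
}

.scalar_outer_solve <- function(op, mesh, phi_init, rhs_time, scheme, psi,
                                tol = 1e-3, max_outer = 50, dc_relax = 1,
                                power_law_method = "exact",
                                on_fail = c("warn", "error")) {
  on_fail <- match.arg(on_fail)
  ni <- mesh$ni; nj <- mesh$nj
  phi <- as.vector(phi_init)
  src <- NULL
  trace <- numeric(0)
  for (it in seq_len(max_outer)) {
    src_new <- .dc_source(mesh, op$Fu, op$Fv, matrix(phi, ni, nj),
                          scheme, psi, op$gamma, op$bc, power_law_method)
    src <- if (is.null(src)) src_new else src + dc_relax * (src_new - src)
    rhs <- op$asm$rhs + rhs_time + src
    res <- .scaled_residual(op$asm$A, op$asm$dia, rhs, phi)
    trace <- c(trace, res)
    if (it > 1L && res <= tol)
      return(list(phi = matrix(phi, ni, nj), residuals = trace,
                  iterations = it, converged = TRUE))
    phi <- as.vector(Matrix::solve(op$lu, rhs))
  }
  msg <- sprintf("outer iterations did not reach tol=%.1e in %d iterations (last residual %.3e)",
                 tol, max_outer, trace[length(trace)])
  if (on_fail == "error") {
    cond <- simpleError(msg)
    cond$residual_trace <- trace
    stop(cond)
  }
  warning(msg)
  list(phi = matrix(phi, ni, nj), residuals = trace,
       iterations = max_outer, converged = FALSE)
}
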