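#' Pseudo-experimental probe time series
#'
#' Stand-in for the unavailable experimental dye measurements: a well-mixed
#' recirculation-compartment fill model, `C(t) = 1 - exp(-t / tau)`, sampled
#' on the withdrawal schedule with additive Gaussian measurement noise and
#' clipped to `[0, 1.05]`.  With `noise_sd = 0` the series is exactly
#' monotone; with noise it is monotone in expectation.  Fixed seeds give
#' bit-identical series.
#'
#' @param tau Fill time constant, s (> 0; default 240 s).
#' @param noise_sd Standard deviation of the additive noise on normalised
#'   concentration (>= 0).
#' @param seed Integer seed for the noise; `NULL` uses the current RNG
#'   state.
#' @param schedule Sampling times, s.
#' @return A [probe_time_series()] with provenance `"pseudo_experiment"`.
#' @export
generate_pseudo_experiment <- function(tau = 240, noise_sd = 0.02,
                                       seed = NULL,
                                       schedule = c(0, 120, 240, 360)) {
  if (!(tau > 0)) stop("tau must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- 1 - exp(-schedule / tau)
  if (noise_sd > 0) v <- v + stats::rnorm(length(schedule), 0, noise_sd)
  probe_time_series(schedule, pmin(pmax(v, 0), 1.05), "pseudo_experiment")
}

#' One-dimensional convection-diffusion benchmark
#'
#' Uniform 1-D finite-volume mesh on `[0, 1]` with constant mass flux and
#' diffusivity realising the requested Peclet number and Dirichlet end
#' values; the exact solution sampler delegates to [exact_1d_solution()].
#'
#' @param Pe Peclet number over the unit interval.
#' @param N Number of cells (>= 4).
#' @param phi0,phiL End values.
#' @return List with the benchmark parameters, cell centres `x` and an
#'   `exact(x)` sampler.
#' @export
generate_1d_benchmark <- function(Pe, N, phi0 = 0, phiL = 1) {
  N <- as.integer(N)
  if (N < 4L) stop("N must be >= 4")
  h <- 1 / N
  list(Pe = Pe, N = N, h = h, phi0 = phi0, phiL = phiL,
       x = (seq_len(N) - 0.5) * h,
       exact = function(x) exact_1d_solution(x, 1, Pe, phi0, phiL))
}

#' Solve the 1-D benchmark with a chosen convection scheme
#'
#' Finite-volume solution of the steady 1-D convection-diffusion problem:
#' implicit first-order-upwind convection + central diffusion, with the
#' higher-order schemes applied through converged deferred correction.  At
#' Dirichlet boundary faces the higher-order convective face value is the
#' boundary value itself (deferred), so second-order accuracy is retained
#' at the outflow end while the implicit matrix stays an M-matrix.
#'
#' @param Pe Peclet number over the unit interval (signed).
#' @param N Number of cells.
#' @param scheme `"fou"`, `"power_law"`, `"sou"` or `"quick"`.
#' @param psi QUICK blend weight.
#' @param phi0,phiL Dirichlet end values.
#' @param power_law_method `"exact"` or `"patankar"`.
#' @param tol Outer-iteration residual tolerance (absolute, on the scaled
#'   residual).
#' @param max_outer Outer iteration cap.
#' @param dc_relax Deferred-correction under-relaxation.
#' @return List with cell centres `x`, solution `phi`, the residual trace
#'   and iteration count.
#' @export
solve_1d_scheme <- function(Pe, N, scheme = "quick", psi = 0.75,
                            phi0 = 0, phiL = 1,
                            power_law_method = "exact",
                            tol = 1e-12, max_outer = 2000, dc_relax = 1) {
  scheme <- match.arg(scheme, c("fou", "power_law", "sou", "quick"))
  N <- as.integer(N)
  if (N < 2L) stop("N must be >= 2")
  h <- 1 / N
  Fl <- Pe                      # rho*u with Gamma = 1 on unit interval
  D <- 1 / h; Db <- 2 / h
  x <- (seq_len(N) - 0.5) * h

  dia <- numeric(N); rhs0 <- numeric(N)
  lower <- numeric(N - 1L); upper <- numeric(N - 1L)
  # interior faces
  dia[1:(N - 1L)] <- dia[1:(N - 1L)] + pmax(Fl, 0) + D
  dia[2:N] <- dia[2:N] + pmax(-Fl, 0) + D
  upper[] <- -(pmax(-Fl, 0) + D)
  lower[] <- -(pmax(Fl, 0) + D)
  # Dirichlet ends: diffusion to the face + upwind convection
  dia[1L] <- dia[1L] + Db + pmax(-Fl, 0)     # left face outward flux = -Fl
  rhs0[1L] <- rhs0[1L] + (Db + pmax(Fl, 0)) * phi0
  dia[N] <- dia[N] + Db + pmax(Fl, 0)
  rhs0[N] <- rhs0[N] + (Db + pmax(-Fl, 0)) * phiL

  A <- Matrix::bandSparse(N, k = c(-1, 0, 1),
                          diagonals = list(lower, dia, upper))
  lu <- Matrix::lu(methods::as(A, "CsparseMatrix"))

  face_ho <- function(phi) {
    # interior faces f = 2..N between cells f-1 and f
    iP <- 1:(N - 1L); iE <- 2:N
    pos <- Fl >= 0
    up <- if (pos) phi[iP] else phi[iE]
    if (scheme == "fou") return(list(ho = up, up = up))
    if (scheme == "power_law") {
      w <- power_law_weight(rep(Pe * h, N - 1L), 0.5, power_law_method)
      return(list(ho = phi[iP] + w * (phi[iE] - phi[iP]), up = up))
    }
    # Green-Gauss cell gradients with boundary face values
    fv <- c(phi0, (phi[iP] + phi[iE]) / 2, phiL)
    g <- (fv[2:(N + 1L)] - fv[1:N]) / h
    if (pos) { gup <- g[iP]; xs <- h / 2 } else { gup <- g[iE]; xs <- -h / 2 }
    ho <- up + gup * xs
    if (scheme == "quick") {
      if (pos) {
        iW <- iP - 1L
        ok <- iW >= 1L
        qv <- psi * (phi[iP] + phi[iE]) / 2 +
          (1 - psi) * (1.5 * phi[iP] - 0.5 * phi[pmax(iW, 1L)])
        ho[ok] <- qv[ok]
      } else {
        iW <- iE + 1L
        ok <- iW <= N
        qv <- psi * (phi[iE] + phi[iP]) / 2 +
          (1 - psi) * (1.5 * phi[iE] - 0.5 * phi[pmin(iW, N)])
        ho[ok] <- qv[ok]
      }
    }
    list(ho = ho, up = up)
  }

  phi <- phi0 + (phiL - phi0) * x   # linear initial guess
  src <- NULL
  trace <- numeric(0)
  for (it in seq_len(max_outer)) {
    fh <- face_ho(phi)
    corr <- Fl * (fh$ho - fh$up)
    s <- numeric(N)
    s[1:(N - 1L)] <- s[1:(N - 1L)] - corr
    s[2:N] <- s[2:N] + corr
    if (scheme != "fou") {
      # higher-order outflow face value = Dirichlet boundary value
      if (Fl >= 0) s[N] <- s[N] - Fl * (phiL - phi[N])
      else s[1L] <- s[1L] - (-Fl) * (phi0 - phi[1L])
    }
    src <- if (is.null(src)) s else src + dc_relax * (s - src)
    rhs <- rhs0 + src
    res <- sum(abs(rhs - as.vector(A %*% phi))) /
      max(sum(abs(dia * phi)), 1e-30)
    trace <- c(trace, res)
    if (it > 1L && res <= tol) break
    phi <- as.vector(Matrix::solve(lu, rhs))
  }
  list(x = x, phi = phi, residuals = trace, iterations = length(trace),
       h = h, scheme = scheme)
}

#' Convergence-order study on the 1-D benchmark
#'
#' Solves the 1-D benchmark over a refinement sequence for each scheme and
#' estimates the observed convergence order as the least-squares slope of
#' `log(L2 error)` against `log(1/N)`, with the exact exponential profile
#' as oracle.
#'
#' @param Pe Peclet number (default 10).
#' @param Ns Refinement sequence of cell counts.
#' @param schemes Character vector of schemes.
#' @param psi QUICK blend weight.
#' @return List with `errors` (data.frame scheme/N/l2) and `orders` (named
#'   numeric, one observed order per scheme).
#' @export
scheme_order_study <- function(Pe = 10, Ns = c(20, 40, 80, 160, 320),
                               schemes = c("fou", "power_law", "sou", "quick"),
                               psi = 0.75) {
  rows <- list()
  for (sc in schemes) for (N in Ns) {
    b <- generate_1d_benchmark(Pe, N)
    sol <- solve_1d_scheme(Pe, N, scheme = sc, psi = psi)
    err <- sqrt(mean((sol$phi - b$exact(sol$x))^2))
    rows[[length(rows) + 1L]] <- data.frame(scheme = sc, N = N, l2 = err)
  }
  errors <- do.call(rbind, rows)
  orders <- vapply(schemes, function(sc) {
    d <- errors[errors$scheme == sc, ]
    -stats::coef(stats::lm(log(d$l2) ~ log(d$N)))[[2]]
  }, numeric(1))
  list(errors = errors, orders = orders)
}

#' Oblique-step pure-convection fixture
#'
#' Uniform velocity at `angle` degrees to the grid on the unit square with
#' zero diffusion; the inflow carries a step (1 on the west boundary, 0 on
#' the south boundary) whose exact steady solution is the unsmeared step
#' convected along the dividing streamline through the origin.  Because the
#' flow crosses the grid obliquely, low-order upwinding smears the step
#' (false diffusion); the mid-domain transition width quantifies it.
#'
#' @param angle Flow angle in degrees, strictly between 0 and 90.
#' @param N Cells per side.
#' @return List of class `oblique_step` with the velocity components, grid
#'   and `exact(x, y)` sampler.
#' @export
generate_oblique_step <- function(angle = 45, N = 64) {
  if (!(angle > 0 && angle < 90)) stop("angle must lie strictly in (0, 90)")
  N <- as.integer(N)
  if (N < 4L) stop("N must be >= 4")
  th <- angle * pi / 180
  structure(list(angle = angle, N = N, h = 1 / N,
                 u = cos(th), v = sin(th),
                 x = (seq_len(N) - 0.5) / N, y = (seq_len(N) - 0.5) / N,
                 exact = function(x, y)
                   as.numeric(y * cos(th) - x * sin(th) > 0)),
            class = "oblique_step")
}

#' Solve the oblique-step fixture with a chosen scheme
#'
#' Steady pure-convection solve on the Cartesian grid: implicit first-order
#' upwinding plus converged deferred correction for the higher-order
#' schemes.  With zero diffusion the power-law scheme reduces exactly to
#' first-order upwinding, so the interesting comparisons are FOU vs SOU vs
#' QUICK.
#'
#' @param fixture A [generate_oblique_step()] result.
#' @param scheme `"fou"`, `"power_law"`, `"sou"` or `"quick"`.
#' @param psi QUICK blend weight.
#' @param tol Outer residual tolerance.
#' @param max_outer Outer iteration cap.
#' @param dc_relax Deferred-correction under-relaxation.
#' @return List with the `field` (N x N matrix, x by y), the fixture and
#'   the residual trace.
#' @export
solve_oblique_step <- function(fixture, scheme = "fou", psi = 0.75,
                               tol = 1e-10, max_outer = 3000,
                               dc_relax = 0.8) {
  stopifnot(inherits(fixture, "oblique_step"))
  scheme <- match.arg(scheme, c("fou", "power_law", "sou", "quick"))
  N <- fixture$N; h <- fixture$h; n <- N * N
  Fx <- fixture$u * h; Fy <- fixture$v * h   # face fluxes, both positive
  k <- matrix(seq_len(n), N, N)

  dia <- numeric(n)
  P <- as.vector(k[1:(N - 1L), ]); E <- as.vector(k[2:N, ])
  Pv <- as.vector(k[, 1:(N - 1L)]); Ev <- as.vector(k[, 2:N])
  dia[P] <- dia[P] + Fx           # positive flux: upwind is P
  dia[Pv] <- dia[Pv] + Fy
  dia[as.vector(k[N, ])] <- dia[as.vector(k[N, ])] + Fx   # east outflow
  dia[as.vector(k[, N])] <- dia[as.vector(k[, N])] + Fy   # north outflow
  # inflow on west (phi = 1) and south (phi = 0) boundaries
  rhs0 <- numeric(n)
  rhs0[as.vector(k[1L, ])] <- rhs0[as.vector(k[1L, ])] + Fx * 1
  # south inflow value 0 contributes nothing
  oi <- c(E, Ev); oj <- c(P, Pv); ox <- c(rep(-Fx, length(P)), rep(-Fy, length(Pv)))
  A <- Matrix::sparseMatrix(i = c(seq_len(n), oi), j = c(seq_len(n), oj),
                            x = c(dia, ox), dims = c(n, n))
  lu <- Matrix::lu(A)

  dc <- function(phi) {
    if (scheme %in% c("fou", "power_law")) return(numeric(n))
    # Green-Gauss gradients with boundary face values (west 1, south 0)
    fx <- matrix(0, N + 1L, N)
    fx[2:N, ] <- (phi[1:(N - 1L), ] + phi[2:N, ]) / 2
    fx[1L, ] <- 1; fx[N + 1L, ] <- phi[N, ]
    fy <- matrix(0, N, N + 1L)
    fy[, 2:N] <- (phi[, 1:(N - 1L)] + phi[, 2:N]) / 2
    fy[, 1L] <- 0; fy[, N + 1L] <- phi[, N]
    gx <- (fx[2:(N + 1L), ] - fx[1:N, ]) / h
    gy <- (fy[, 2:(N + 1L)] - fy[, 1:N]) / h
    s <- numeric(n)
    # x faces (flux positive, upwind = cell i-1)
    up <- phi[1:(N - 1L), , drop = FALSE]
    ho <- up + gx[1:(N - 1L), , drop = FALSE] * (h / 2)
    if (scheme == "quick" && N >= 3L) {
      qW <- rbind(rep(NA_real_, N), phi[1:(N - 2L), , drop = FALSE])
      qv <- psi * (up + phi[2:N, , drop = FALSE]) / 2 +
        (1 - psi) * (1.5 * up - 0.5 * qW)
      ho <- ifelse(is.na(qW), ho, qv)
    }
    corr <- Fx * (ho - up)
    s[P] <- s[P] - as.vector(corr); s[E] <- s[E] + as.vector(corr)
    # y faces
    up <- phi[, 1:(N - 1L), drop = FALSE]
    ho <- up + gy[, 1:(N - 1L), drop = FALSE] * (h / 2)
    if (scheme == "quick" && N >= 3L) {
      qW <- cbind(rep(NA_real_, N), phi[, 1:(N - 2L), drop = FALSE])
      qv <- psi * (up + phi[, 2:N, drop = FALSE]) / 2 +
        (1 - psi) * (1.5 * up - 0.5 * qW)
      ho <- ifelse(is.na(qW), ho, qv)
    }
    corr <- Fy * (ho - up)
    s[Pv] <- s[Pv] - as.vector(corr); s[Ev] <- s[Ev] + as.vector(corr)
    s
  }

  phi <- numeric(n)
  src <- NULL
  trace <- numeric(0)
  for (it in seq_len(max_outer)) {
    s <- dc(matrix(phi, N, N))
    src <- if (is.null(src)) s else src + dc_relax * (s - src)
    rhs <- rhs0 + src
    res <- sum(abs(rhs - as.vector(A %*% phi))) / max(sum(abs(dia * phi)), 1e-30)
    trace <- c(trace, res)
    if (it > 1L && res <= tol) break
    phi <- as.vector(Matrix::solve(lu, rhs))
  }
  list(field = matrix(phi, N, N), fixture = fixture,
       residuals = trace, scheme = scheme)
}

#' Transition width of a solved oblique-step field
#'
#' Width of the 0.1-0.9 normalised transition along the mid-domain vertical
#' line, robust to higher-order over/undershoots: the lower edge is the
#' last height below which the profile stays at or below 0.1, the upper
#' edge the first height above which it stays at or above 0.9, each refined
#' by linear interpolation.
#'
#' @param solution A [solve_oblique_step()] result.
#' @return Transition width in domain units.
#' @export
transition_width <- function(solution) {
  f <- solution$field; N <- solution$fixture$N
  y <- solution$fixture$y
  prof <- f[max(1L, N %/% 2L), ]
  below <- cumsum(prof > 0.1) == 0          # prefix all <= 0.1
  j_lo <- if (any(below)) max(which(below)) else 0L
  above <- rev(cumsum(rev(prof < 0.9)) == 0) # suffix all >= 0.9
  j_hi <- if (any(above)) min(which(above)) else N + 1L
  y_lo <- if (j_lo >= 1L && j_lo < N)
    y[j_lo] + (0.1 - prof[j_lo]) / (prof[j_lo + 1L] - prof[j_lo]) *
      (y[j_lo + 1L] - y[j_lo]) else if (j_lo == 0L) y[1L] else y[N]
  y_hi <- if (j_hi > 1L && j_hi <= N)
    y[j_hi - 1L] + (0.9 - prof[j_hi - 1L]) / (prof[j_hi] - prof[j_hi - 1L]) *
      (y[j_hi] - y[j_hi - 1L]) else if (j_hi > N) y[N] else y[1L]
  max(y_hi - y_lo, 0)
}

#' Stokes-Einstein diffusivity of a spherical molecule
#'
#' `D = k_B T / (6 pi mu a)` with Boltzmann's constant
#' `k_B = 1.380649e-23` J/K.  Doubling the viscosity halves the
#' diffusivity; the `T -> 0` limit is zero.
#'
#' @param temperature Absolute temperature, K (>= 0).
#' @param viscosity Dynamic viscosity, Pa s (> 0).
#' @param radius Molecule radius, m (> 0).
#' @return Diffusivity, m^2/s.
#' @export
stokes_einstein_diffusivity <- function(temperature, viscosity, radius) {
  if (any(temperature < 0) || any(viscosity <= 0) || any(radius <= 0))
    stop("temperature must be >= 0; viscosity and radius must be positive")
  1.380649e-23 * temperature / (6 * pi * viscosity * radius)
}
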