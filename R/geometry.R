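#' Idealised axisymmetric aneurysm geometry
#'
#' Describes the idealised fusiform aneurysm used throughout the package: a
#' straight tube of radius `inlet_radius` that bulges smoothly to `max_radius`
#' at the midpoint of a sac of length `sac_length`, returning to the inlet
#' radius at the sac outlet.  The wall profile is a raised-cosine (`sin^2`)
#' bulge, which is smooth, symmetric and matches the three defining
#' dimensions.  Straight entrance and exit extensions (expressed in inlet
#' diameters) keep the inflow and outflow boundaries away from the sac.
#'
#' The default dimensions are an inlet/outlet diameter of 25.1 mm, a maximum
#' sac diameter of 50.2 mm and a sac length of 75.3 mm.
#'
#' The axial coordinate `z` is zero at the sac inlet and positive streamwise,
#' so the meshed domain spans `[-entrance_length, sac_length + exit_length]`.
#' All lengths are SI metres.
#'
#' @param inlet_radius Inlet/outlet tube radius in metres.
#' @param max_radius Maximum sac radius in metres (must be >= `inlet_radius`;
#'   equality gives a straight tube).
#' @param sac_length Axial length of the bulged section in metres.
#' @param entrance_diameters Length of the straight entrance extension in
#'   inlet diameters (>= 0).
#' @param exit_diameters Length of the straight exit extension in inlet
#'   diameters (>= 0).
#' @return An object of class `aneurysm_geometry`.
#' @examples
#' geo <- aneurysm_geometry()
#' wall_radius(geo, geo$sac_length / 2)  # 0.0251 m at the sac midpoint
#' @export
aneurysm_geometry <- function(inlet_radius = 0.01255,
                              max_radius = 0.0251,
                              sac_length = 0.0753,
                              entrance_diameters = 2,
                              exit_diameters = 4) {
  stopifnot(is.numeric(inlet_radius), length(inlet_radius) == 1L,
            is.numeric(max_radius), length(max_radius) == 1L,
            is.numeric(sac_length), length(sac_length) == 1L)
  if (!(inlet_radius > 0)) stop("inlet_radius must be positive")
  if (max_radius < inlet_radius)
    stop("max_radius must be >= inlet_radius")
  if (!(sac_length > 0)) stop("sac_length must be positive")
  if (entrance_diameters < 0 || exit_diameters < 0)
    stop("entrance/exit extensions must be non-negative")
  d_in <- 2 * inlet_radius
  structure(list(
    inlet_radius = inlet_radius,
    max_radius = max_radius,
    sac_length = sac_length,
    entrance_length = entrance_diameters * d_in,
    exit_length = exit_diameters * d_in,
    inlet_diameter = d_in,
    wall_profile_id = "cosine_bulge"
  ), class = "aneurysm_geometry")
}

#' Straight-tube geometry
#'
#' Degenerate aneurysm geometry with no bulge, used for validation cases
#' (Poiseuille flow, film mass transfer, pure-convection fronts).
#'
#' @param radius Tube radius in metres.
#' @param length Tube length in metres.
#' @return An `aneurysm_geometry` whose wall radius is constant.
#' @export
tube_geometry <- function(radius, length) {
  aneurysm_geometry(inlet_radius = radius, max_radius = radius,
                    sac_length = length,
                    entrance_diameters = 0, exit_diameters = 0)
}

#' @export
print.aneurysm_geometry <- function(x, ...) {
  cat("Idealised axisymmetric aneurysm geometry\n")
  cat(sprintf("  inlet/outlet diameter : %.4g mm\n", 2e3 * x$inlet_radius))
  cat(sprintf("  maximum sac diameter  : %.4g mm\n", 2e3 * x$max_radius))
  cat(sprintf("  sac length            : %.4g mm\n", 1e3 * x$sac_length))
  cat(sprintf("  entrance / exit       : %.4g / %.4g mm\n",
              1e3 * x$entrance_length, 1e3 * x$exit_length))
  invisible(x)
}

#' Wall radius of the idealised aneurysm
#'
#' Evaluates the wall-radius profile at axial position(s) `z` (z = 0 at the
#' sac inlet).  Outside the sac the radius equals the inlet radius; inside it
#' follows `inlet_radius + (max_radius - inlet_radius) * sin^2(pi z / L)`,
#' which is continuous, equals the inlet radius at both sac ends, and peaks
#' at the sac midpoint.
#'
#' @param geometry An [aneurysm_geometry()].
#' @param z Axial position(s) in metres, within
#'   `[-entrance_length, sac_length + exit_length]`.
#' @return Wall radius in metres, vectorised over `z`.
#' @export
wall_radius <- function(geometry, z) {
  stopifnot(inherits(geometry, "aneurysm_geometry"))
  lo <- -geometry$entrance_length
  hi <- geometry$sac_length + geometry$exit_length
  tol <- 1e-12 * max(1, hi - lo)
  if (any(z < lo - tol | z > hi + tol))
    stop("z outside the domain [",
         signif(lo, 6), ", ", signif(hi, 6), "] m")
  r <- rep(geometry$inlet_radius, length(z))
  sac <- z > 0 & z < geometry$sac_length
  r[sac] <- geometry$inlet_radius +
    (geometry$max_radius - geometry$inlet_radius) *
    sin(pi * z[sac] / geometry$sac_length)^2
  r
}
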