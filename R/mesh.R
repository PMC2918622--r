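#' Generate the body-fitted structured quadrilateral mesh
#'
#' Builds an `ni x nj` structured grid for an axisymmetric geometry.  Axial
#' node stations are uniform; radial node lines are scaled to the local wall
#' radius so the grid is body fitted.  An optional geometric grading packs
#' cells toward the wall for boundary-layer resolution.
#'
#' Axisymmetric face areas and cell volumes are stored *per radian* of
#' revolved angle (the `2*pi` factor cancels in every flux balance):
#' a face swept from a straight segment has per-radian area
#' `mean(r) * segment length` directed along the segment normal, and cell
#' volumes are the exact per-radian swept volume of each quadrilateral
#' (second Pappus rule, evaluated edgewise).  Cell centroids are the planar
#' quadrilateral centroids, which makes the Green-Gauss gradient exact for
#' linear fields on uniform grids.
#'
#' Boundary faces are tagged implicitly by the structured layout: logical
#' `i = 1` faces are the inlet, `i = ni + 1` the outlet, `j = 1` the axis
#' (zero swept area because r = 0 there) and `j = nj + 1` the wall.
#'
#' @param geometry An [aneurysm_geometry()].
#' @param ni Number of axial cells (>= 8 for the aneurysm; >= 1 accepted for
#'   degenerate test meshes).
#' @param nj Number of radial cells (>= 1).
#' @param wall_stretch Ratio of the axis-adjacent cell height to the
#'   wall-adjacent cell height (>= 1; 1 = uniform).  Cell heights follow a
#'   geometric progression, so refining `nj` at fixed `wall_stretch` keeps
#'   the relative size distribution and halves every cell.
#' @return An object of class `structured_mesh`.
#' @examples
#' m <- generate_mesh(aneurysm_geometry(), ni = 60, nj = 16)
#' mesh_quality(m)
#' @export
generate_mesh <- function(geometry, ni = 240, nj = 60, wall_stretch = 1) {
  stopifnot(inherits(geometry, "aneurysm_geometry"))
  ni <- as.integer(ni); nj <- as.integer(nj)
  if (ni < 1L || nj < 1L) stop("ni and nj must be positive integers")
  if (wall_stretch < 1) stop("wall_stretch must be >= 1")
  if (!(geometry$inlet_radius > 0)) stop("degenerate geometry: non-positive radius")

  z0 <- -geometry$entrance_length
  z1 <- geometry$sac_length + geometry$exit_length
  z <- seq(z0, z1, length.out = ni + 1L)
  rw <- wall_radius(geometry, z)

  # radial node fractions: cell heights ~ q^j shrinking toward the wall
  if (nj == 1L || wall_stretch == 1) {
    s <- seq(0, 1, length.out = nj + 1L)
  } else {
    q <- wall_stretch^(-1 / (nj - 1))
    h <- q^(0:(nj - 1L))
    s <- c(0, cumsum(h)) / sum(h)
    s[nj + 1L] <- 1
  }

  r_node <- outer(rw, s)                       # (ni+1) x (nj+1)
  z_node <- matrix(z, ni + 1L, nj + 1L)

  ii <- 1:ni; jj <- 1:nj
  # cell corner coordinates (ccw in the (z, r) plane)
  x00 <- z_node[ii, jj, drop = FALSE];     y00 <- r_node[ii, jj, drop = FALSE]
  x10 <- z_node[ii + 1L, jj, drop = FALSE]; y10 <- r_node[ii + 1L, jj, drop = FALSE]
  x11 <- z_node[ii + 1L, jj + 1L, drop = FALSE]; y11 <- r_node[ii + 1L, jj + 1L, drop = FALSE]
  x01 <- z_node[ii, jj + 1L, drop = FALSE]; y01 <- r_node[ii, jj + 1L, drop = FALSE]

  cross_sum <- function(xa, ya, xb, yb) xa * yb - xb * ya
  c1 <- cross_sum(x00, y00, x10, y10)
  c2 <- cross_sum(x10, y10, x11, y11)
  c3 <- cross_sum(x11, y11, x01, y01)
  c4 <- cross_sum(x01, y01, x00, y00)
  parea <- 0.5 * (c1 + c2 + c3 + c4)           # planar (z, r) area, ccw > 0
  if (any(parea <= 0)) stop("degenerate geometry: non-positive cell area")
  cz <- ((x00 + x10) * c1 + (x10 + x11) * c2 +
         (x11 + x01) * c3 + (x01 + x00) * c4) / (6 * parea)
  cr <- ((y00 + y10) * c1 + (y10 + y11) * c2 +
         (y11 + y01) * c3 + (y01 + y00) * c4) / (6 * parea)

  # per-radian swept volume: V = -sum_edges dz*(r1^2 + r1 r2 + r2^2)/6 (ccw)
  edge_v <- function(xa, ya, xb, yb) (xb - xa) * (ya * ya + ya * yb + yb * yb) / 6
  vol <- -(edge_v(x00, y00, x10, y10) + edge_v(x10, y10, x11, y11) +
           edge_v(x11, y11, x01, y01) + edge_v(x01, y01, x00, y00))
  if (any(vol <= 0)) stop("degenerate geometry: non-positive cell volume")

  # u-faces (constant-z segments), normal +z; per-radian area = (r2^2-r1^2)/2
  iu <- 1:(ni + 1L)
  uf_Az <- (r_node[iu, jj + 1L, drop = FALSE]^2 - r_node[iu, jj, drop = FALSE]^2) / 2
  uf_cz <- z_node[iu, jj, drop = FALSE]
  uf_cr <- (r_node[iu, jj, drop = FALSE] + r_node[iu, jj + 1L, drop = FALSE]) / 2

  # v-faces (sloped segments between axial stations), normal toward +j
  jv <- 1:(nj + 1L)
  vdz <- z_node[ii + 1L, jv, drop = FALSE] - z_node[ii, jv, drop = FALSE]
  vdr <- r_node[ii + 1L, jv, drop = FALSE] - r_node[ii, jv, drop = FALSE]
  vrb <- (r_node[ii, jv, drop = FALSE] + r_node[ii + 1L, jv, drop = FALSE]) / 2
  vf_Az <- -vdr * vrb
  vf_Ar <- vdz * vrb
  vf_cz <- (z_node[ii, jv, drop = FALSE] + z_node[ii + 1L, jv, drop = FALSE]) / 2
  vf_cr <- vrb
  vf_mag <- vrb * sqrt(vdz^2 + vdr^2)

  # geometric diffusion factors |A|^2 / (A . d) for two-point normal gradients
  gdu <- NULL
  if (ni >= 2L) {
    dcz <- cz[2:ni, , drop = FALSE] - cz[1:(ni - 1L), , drop = FALSE]
    gdu <- uf_Az[2:ni, , drop = FALSE] / dcz
  }
  gdv <- NULL
  if (nj >= 2L) {
    az <- vf_Az[, 2:nj, drop = FALSE]; ar <- vf_Ar[, 2:nj, drop = FALSE]
    ddz <- cz[, 2:nj, drop = FALSE] - cz[, 1:(nj - 1L), drop = FALSE]
    ddr <- cr[, 2:nj, drop = FALSE] - cr[, 1:(nj - 1L), drop = FALSE]
    gdv <- (az^2 + ar^2) / (az * ddz + ar * ddr)
  }
  gdb_in <- uf_Az[1L, ] / abs(cz[1L, ] - uf_cz[1L, ])
  gdb_out <- uf_Az[ni + 1L, ] / abs(uf_cz[ni + 1L, ] - cz[ni, ])
  aw <- vf_Az[, nj + 1L]; arw <- vf_Ar[, nj + 1L]
  gdb_wall <- (aw^2 + arw^2) /
    abs(aw * (vf_cz[, nj + 1L] - cz[, nj]) + arw * (vf_cr[, nj + 1L] - cr[, nj]))

  structure(list(
    geometry = geometry, ni = ni, nj = nj,
    wall_stretch = wall_stretch,
    z = z, s = s, rw = rw,
    z_node = z_node, r_node = r_node,
    cz = cz, cr = cr, vol = vol, parea = parea,
    uf_Az = uf_Az, uf_cz = uf_cz, uf_cr = uf_cr,
    vf_Az = vf_Az, vf_Ar = vf_Ar, vf_cz = vf_cz, vf_cr = vf_cr,
    vf_mag = vf_mag,
    gdu = gdu, gdv = gdv,
    gdb_in = gdb_in, gdb_out = gdb_out, gdb_wall = gdb_wall,
    wz = diff(z),
    hr = (r_node[ii, jj + 1L, drop = FALSE] - r_node[ii, jj, drop = FALSE] +
          r_node[ii + 1L, jj + 1L, drop = FALSE] - r_node[ii + 1L, jj, drop = FALSE]) / 2,
    kmat = matrix(seq_len(ni * nj), ni, nj)
  ), class = "structured_mesh")
}

#' @export
print.structured_mesh <- function(x, ...) {
  cat(sprintf("Structured axisymmetric mesh: %d x %d cells (%d total)\n",
              x$ni, x$nj, x$ni * x$nj))
  cat(sprintf("  domain z in [%.4g, %.4g] m, total per-radian volume %.6g m^3\n",
              min(x$z), max(x$z), sum(x$vol)))
  if (x$wall_stretch != 1)
    cat(sprintf("  radial grading toward wall, stretch %.3g\n", x$wall_stretch))
  invisible(x)
}

#' Equiangle skew of a quadrilateral cell
#'
#' The worst angular deviation from the equiangular reference (90 degrees
#' for quadrilaterals), normalised to `[0, 1]`:
#' `max((theta_max - 90) / 90, (90 - theta_min) / 90)`.
#'
#' @param angles Numeric vector of the four interior corner angles in
#'   degrees of a simple quadrilateral.
#' @return Dimensionless skew in `[0, 1]`.
#' @examples
#' equiangle_skew(c(90, 90, 90, 90))    # 0
#' equiangle_skew(c(45, 135, 45, 135))  # 0.5
#' @export
equiangle_skew <- function(angles) {
  if (length(angles) != 4L || !is.numeric(angles))
    stop("four interior angles required")
  if (any(angles <= 0 | angles >= 180))
    stop("non-simple quadrilateral: angles must lie in (0, 180) degrees")
  max((max(angles) - 90) / 90, (90 - min(angles)) / 90)
}

# interior corner angles (degrees) of every cell; list of four ni x nj matrices
.cell_corner_angles <- function(mesh) {
  ii <- 1:mesh$ni; jj <- 1:mesh$nj
  zn <- mesh$z_node; rn <- mesh$r_node
  px <- list(zn[ii, jj], zn[ii + 1L, jj], zn[ii + 1L, jj + 1L], zn[ii, jj + 1L])
  py <- list(rn[ii, jj], rn[ii + 1L, jj], rn[ii + 1L, jj + 1L], rn[ii, jj + 1L])
  ang <- vector("list", 4L)
  for (k in 1:4) {
    kp <- if (k == 4L) 1L else k + 1L
    km <- if (k == 1L) 4L else k - 1L
    ax <- px[[kp]] - px[[k]]; ay <- py[[kp]] - py[[k]]
    bx <- px[[km]] - px[[k]]; by <- py[[km]] - py[[k]]
    ang[[k]] <- atan2(abs(ax * by - ay * bx), ax * bx + ay * by) * 180 / pi
  }
  ang
}

#' Mesh quality report
#'
#' Aggregates the per-cell equiangle skew and aspect ratio over a structured
#' mesh.  The aspect ratio of a cell is the mean length of its longer
#' opposite-edge pair divided by the mean length of its shorter pair.
#'
#' @param mesh A [generate_mesh()] result.
#' @return A list of class `mesh_quality_report` with `max_equiangle_skew`,
#'   `max_aspect_ratio` and `cell_count`.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "structured_mesh"))
  ang <- .cell_corner_angles(mesh)
  amax <- pmax(ang[[1]], ang[[2]], ang[[3]], ang[[4]])
  amin <- pmin(ang[[1]], ang[[2]], ang[[3]], ang[[4]])
  skew <- pmax((amax - 90) / 90, (90 - amin) / 90)

  ii <- 1:mesh$ni; jj <- 1:mesh$nj
  zn <- mesh$z_node; rn <- mesh$r_node
  elen <- function(xa, ya, xb, yb) sqrt((xb - xa)^2 + (yb - ya)^2)
  bot <- elen(zn[ii, jj], rn[ii, jj], zn[ii + 1L, jj], rn[ii + 1L, jj])
  top <- elen(zn[ii, jj + 1L], rn[ii, jj + 1L], zn[ii + 1L, jj + 1L], rn[ii + 1L, jj + 1L])
  lef <- elen(zn[ii, jj], rn[ii, jj], zn[ii, jj + 1L], rn[ii, jj + 1L])
  rig <- elen(zn[ii + 1L, jj], rn[ii + 1L, jj], zn[ii + 1L, jj + 1L], rn[ii + 1L, jj + 1L])
  mz <- (bot + top) / 2; mr <- (lef + rig) / 2
  aspect <- pmax(mz, mr) / pmin(mz, mr)

  structure(list(max_equiangle_skew = max(skew),
                 max_aspect_ratio = max(aspect),
                 cell_count = mesh$ni * mesh$nj),
            class = "mesh_quality_report")
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat(sprintf("Mesh quality: %d cells, max equiangle skew %.4f, max aspect ratio %.3f\n",
              x$cell_count, x$max_equiangle_skew, x$max_aspect_ratio))
  invisible(x)
}

#' Interpolate a cell-centred field at physical points
#'
#' Bilinear interpolation in the logical (index) space of the structured
#' grid: each query point is mapped to fractional logical coordinates using
#' the uniform axial spacing and the known radial node fractions, then the
#' cell-centroid field is interpolated bilinearly (clamped at boundaries).
#'
#' @param mesh A [generate_mesh()] result.
#' @param field `ni x nj` matrix of cell-centred values.
#' @param z,r Physical coordinates of the query points (vectors, metres).
#' @return Interpolated values, one per query point.
#' @export
interp_field <- function(mesh, field, z, r) {
  stopifnot(inherits(mesh, "structured_mesh"),
            all(dim(field) == c(mesh$ni, mesh$nj)), length(z) == length(r))
  zlo <- mesh$z[1L]; zhi <- mesh$z[mesh$ni + 1L]
  dz <- (zhi - zlo) / mesh$ni
  tol <- 1e-9 * (zhi - zlo)
  if (any(z < zlo - tol | z > zhi + tol)) stop("query point outside the axial domain")
  rw <- wall_radius(mesh$geometry, pmin(pmax(z, zlo), zhi))
  f <- r / rw
  if (any(r < -tol | f > 1 + 1e-9)) stop("query point outside the fluid domain")
  ui <- (z - zlo) / dz                       # node-based logical axial coord
  ji <- stats::approx(mesh$s, seq(0, mesh$nj), pmin(pmax(f, 0), 1),
                      rule = 2)$y
  bilin_axis <- function(a, n) {
    a <- pmin(pmax(a - 0.5, 0), n - 1)       # centroid-based coordinate
    i0 <- pmin(floor(a) + 1, n - 1); list(i0 = i0, w = a - (i0 - 1))
  }
  if (mesh$ni == 1L) { az <- list(i0 = rep(1, length(z)), w = rep(0, length(z))) } else az <- bilin_axis(ui, mesh$ni)
  if (mesh$nj == 1L) { ar <- list(i0 = rep(1, length(r)), w = rep(0, length(r))) } else ar <- bilin_axis(ji, mesh$nj)
  i0 <- az$i0; wz <- az$w; j0 <- ar$i0; wr <- ar$w
  i1 <- pmin(i0 + 1, mesh$ni); j1 <- pmin(j0 + 1, mesh$nj)
  (1 - wz) * (1 - wr) * field[cbind(i0, j0)] +
    wz * (1 - wr) * field[cbind(i1, j0)] +
    (1 - wz) * wr * field[cbind(i0, j1)] +
    wz * wr * field[cbind(i1, j1)]
}

#' Write a mesh (and optional cell fields) as a legacy ASCII VTK file
#'
#' Emits a `STRUCTURED_GRID` dataset with the mesh nodes and any number of
#' cell-centred scalar fields, plus a `boundary` cell field tagging cells
#' adjacent to the inlet (1), outlet (2), axis (3) and wall (4); interior
#' cells are 0.  Areas and volumes are stored per radian internally; the
#' written grid is the (z, r) plane.
#'
#' @param mesh A [generate_mesh()] result.
#' @param file Output path.
#' @param cell_data Named list of `ni x nj` matrices.
#' @return `file`, invisibly.
#' @export
write_vtk_structured <- function(mesh, file, cell_data = list()) {
  stopifnot(inherits(mesh, "structured_mesh"))
  ni <- mesh$ni; nj <- mesh$nj
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aneumt structured axisymmetric mesh (z, r per-radian measures)",
               "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", ni + 1L, nj + 1L),
               sprintf("POINTS %d double", (ni + 1L) * (nj + 1L))), con)
  pts <- cbind(as.vector(mesh$z_node), as.vector(mesh$r_node), 0)
  writeLines(sprintf("%.10g %.10g %g", pts[, 1], pts[, 2], pts[, 3]), con)
  tag <- matrix(0L, ni, nj)
  tag[, nj] <- 4L; tag[, 1L] <- 3L; tag[ni, ] <- 2L; tag[1L, ] <- 1L
  cell_data <- c(cell_data, list(boundary = tag))
  writeLines(sprintf("CELL_DATA %d", ni * nj), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", as.vector(cell_data[[nm]])), con)
  }
  invisible(file)
}

#' Write the mesh node table as CSV
#'
#' Plain node table with 0-based logical indices and physical coordinates,
#' columns `i, j, z, r`.
#'
#' @param mesh A [generate_mesh()] result.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_mesh_csv <- function(mesh, file) {
  stopifnot(inherits(mesh, "structured_mesh"))
  g <- expand.grid(i = 0:mesh$ni, j = 0:mesh$nj)
  utils::write.csv(data.frame(i = g$i, j = g$j,
                              z = as.vector(mesh$z_node),
                              r = as.vector(mesh$r_node)),
                   file, row.names = FALSE)
  invisible(file)
}
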