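#' Radius of a hemisphere of given volume
#'
#' Exact inversion of `V = (2/3) pi r^3`: `r = (3 V / (2 pi))^(1/3)`.
#' A withdrawn volume of 0.8 ml corresponds to a hemisphere radius of
#' 7.2558 mm.
#'
#' @param volume Hemisphere volume, m^3 (> 0).
#' @return Radius in metres.
#' @export
hemisphere_radius <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  (3 * volume / (2 * pi))^(1 / 3)
}

#' Equal-height slab partition of a hemisphere
#'
#' Splits a hemisphere of radius `r` into `n` slabs of equal height
#' `h = r / n`, measured from the flat face.  Slab `k` (k = 0..n-1) spans
#' heights `[k h, (k+1) h]` and has the exact cap-slab volume
#' `V_k = pi (r^2 h - (z_{k+1}^3 - z_k^3) / 3)` and volumetric centroid
#' height
#' `zbar_k = pi (r^2 (z_{k+1}^2 - z_k^2)/2 - (z_{k+1}^4 - z_k^4)/4) / V_k`.
#' The volumes sum to `(2/3) pi r^3` to round-off and decrease strictly
#' with `k` (shrinking cross-section).
#'
#' @param radius Hemisphere radius, m (> 0).
#' @param n_slabs Number of slabs (>= 1).
#' @return A data.frame with columns `slab`, `volume` (m^3) and
#'   `centroid_height` (m, from the flat face).
#' @export
slab_partition <- function(radius, n_slabs = 5) {
  if (!(radius > 0)) stop("radius must be positive")
  n_slabs <- as.integer(n_slabs)
  if (n_slabs < 1L) stop("n_slabs must be >= 1")
  h <- radius / n_slabs
  z0 <- (0:(n_slabs - 1L)) * h
  z1 <- z0 + h
  vol <- pi * (radius^2 * h - (z1^3 - z0^3) / 3)
  zc <- pi * (radius^2 * (z1^2 - z0^2) / 2 - (z1^4 - z0^4) / 4) / vol
  data.frame(slab = seq_len(n_slabs), volume = vol, centroid_height = zc)
}

#' Probe specification for the hemispherical extraction measurement
#'
#' Describes the emulated fluid-extraction measurement: a hemispherical
#' sampling volume whose flat face sits on the wall at the location of
#' maximum sac diameter, with its axis along the inward wall normal
#' (radially inward for the axisymmetric sac).  The hemisphere is divided
#' into `n_slabs` equal-height slabs; the concentration is read at each
#' slab's on-axis volumetric centroid and volume-weighted.
#'
#' Withdrawals of `extraction_volume` start at the `schedule` times and
#' last `withdrawal_s`; each is represented by an instantaneous sample of
#' the field at the withdrawal mid-time, reported at the nominal start
#' time.
#'
#' The default extraction volume of 0.8 ml implies a hemisphere radius of
#' 7.2558 mm by exact inversion; `radius_override` forces any other radius
#' (e.g. 3.37 mm) without changing the volume bookkeeping.
#'
#' @param extraction_volume Withdrawn volume, m^3 (default 0.8e-6).
#' @param n_slabs Number of equal-height slabs (default 5).
#' @param schedule Withdrawal start times, s (default 0, 120, 240, 360 —
#'   every second minute from time zero).
#' @param withdrawal_s Withdrawal duration, s (default 60).
#' @param radius_override Optional hemisphere radius in metres, replacing
#'   the radius implied by the volume.
#' @return A list of class `probe_spec`.
#' @export
probe_spec <- function(extraction_volume = 0.8e-6, n_slabs = 5,
                       schedule = c(0, 120, 240, 360), withdrawal_s = 60,
                       radius_override = NULL) {
  if (!(extraction_volume > 0)) stop("extraction_volume must be positive")
  if (n_slabs < 1) stop("n_slabs must be >= 1")
  structure(list(extraction_volume = extraction_volume,
                 n_slabs = as.integer(n_slabs),
                 schedule = schedule, withdrawal_s = withdrawal_s,
                 radius = if (is.null(radius_override))
                   hemisphere_radius(extraction_volume) else radius_override),
            class = "probe_spec")
}

#' Volume-weighted probe concentration from a field snapshot
#'
#' Reads the concentration at the on-axis volumetric centroid of each
#' equal-height slab of the probe hemisphere (anchored on the wall at the
#' maximum sac diameter, axis pointing radially inward) by bilinear
#' interpolation from cell centroids, and returns the volume-weighted
#' average `sum(V_k C_k) / sum(V_k)`.
#'
#' @param field `ni x nj` concentration field.
#' @param mesh A [generate_mesh()] result.
#' @param probe A [probe_spec()].
#' @return The volume-weighted normalised concentration.
#' @export
sample_concentration <- function(field, mesh, probe = probe_spec()) {
  stopifnot(inherits(mesh, "structured_mesh"), inherits(probe, "probe_spec"))
  geo <- mesh$geometry
  z_anchor <- geo$sac_length / 2
  r_wall <- wall_radius(geo, z_anchor)
  if (probe$radius > r_wall)
    stop("probe hemisphere (radius ", signif(probe$radius, 4),
         " m) does not fit inside the sac (wall-to-axis distance ",
         signif(r_wall, 4), " m)")
  slabs <- slab_partition(probe$radius, probe$n_slabs)
  r_pts <- r_wall - slabs$centroid_height
  bad <- r_pts < 0 | r_pts > r_wall
  if (any(bad))
    stop("slab ", paste(slabs$slab[bad], collapse = ", "),
         " centroid lies outside the fluid domain")
  vals <- interp_field(mesh, field, rep(z_anchor, nrow(slabs)), r_pts)
  sum(slabs$volume * vals) / sum(slabs$volume)
}

#' Probe concentration time series
#'
#' Container for a normalised-concentration time series at the extraction
#' site, computed or (pseudo-)experimental.  Times must be strictly
#' increasing and values finite.
#'
#' @param times Sample times, s.
#' @param values Normalised concentrations.
#' @param provenance `"computed"`, `"pseudo_experiment"` or `"external"`.
#' @return A list of class `probe_series`.
#' @export
probe_time_series <- function(times, values,
                              provenance = c("computed", "pseudo_experiment",
                                             "external")) {
  provenance <- match.arg(provenance)
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 provenance = provenance),
            class = "probe_series")
}

#' @export
print.probe_series <- function(x, ...) {
  cat(sprintf("Probe time series (%s), %d samples\n", x$provenance,
              length(x$times)))
  print(data.frame(time_s = x$times, c_norm = signif(x$values, 5)))
  invisible(x)
}

#' @export
as.data.frame.probe_series <- function(x, ...) {
  data.frame(time_s = x$times, c_norm = x$values, provenance = x$provenance)
}

#' Probe a transient transport result on the withdrawal schedule
#'
#' Samples the stored snapshots at each withdrawal mid-time
#' (`t + withdrawal_s / 2`) and reports them at the nominal schedule times.
#' The transient run must have been configured with snapshots at those
#' mid-times (see [pipeline_snapshot_times()]).
#'
#' @param result A `transport_result` from [run_transient()].
#' @param mesh The mesh of the run.
#' @param probe A [probe_spec()].
#' @return A [probe_time_series()] with provenance `"computed"`.
#' @export
probe_transient <- function(result, mesh, probe = probe_spec()) {
  stopifnot(inherits(result, "transport_result"))
  want <- probe$schedule + probe$withdrawal_s / 2
  have <- names(result$snapshots)
  vals <- vapply(want, function(t) {
    key <- as.character(t)
    if (!key %in% have)
      stop("no snapshot stored at sac time ", t,
           " s; configure snapshot_times accordingly")
    sample_concentration(result$snapshots[[key]], mesh, probe)
  }, numeric(1))
  probe_time_series(probe$schedule, vals, "computed")
}

#' Snapshot times needed to probe a withdrawal schedule
#'
#' @param probe A [probe_spec()].
#' @return Withdrawal mid-times, s.
#' @export
pipeline_snapshot_times <- function(probe = probe_spec()) {
  probe$schedule + probe$withdrawal_s / 2
}

#' Write / read a probe series as CSV
#'
#' Flat schema shared by computed and pseudo-experimental series:
#' columns `time_s`, `c_norm`, `provenance`.
#'
#' @param series A [probe_time_series()].
#' @param file Path.
#' @return `file` (write) or a [probe_time_series()] (read).
#' @export
write_probe_csv <- function(series, file) {
  utils::write.csv(as.data.frame(series), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_probe_csv
#' @export
read_probe_csv <- function(file) {
  d <- utils::read.csv(file)
  prov <- as.character(d$provenance[1])
  if (!prov %in% c("computed", "pseudo_experiment", "external"))
    prov <- "external"
  probe_time_series(d$time_s, d$c_norm, prov)
}
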