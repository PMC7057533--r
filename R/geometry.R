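# Detector geometry, per-pixel scattering angles, and the energy/angle to
# momentum-transfer mapping used throughout the reduction chain.

#' Detector geometry
#'
#' Describes a flat, square-pixel, energy-resolving detector facing the sample
#' along the beam axis.  Defaults correspond to an 80 x 80 pixel spectroscopic
#' detector with 0.25 mm pitch at a sample-to-detector distance (SDD) of
#' 214 mm, with the direct beam at the geometric center of the pixel grid.
#'
#' Pixel indices are 0-based `(row, col)`; pixel centers sit at integer index
#' times the pitch.  The beam center is given in the same fractional pixel
#' coordinate system and may lie outside the grid (off-center beam).
#'
#' @param n_rows,n_cols Pixel counts along the two detector axes.
#' @param pixel_pitch Pixel pitch in mm (center-to-center spacing).
#' @param sdd Sample-to-detector distance in mm.
#' @param beam_center Numeric length-2, `(row, col)` of the direct-beam
#'   position in fractional 0-based pixel coordinates.  Default: the geometric
#'   center of the grid.
#' @return An object of class `detector_geometry`.
#' @examples
#' geom <- detector_geometry()
#' geom
#' @export
detector_geometry <- function(n_rows = 80L, n_cols = 80L, pixel_pitch = 0.25,
                              sdd = 214, beam_center = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.null(beam_center)) {
    beam_center <- c((n_rows - 1) / 2, (n_cols - 1) / 2)
  }
  geom <- structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_pitch = pixel_pitch,
         sdd = sdd, beam_center = as.numeric(beam_center)),
    class = "detector_geometry")
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  with(geom, {
    if (!is.finite(sdd) || sdd <= 0) stop("invalid geometry: sdd must be finite and > 0")
    if (!is.finite(pixel_pitch) || pixel_pitch <= 0) stop("invalid geometry: pixel_pitch must be finite and > 0")
    if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
      stop("invalid geometry: n_rows and n_cols must be >= 1")
    if (length(beam_center) != 2L || any(!is.finite(beam_center)))
      stop("invalid geometry: beam_center must be two finite numbers")
  })
  invisible(geom)
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("Detector geometry: %d x %d pixels, pitch %g mm, SDD %g mm\n",
              x$n_rows, x$n_cols, x$pixel_pitch, x$sdd))
  cat(sprintf("  beam center (row, col) = (%.3f, %.3f) [0-based fractional pixels]\n",
              x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Per-pixel scattering angles and solid angles
#'
#' For the pixel at radial distance `r` (mm) from the beam center, the
#' scattering angle is `two_theta = atan(r / sdd)` (pixel-center point
#' approximation) and the subtended solid angle is
#' `(pixel_pitch^2 / sdd^2) * cos(two_theta)^3`, which accounts for the
#' increased distance and obliquity of off-axis pixels.
#'
#' @param geom A [detector_geometry()].
#' @return A list of class `angle_map` with matrices `two_theta` (radians) and
#'   `solid_angle` (steradians), both `n_rows x n_cols`, plus `r` (mm).
#' @export
compute_angle_map <- function(geom) {
  validate_geometry(geom)
  dy <- (seq_len(geom$n_rows) - 1 - geom$beam_center[1]) * geom$pixel_pitch
  dx <- (seq_len(geom$n_cols) - 1 - geom$beam_center[2]) * geom$pixel_pitch
  r <- sqrt(outer(dy^2, dx^2, `+`))
  two_theta <- atan(r / geom$sdd)
  solid_angle <- (geom$pixel_pitch^2 / geom$sdd^2) * cos(two_theta)^3
  structure(list(two_theta = two_theta, solid_angle = solid_angle, r = r),
            class = "angle_map")
}

#' Momentum transfer from photon energy and scattering angle
#'
#' `q = 4 * pi * E * sin(two_theta / 2) / hc` with `hc = 1.24 keV nm`, so that
#' `q` is in inverse nanometers when `energy` is in keV.
#'
#' @param energy Photon energy in keV (> 0).  Recycled against `two_theta`.
#' @param two_theta Scattering angle in radians, in `[0, pi)`.
#' @return Momentum transfer q in nm^-1.
#' @examples
#' q_transfer(31, 2 * asin(0.01))  # = pi
#' @export
q_transfer <- function(energy, two_theta) {
  if (any(energy <= 0) || any(!is.finite(energy)))
    stop("energy must be finite and > 0")
  if (any(two_theta < 0) || any(two_theta >= pi))
    stop("two_theta must lie in [0, pi)")
  4 * pi * energy * sin(two_theta / 2) / 1.24
}

#' Real-space spacing from momentum transfer
#'
#' `d = 2 * pi / q` (nm when q is in nm^-1).  The inverse relation
#' `q = 2 * pi / d` converts a lattice or repeat spacing to its peak position.
#'
#' @param q Momentum transfer, nm^-1 (> 0).
#' @return d-spacing in nm.
#' @export
d_spacing <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0")
  2 * pi / q
}

#' Accessible momentum-transfer range of a geometry and energy window
#'
#' The smallest q is reached at the lowest energy and the innermost usable
#' radius `r_min` (e.g. a beam-stop or direct-beam exclusion); the largest q
#' at the highest energy and the farthest pixel center from the beam.
#'
#' @param geom A [detector_geometry()].
#' @param energy_window Numeric length-2 `(low, high)` in keV, ordered.
#' @param r_min Innermost usable radius in mm (default 0).
#' @return Named numeric `c(q_min, q_max)` in nm^-1.
#' @export
accessible_q_range <- function(geom, energy_window = c(30, 45), r_min = 0) {
  validate_geometry(geom)
  if (length(energy_window) != 2L || energy_window[1] >= energy_window[2])
    stop("energy_window must be an ordered pair (low < high)")
  if (r_min < 0) stop("r_min must be >= 0")
  am <- compute_angle_map(geom)
  r_corner <- max(am$r)
  q_min <- if (r_min == 0) 0 else
    q_transfer(energy_window[1], atan(r_min / geom$sdd))
  q_max <- if (r_corner == 0) 0 else
    q_transfer(energy_window[2], atan(r_corner / geom$sdd))
  c(q_min = q_min, q_max = q_max)
}
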