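#' Cylindrical detector geometry
#'
#' Describes a diode array laid out on a cylinder, unwrapped to an
#' `n_axial` x `n_circ` matrix.  Row 1 is the most superior ring; column `j`
#' sits at azimuth `2*pi*(j-1)/n_circ`, with column 1 at the azimuth of
#' gantry zero (beam from above).  Defaults mimic a 21 x 66 = 1386 diode
#' cylindrical phantom of radius 104 mm and 10 mm ring pitch.
#'
#' @param n_axial number of diode rings (rows), at least 2.
#' @param n_circ number of diodes per ring (columns), at least 4.
#' @param radius cylinder radius in mm.
#' @param axial_pitch spacing between rings in mm.
#' @return an object of class `detector_geometry`.
#' @export
detector_geometry <- function(n_axial = 21L, n_circ = 66L,
                              radius = 104, axial_pitch = 10) {
  n_axial <- as.integer(n_axial); n_circ <- as.integer(n_circ)
  if (n_axial < 2L) stop("n_axial must be >= 2")
  if (n_circ < 4L) stop("n_circ must be >= 4")
  if (radius <= 0) stop("radius must be > 0")
  if (axial_pitch <= 0) stop("axial_pitch must be > 0")
  structure(list(n_axial = n_axial, n_circ = n_circ,
                 radius = radius, axial_pitch = axial_pitch),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d x %d diodes, radius %.1f mm, pitch %.1f mm\n",
              x$n_axial, x$n_circ, x$radius, x$axial_pitch))
  invisible(x)
}

#' Diode coordinates in room space
#'
#' Returns one row per diode (row-major over the unwrapped grid) with the
#' 3D position in the fixed room frame: `x` lateral, `y` vertical (up
#' positive), `z` along the cylinder/couch axis (superior positive, row 1
#' at the largest `z`).  Azimuth is measured from the vertical, in the
#' rotation sense of the gantry.
#'
#' @param geometry a [detector_geometry()].
#' @return data.frame with columns `row`, `col`, `x`, `y`, `z`, `phi`,
#'   `s` (circumferential arc length from column 1).
#' @export
diode_positions <- function(geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  rows <- seq_len(geometry$n_axial)
  cols <- seq_len(geometry$n_circ)
  z <- (( (geometry$n_axial + 1) / 2) - rows) * geometry$axial_pitch
  phi <- 2 * pi * (cols - 1) / geometry$n_circ
  g <- expand.grid(col = cols, row = rows)      # row-major blocks
  g <- g[, c("row", "col")]
  g$x <- geometry$radius * sin(phi[g$col])
  g$y <- geometry$radius * cos(phi[g$col])
  g$z <- z[g$row]
  g$phi <- phi[g$col]
  g$s <- geometry$radius * g$phi
  g
}

#' A detector dose map
#'
#' A non-negative `n_axial` x `n_circ` matrix of relative absorbed dose on
#' the cylinder surface, tied to its [detector_geometry()].
#'
#' @param values numeric matrix of doses, dimensions matching `geometry`.
#' @param geometry a [detector_geometry()].
#' @return object of class `detector_map`.
#' @export
detector_map <- function(values, geometry) {
  stopifnot(inherits(geometry, "detector_geometry"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(geometry$n_axial, geometry$n_circ)))
    stop(sprintf("values must be %d x %d to match geometry",
                 geometry$n_axial, geometry$n_circ))
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("dose values must be >= 0")
  structure(list(values = values, geometry = geometry),
            class = "detector_map")
}

#' @export
print.detector_map <- function(x, ...) {
  cat(sprintf("<detector_map> %d x %d, dose range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(unclass(a$geometry), unclass(b$geometry)))
}
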