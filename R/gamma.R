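#' Gamma-analysis criteria
#'
#' A clinical acceptance criterion triple: dose-difference tolerance (as a
#' fraction of the reference maximum under global normalization),
#' distance-to-agreement tolerance in mm, the low-dose exclusion threshold
#' (fraction of the reference maximum), and the pass-rate bound used for
#' plan approval ("pass" requires the gamma pass rate to be strictly
#' greater than the bound).
#'
#' @param dose_tol dose tolerance as a fraction, e.g. `0.03`.
#' @param dta_tol distance-to-agreement tolerance in mm, e.g. `3`.
#' @param low_dose_threshold exclude diodes whose reference dose is below
#'   this fraction of the reference maximum (default 0.10).
#' @param pass_rate_threshold approval bound in percent (95, 90 or 85 in
#'   the clinical standards).
#' @export
gamma_criteria <- function(dose_tol, dta_tol, low_dose_threshold = 0.10,
                           pass_rate_threshold = 95) {
  if (dose_tol <= 0 || dta_tol <= 0 || low_dose_threshold <= 0 ||
      pass_rate_threshold <= 0)
    stop("all criteria fields must be > 0")
  if (low_dose_threshold >= 1)
    stop("low_dose_threshold must be < 1")
  structure(list(dose_tol = dose_tol, dta_tol = dta_tol,
                 low_dose_threshold = low_dose_threshold,
                 pass_rate_threshold = pass_rate_threshold),
            class = "gamma_criteria")
}

#' The three standard clinical criteria
#'
#' 3%/3 mm with a 95% approval bound, 3%/2 mm with 90%, and 2%/2 mm with
#' 85% (the last bound is deliberately lenient: current guidelines state no
#' pass-rate requirement for 2%/2 mm).  All use a 10% low-dose threshold.
#'
#' @return named list of three [gamma_criteria()].
#' @export
clinical_criteria <- function() {
  list("3%/3mm" = gamma_criteria(0.03, 3, 0.10, 95),
       "3%/2mm" = gamma_criteria(0.03, 2, 0.10, 90),
       "2%/2mm" = gamma_criteria(0.02, 2, 0.10, 85))
}

# bilinear interpolation of a map at fractional (row, col), 0-based,
# circular in the column direction
interp_map <- function(values, rr, cc) {
  R <- nrow(values); C <- ncol(values)
  r0 <- pmin(floor(rr), R - 2); fr <- rr - r0
  cw <- cc %% C
  c0 <- floor(cw); c1 <- (c0 + 1) %% C; fc <- cw - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c1 + 1)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c1 + 1)
  (1 - fr) * ((1 - fc) * values[i00] + fc * values[i01]) +
    fr * ((1 - fc) * values[i10] + fc * values[i11])
}

#' Gamma index of a single evaluated point
#'
#' Minimizes, over candidate positions of the continuous reference surface
#' within a disk of radius `3 * dta_tol` (sub-lattice step `dta_tol / 10`,
#' reference dose bilinearly interpolated), the combined squared dose and
#' distance criterion and returns its square root.  Distance on the
#' cylinder is geodesic: circumferential arc length with wraparound plus
#' axial offset.
#'
#' @param ref_map reference [detector_map()].
#' @param eval_dose dose of the evaluated point.
#' @param eval_pos surface position `c(s, z)` of the evaluated point:
#'   circumferential arc length from column 1 and axial coordinate, mm.
#' @param criteria a [gamma_criteria()].
#' @param local_norm use local (per-point) dose normalization instead of
#'   the global reference maximum.
#' @param step_mm candidate-lattice step in mm (default `dta_tol / 10`).
#'   The gamma value is the exact minimum over this lattice; see the
#'   methods vignette for the discretization convention.
#' @return the gamma value (dimensionless, >= 0).
#' @export
gamma_point <- function(ref_map, eval_dose, eval_pos, criteria,
                        local_norm = FALSE, step_mm = NULL) {
  stopifnot(inherits(ref_map, "detector_map"),
            inherits(criteria, "gamma_criteria"))
  g <- ref_map$geometry
  ref_max <- max(ref_map$values)
  if (ref_max <= 0) stop("reference map maximum dose is zero")
  pitch_s <- 2 * pi * g$radius / g$n_circ
  z_top <- ((g$n_axial + 1) / 2 - 1) * g$axial_pitch
  cc0 <- eval_pos[1] / pitch_s
  rr0 <- (z_top - eval_pos[2]) / g$axial_pitch
  step <- if (is.null(step_mm)) criteria$dta_tol / 10 else step_mm
  radius <- 3 * criteria$dta_tol
  n <- ceiling(radius / step)
  ds <- rep(seq(-n, n) * step, times = 2 * n + 1)
  dz <- rep(seq(-n, n) * step, each = 2 * n + 1)
  keep <- ds^2 + dz^2 <= radius^2 + 1e-9
  ds <- ds[keep]; dz <- dz[keep]
  rr <- rr0 + dz / g$axial_pitch
  ok <- rr >= 0 & rr <= g$n_axial - 1
  ds <- ds[ok]; dz <- dz[ok]; rr <- rr[ok]
  dref <- interp_map(ref_map$values, rr, cc0 + ds / pitch_s)
  tol <- if (local_norm) criteria$dose_tol * dref else criteria$dose_tol * ref_max
  gam2 <- (ds^2 + dz^2) / criteria$dta_tol^2 + (eval_dose - dref)^2 / tol^2
  sqrt(min(gam2[tol > 0]))
}

#' Full gamma analysis of a calculated map against a measured map
#'
#' The measured map is the reference; normalization is global (by the
#' measured maximum) unless `local_norm`.  Diodes whose reference dose is
#' below `low_dose_threshold` times the reference maximum are excluded
#' from the analysis.  The gamma pass rate is the percentage of analyzed
#' diodes with gamma <= 1.
#'
#' @param measured reference [detector_map()] (the measurement).
#' @param calculated evaluated [detector_map()] (the planned dose).
#' @param criteria a [gamma_criteria()].
#' @param local_norm use local dose normalization (not used by the
#'   clinical comparisons here; provided for completeness).
#' @param step_mm candidate-lattice step in mm (default `dta_tol / 10`).
#' @return object of class `gamma_result` with fields `gamma_map` (NA at
#'   excluded diodes), `gpr` (percent), `n_analyzed`, `pass`, `criteria`.
#' @export
gamma_analysis <- function(measured, calculated, criteria,
                           local_norm = FALSE, step_mm = NULL) {
  stopifnot(inherits(measured, "detector_map"),
            inherits(calculated, "detector_map"),
            inherits(criteria, "gamma_criteria"))
  if (!same_geometry(measured, calculated))
    stop("measured and calculated maps must share one geometry")
  g <- measured$geometry
  ref_max <- max(measured$values)
  if (ref_max <= 0) stop("reference map maximum dose is zero")
  pitch_s <- 2 * pi * g$radius / g$n_circ
  gam <- .gamma_kernel(measured$values, calculated$values,
                       pitch_s, g$axial_pitch,
                       criteria$dose_tol, criteria$dta_tol,
                       3 * criteria$dta_tol,
                       if (is.null(step_mm)) criteria$dta_tol / 10 else step_mm,
                       local_norm)
  analyzed <- measured$values >= criteria$low_dose_threshold * ref_max
  gam[!analyzed] <- NA_real_
  n_analyzed <- sum(analyzed)
  if (n_analyzed == 0) stop("no diodes above the low-dose threshold")
  gpr <- 100 * sum(gam[analyzed] <= 1) / n_analyzed
  structure(list(gamma_map = gam, gpr = gpr, n_analyzed = n_analyzed,
                 pass = gpr > criteria$pass_rate_threshold,
                 criteria = criteria),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %.1f%%/%.1fmm: GPR %.2f%% (%d analyzed) -> %s\n",
              100 * x$criteria$dose_tol, x$criteria$dta_tol, x$gpr,
              x$n_analyzed, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Pass/fail decision from a gamma result
#'
#' Approval requires the gamma pass rate to be strictly greater than the
#' criterion's pass-rate bound.
#'
#' @param result a `gamma_result`.
#' @return logical: `TRUE` for pass.
#' @export
gpr_classify <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  result$gpr > result$criteria$pass_rate_threshold
}
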