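#' Rectangular beam aperture
#'
#' An opening in the beam's eye view, specified at the isocenter plane:
#' center `(cu, cv)` and half-widths `(hu, hv)` in mm.  `u` lies in the
#' gantry rotation plane, `v` along the couch axis (for collimator 0).
#'
#' @param cu,cv aperture center in mm at isocenter.
#' @param hu,hv half-widths in mm, strictly positive.
#' @export
aperture <- function(cu, cv, hu, hv) {
  if (hu <= 0 || hv <= 0)
    stop("aperture half-widths (hu, hv) must be > 0")
  structure(list(cu = cu, cv = cv, hu = hu, hv = hv), class = "aperture")
}

#' Beam configuration
#'
#' One static field, or one arc discretized into control points.  Arcs are
#' expanded at render time into `n_control_points` elementary beams evenly
#' spaced over `arc_span_deg` centred on `gantry_deg`, each carrying
#' `mu_weight / n_control_points` monitor units.  `cp_apertures`, when
#' given, supplies a per-control-point aperture list (modulated arc).
#'
#' @param gantry_deg gantry angle, degrees (0 = beam from above, IEC sense).
#' @param collimator_deg collimator rotation about the beam axis, degrees.
#' @param mu_weight relative monitor units delivered by the beam, > 0.
#' @param apertures list of [aperture()] objects (at least one).
#' @param is_arc logical; TRUE for an arc.
#' @param arc_span_deg arc length in degrees (arcs only).
#' @param n_control_points number of control points (arcs only, >= 8).
#' @param cp_apertures optional list (length `n_control_points`) of
#'   aperture lists, one per control point.
#' @export
beam_config <- function(gantry_deg, collimator_deg = 0, mu_weight = 1,
                        apertures, is_arc = FALSE, arc_span_deg = 360,
                        n_control_points = 36L, cp_apertures = NULL) {
  if (mu_weight <= 0) stop("mu_weight must be > 0")
  if (missing(apertures) || length(apertures) == 0)
    stop("at least one aperture is required")
  if (!all(vapply(apertures, inherits, TRUE, "aperture")))
    stop("apertures must be a list of aperture() objects")
  if (is_arc && n_control_points < 8L)
    stop("arc beams need n_control_points >= 8")
  if (!is.null(cp_apertures) && length(cp_apertures) != n_control_points)
    stop("cp_apertures must have one aperture list per control point")
  structure(list(gantry_deg = gantry_deg, collimator_deg = collimator_deg,
                 mu_weight = mu_weight, apertures = apertures,
                 is_arc = isTRUE(is_arc), arc_span_deg = arc_span_deg,
                 n_control_points = as.integer(n_control_points),
                 cp_apertures = cp_apertures),
            class = "beam_config")
}

ERROR_CLASSES <- c(normal = 0L, gantry = 1L, collimator = 2L,
                   couch = 3L, dose = 4L)

#' Delivery-error specification
#'
#' Exactly one error per plan: a rotational offset of the gantry,
#' collimator or couch (default 1 degree, the mechanical tolerance), a
#' monitor-unit scaling (default 2 percent, the output tolerance), or no
#' error at all.  Both signs of an offset belong to the same class.
#'
#' @param class one of `"normal"`, `"gantry"`, `"collimator"`, `"couch"`,
#'   `"dose"`, or the corresponding integer code 0-4.
#' @param magnitude degrees for rotational classes, fraction for dose;
#'   defaults 1 degree / 0.02, forced to 0 for `"normal"`.
#' @param sign +1 or -1.
#' @export
error_spec <- function(class = "normal", magnitude = NULL, sign = 1) {
  if (is.numeric(class)) class <- names(ERROR_CLASSES)[match(class, ERROR_CLASSES)]
  class <- match.arg(class, names(ERROR_CLASSES))
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1")
  if (is.null(magnitude))
    magnitude <- switch(class, normal = 0, dose = 0.02, 1.0)
  if (class == "normal") magnitude <- 0
  if (magnitude < 0) stop("magnitude must be >= 0 (use sign)")
  structure(list(class = class, code = ERROR_CLASSES[[class]],
                 magnitude = magnitude, sign = sign),
            class = "error_spec")
}

#' Simulation configuration
#'
#' Defaults reproduce the study design: 60 plans per class (300 total),
#' roughly two thirds IMRT, 0.5 percent multiplicative detector noise on
#' the measured channel, and gantry-error plans drawn only from IMRT
#' (gantry offsets cannot be emulated in a full arc).
#'
#' @param n_per_class plans per error class (>= 1).
#' @param mu_atten linear attenuation coefficient of the phantom, 1/mm.
#' @param noise_sigma measured-channel multiplicative noise, fraction of 1;
#'   0 gives the noise-free mode used by the analytic checks.
#' @param seed integer seed; the full dataset is a pure function of the
#'   configuration.
#' @param imrt_frac fraction of IMRT plans among classes that allow both
#'   techniques.
#' @param n_beams_range inclusive range of static-field counts for IMRT.
#' @param penumbra_sigma Gaussian penumbra width of field edges, mm.
#' @param sad source-axis distance, mm.
#' @param geometry a [detector_geometry()].
#' @export
sim_config <- function(n_per_class = 60L, mu_atten = 0.005,
                       noise_sigma = 0.005, seed = 1L,
                       imrt_frac = 0.66, n_beams_range = c(5L, 9L),
                       penumbra_sigma = 3.0, sad = 1000,
                       geometry = detector_geometry()) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (mu_atten < 0) stop("mu_atten must be >= 0")
  structure(list(n_per_class = as.integer(n_per_class), mu_atten = mu_atten,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 imrt_frac = imrt_frac,
                 n_beams_range = as.integer(n_beams_range),
                 penumbra_sigma = penumbra_sigma, sad = sad,
                 geometry = geometry),
            class = "sim_config")
}

## --- forward model -------------------------------------------------------

# Expand arcs to elementary (static) beams; returns a list of lists with
# gantry, collimator, mu, apertures.
expand_beams <- function(beams) {
  out <- list()
  for (b in beams) {
    if (!b$is_arc) {
      out[[length(out) + 1L]] <- list(gantry = b$gantry_deg,
                                      collimator = b$collimator_deg,
                                      mu = b$mu_weight,
                                      apertures = b$apertures)
    } else {
      n <- b$n_control_points
      ang <- b$gantry_deg + b$arc_span_deg * ((seq_len(n) - 0.5) / n - 0.5)
      for (i in seq_len(n)) {
        aps <- if (!is.null(b$cp_apertures)) b$cp_apertures[[i]] else b$apertures
        out[[length(out) + 1L]] <- list(gantry = ang[i],
                                        collimator = b$collimator_deg,
                                        mu = b$mu_weight / n,
                                        apertures = aps)
      }
    }
  }
  out
}

# Dose from one elementary beam at the diode points (matrix nx3, all lying
# on the phantom cylinder), using a divergent beam, erf-smoothed
# rectangular apertures, exponential attenuation along the chord through
# the cylinder, and inverse square.  A couch rotation of the phantom by
# +delta about the vertical axis is applied as the equivalent rotation of
# the beam frame by -delta, so diodes stay exactly on the cylinder and the
# chord geometry stays exact.
elementary_beam_dose <- function(pts, gantry_deg, collimator_deg, mu,
                                 apertures, radius, mu_atten,
                                 penumbra_sigma, sad, couch_deg = 0) {
  th <- gantry_deg * pi / 180
  S <- c(sin(th), cos(th), 0) * sad           # source position
  a <- -c(sin(th), cos(th), 0)                # beam axis unit vector
  eu <- c(cos(th), -sin(th), 0)               # transverse, rotation plane
  ev <- c(0, 0, 1)                            # axial
  if (couch_deg != 0) {
    al <- -couch_deg * pi / 180
    ry <- function(p) c(p[1] * cos(al) + p[3] * sin(al), p[2],
                        -p[1] * sin(al) + p[3] * cos(al))
    S <- ry(S); a <- ry(a); eu <- ry(eu); ev <- ry(ev)
  }
  w <- sweep(pts, 2, S)                       # source -> point
  l <- drop(w %*% a)                          # depth along axis
  scale <- sad / l
  u0 <- scale * drop(w %*% eu)
  v0 <- scale * drop(w %*% ev)
  # collimator rotates the aperture frame about the beam axis
  ps <- collimator_deg * pi / 180
  u <- u0 * cos(ps) + v0 * sin(ps)
  v <- -u0 * sin(ps) + v0 * cos(ps)
  trans <- 0
  for (ap in apertures) {
    tu <- pnorm((ap$cu + ap$hu - u) / penumbra_sigma) -
          pnorm((ap$cu - ap$hu - u) / penumbra_sigma)
    tv <- pnorm((ap$cv + ap$hv - v) / penumbra_sigma) -
          pnorm((ap$cv - ap$hv - v) / penumbra_sigma)
    trans <- trans + tu * tv
  }
  # chord through the cylinder x^2 + y^2 = R^2 from entry to the diode:
  # the segment S + t*w has t = 1 at the diode; the other quadratic root
  # gives the entry point when the ray crosses the interior first.
  wxy2 <- w[, 1]^2 + w[, 2]^2
  swxy <- S[1] * w[, 1] + S[2] * w[, 2]
  # roots of wxy2 t^2 + 2 swxy t + (|Sxy|^2 - R^2) = 0; product of roots:
  c0 <- (S[1]^2 + S[2]^2) - radius^2
  t_other <- c0 / (wxy2 * 1)                  # t1*t2 = c0/wxy2, one root is 1
  wlen <- sqrt(rowSums(w^2))
  path <- pmax(0, (1 - t_other)) * wlen
  att <- exp(-mu_atten * path)
  invsq <- (sad / wlen)^2
  mu * trans * att * invsq
}

#' Render a plan onto the detector
#'
#' Forward dose model: each diode receives, summed over elementary beams
#' (arcs expanded to control points), the product of monitor units, the
#' penumbra-smoothed aperture transmission of the diode's divergent
#' projection into the beam's eye view, exponential attenuation along the
#' chord through the phantom to the diode, and the inverse-square factor.
#' The requested delivery error is applied before rendering: gantry and
#' collimator offsets shift the respective angles of every beam, a couch
#' offset rotates the diode array about the vertical axis through
#' isocenter, and a dose error scales all monitor units by
#' `1 + sign * magnitude`.
#'
#' @param beams list of [beam_config()] objects (at least one).
#' @param geometry a [detector_geometry()].
#' @param error an [error_spec()]; default none.
#' @param config a [sim_config()] supplying the physics constants.
#' @return a [detector_map()].
#' @export
render_plan <- function(beams, geometry = detector_geometry(),
                        error = error_spec("normal"),
                        config = sim_config(geometry = geometry)) {
  if (length(beams) == 0) stop("at least one beam is required")
  if (inherits(beams, "beam_config")) beams <- list(beams)
  if (!all(vapply(beams, inherits, TRUE, "beam_config")))
    stop("beams must be beam_config objects")
  stopifnot(inherits(error, "error_spec"))
  delta <- error$sign * error$magnitude
  eb <- expand_beams(beams)
  if (error$class == "gantry")
    eb <- lapply(eb, function(b) { b$gantry <- b$gantry + delta; b })
  if (error$class == "collimator")
    eb <- lapply(eb, function(b) { b$collimator <- b$collimator + delta; b })
  if (error$class == "dose")
    eb <- lapply(eb, function(b) { b$mu <- b$mu * (1 + delta); b })

  pos <- diode_positions(geometry)
  pts <- cbind(pos$x, pos$y, pos$z)
  couch_deg <- if (error$class == "couch") delta else 0
  dose <- 0
  for (b in eb)
    dose <- dose + elementary_beam_dose(pts, b$gantry, b$collimator, b$mu,
                                        b$apertures, geometry$radius,
                                        config$mu_atten,
                                        config$penumbra_sigma, config$sad,
                                        couch_deg)
  m <- matrix(0, geometry$n_axial, geometry$n_circ)
  m[cbind(pos$row, pos$col)] <- pmax(dose, 0)
  detector_map(m, geometry)
}

#' Simulate a measurement of a dose map
#'
#' Applies independent multiplicative noise `Normal(1, noise_sigma)` per
#' diode (negative results clipped to zero); `noise_sigma = 0` returns the
#' input unchanged.  Reproducible for a given seed.
#'
#' @param true_map a [detector_map()].
#' @param noise_sigma noise standard deviation as a fraction, >= 0.
#' @param seed integer seed.
#' @return a [detector_map()].
#' @export
measure <- function(true_map, noise_sigma = 0.005, seed = 1L) {
  stopifnot(inherits(true_map, "detector_map"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (noise_sigma == 0) return(true_map)
  v <- true_map$values
  fac <- withr_seed(seed, matrix(rnorm(length(v), 1, noise_sigma),
                                 nrow(v), ncol(v)))
  detector_map(pmax(v * fac, 0), true_map$geometry)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## --- random plan generators ---------------------------------------------

random_apertures <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:3, 1)
  lapply(seq_len(n), function(i)
    aperture(cu = runif(1, -30, 30), cv = runif(1, -40, 40),
             hu = runif(1, 15, 50), hv = runif(1, 25, 70)))
}

random_imrt_plan <- function(config) {
  nb <- sample(seq(config$n_beams_range[1], config$n_beams_range[2]), 1)
  base <- runif(1, 0, 360)
  ang <- (base + 360 * (seq_len(nb) - 1) / nb + rnorm(nb, 0, 8)) %% 360
  lapply(seq_len(nb), function(i)
    beam_config(gantry_deg = ang[i],
                collimator_deg = runif(1, 0, 360),
                mu_weight = runif(1, 0.7, 1.3),
                apertures = random_apertures()))
}

random_vmat_plan <- function(config, n_cp = 36L) {
  # modulated full arc: aperture parameters interpolated between key points
  n_key <- 6L
  key <- replicate(n_key, unlist(random_apertures(1)[[1]])[c("cu", "cv", "hu", "hv")])
  key <- cbind(key, key[, 1])                  # close the loop
  tt <- seq(0, n_key, length.out = n_cp + 1L)[seq_len(n_cp)]
  interp <- function(k) approx(0:n_key, key[k, ], xout = tt)$y
  cps <- lapply(seq_len(n_cp), function(i)
    list(aperture(cu = interp("cu")[i], cv = interp("cv")[i],
                  hu = interp("hu")[i], hv = interp("hv")[i])))
  list(beam_config(gantry_deg = runif(1, 0, 360), collimator_deg = runif(1, 0, 360),
                   mu_weight = runif(1, 0.8 * 6, 1.2 * 6),
                   apertures = cps[[1]], is_arc = TRUE, arc_span_deg = 360,
                   n_control_points = n_cp, cp_apertures = cps))
}

#' Generate a balanced synthetic QA dataset
#'
#' Produces `5 * n_per_class` plan samples, exactly `n_per_class` per error
#' class.  Each sample pairs a "calculated" map rendered with its injected
#' error against an error-free "measured" map carrying multiplicative
#' detector noise.  Error signs alternate 50/50 within a class; gantry
#' errors are drawn only from IMRT-technique plans.  Bit-identical
#' reproduction for identical configurations.
#'
#' @param config a [sim_config()].
#' @return object of class `qa_dataset`: a list of `plan_sample`s, each with
#'   fields `calculated`, `measured`, `label` ([error_spec()]), `technique`
#'   (`"IMRT"`/`"VMAT"`) and `plan_id`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, {
    samples <- list()
    idx <- 0L
    for (cls in names(ERROR_CLASSES)) {
      for (i in seq_len(config$n_per_class)) {
        idx <- idx + 1L
        technique <- if (cls == "gantry") "IMRT"
                     else if (runif(1) < config$imrt_frac) "IMRT" else "VMAT"
        beams <- if (technique == "IMRT") random_imrt_plan(config)
                 else random_vmat_plan(config)
        sgn <- if (i %% 2 == 0) -1 else 1
        err <- error_spec(cls, sign = sgn)
        truth <- render_plan(beams, config$geometry, error_spec("normal"),
                             config)
        calc <- if (cls == "normal") truth
                else render_plan(beams, config$geometry, err, config)
        mseed <- sample.int(.Machine$integer.max, 1)
        meas <- measure(truth, config$noise_sigma, mseed)
        samples[[idx]] <- structure(
          list(calculated = calc, measured = meas, label = err,
               technique = technique,
               plan_id = sprintf("plan%04d", idx)),
          class = "plan_sample")
      }
    }
    structure(samples, class = "qa_dataset", config = config)
  })
}

#' @export
print.qa_dataset <- function(x, ...) {
  labs <- vapply(x, function(s) s$label$class, "")
  cat(sprintf("<qa_dataset> %d samples\n", length(x)))
  print(table(labs))
  invisible(x)
}

#' Class labels of a dataset
#' @param dataset a `qa_dataset`.
#' @return integer vector of class codes 0-4.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, function(s) s$label$code, 0L)
}
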