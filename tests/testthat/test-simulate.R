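geom <- detector_geometry()
cfg0 <- sim_config(noise_sigma = 0, seed = 7, geometry = geom)

test_that("geometry invariants hold and bad geometries are rejected", {
  pos <- diode_positions(geom)
  expect_equal(nrow(pos), 21 * 66)
  # diodes lie exactly on the cylinder
  expect_equal(sqrt(pos$x^2 + pos$y^2), rep(geom$radius, nrow(pos)))
  # column j maps to azimuth 2*pi*(j-1)/66
  expect_equal(pos$phi[pos$row == 1], 2 * pi * (0:65) / 66)
  # row 1 is the most superior ring
  expect_equal(max(pos$z), pos$z[1])
  expect_error(detector_geometry(1, 66), "n_axial")
  expect_error(detector_geometry(21, 3), "n_circ")
  expect_error(detector_geometry(radius = -1), "radius")
})

test_that("a dose error scales the whole map by exactly 1 +/- magnitude", {
  beams <- fixture_beams()
  m0 <- render_plan(beams, geom, error_spec("normal"), cfg0)
  mp <- render_plan(beams, geom, error_spec("dose", sign = 1), cfg0)
  mm <- render_plan(beams, geom, error_spec("dose", sign = -1), cfg0)
  expect_equal(mp$values, 1.02 * m0$values, tolerance = 1e-12)
  expect_equal(mm$values, 0.98 * m0$values, tolerance = 1e-12)
})

test_that("rendering is deterministic", {
  beams <- fixture_beams()
  a <- render_plan(beams, geom, error_spec("collimator"), cfg0)
  b <- render_plan(beams, geom, error_spec("collimator"), cfg0)
  expect_identical(a$values, b$values)
})

test_that("a 1-degree couch error perturbs diodes well above the noise floor", {
  # single beam from above; require max relative change > 10x noise_sigma
  beams <- list(beam_config(0, 0, 1, list(aperture(0, 0, 40, 60))))
  m0 <- render_plan(beams, geom, error_spec("normal"), cfg0)
  m1 <- render_plan(beams, geom, error_spec("couch", sign = 1), cfg0)
  hot <- m0$values > 0.1 * max(m0$values)
  rel <- max(abs(m1$values[hot] - m0$values[hot]) / m0$values[hot])
  expect_gt(rel, 10 * sim_config()$noise_sigma)
  expect_false(isTRUE(all.equal(m0$values, m1$values)))
})

test_that("geometric errors are not a constant rescaling of the map", {
  beams <- fixture_beams()
  m0 <- render_plan(beams, geom, error_spec("normal"), cfg0)
  for (cls in c("gantry", "collimator", "couch")) {
    m1 <- render_plan(beams, geom, error_spec(cls), cfg0)
    hot <- m0$values > 0.1 * max(m0$values)
    ratio <- m1$values[hot] / m0$values[hot]
    expect_gt(diff(range(ratio)), 0.01)
    expect_gt(max(abs(m1$values - m0$values)), 0)
  }
})

test_that("degenerate beam inputs are rejected by name", {
  expect_error(render_plan(list(), geom), "beam")
  expect_error(aperture(0, 0, -1, 10), "half-widths")
  expect_error(beam_config(0, 0, 0, list(aperture(0, 0, 10, 10))),
               "mu_weight")
  expect_error(beam_config(0, 0, 1, list(aperture(0, 0, 10, 10)),
                           is_arc = TRUE, n_control_points = 4),
               "control_points")
})

test_that("measure applies reproducible multiplicative noise", {
  m <- smooth_random_map(geom, seed = 3)
  expect_identical(measure(m, 0, 1)$values, m$values)
  a <- measure(m, 0.005, seed = 42)
  b <- measure(m, 0.005, seed = 42)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, m$values))
  # constant map of 1.0: sd of the output estimates noise_sigma
  flat <- detector_map(matrix(1, 21, 66), geom)
  s <- sd(measure(flat, 0.005, seed = 9)$values)
  expect_gt(s, 0.004); expect_lt(s, 0.006)
})

test_that("generate_dataset respects counts, balance and technique rules", {
  ds <- generate_dataset(sim_config(n_per_class = 3, noise_sigma = 0.005,
                                    seed = 5))
  expect_length(ds, 15)
  labs <- dataset_labels(ds)
  expect_equal(as.vector(table(labs)), rep(3L, 5))
  tech <- vapply(ds, function(s) s$technique, "")
  expect_equal(sum(tech == "VMAT" & labs == 1L), 0)
  # both signs appear within a rotational class
  signs <- vapply(ds, function(s) s$label$sign, 0)
  expect_setequal(unique(signs[labs == 3L]), c(1, -1))
  # plan ids unique
  expect_equal(anyDuplicated(vapply(ds, function(s) s$plan_id, "")), 0L)
})

test_that("datasets are bit-identical under the same configuration", {
  c1 <- sim_config(n_per_class = 1, seed = 99)
  d1 <- generate_dataset(c1)
  d2 <- generate_dataset(c1)
  expect_length(d1, 5)
  for (i in seq_along(d1)) {
    expect_identical(d1[[i]]$calculated$values, d2[[i]]$calculated$values)
    expect_identical(d1[[i]]$measured$values, d2[[i]]$measured$values)
  }
})

test_that("noise-free dose-error samples have a constant channel ratio", {
  ds <- generate_dataset(sim_config(n_per_class = 2, noise_sigma = 0,
                                    seed = 31))
  labs <- dataset_labels(ds)
  for (s in ds[labs == 4L]) {
    pos <- s$measured$values > 0
    ratio <- s$calculated$values[pos] / s$measured$values[pos]
    expect_equal(diff(range(ratio)), 0, tolerance = 1e-9)
    expect_equal(abs(mean(ratio) - 1), 0.02, tolerance = 1e-9)
  }
  # geometric-error samples: difference is not a multiple of the map
  for (s in ds[labs %in% 1:3]) {
    hot <- s$measured$values > 0.1 * max(s$measured$values)
    ratio <- s$calculated$values[hot] / s$measured$values[hot]
    expect_gt(diff(range(ratio)), 1e-3)
  }
})
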