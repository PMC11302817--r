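crit33 <- gamma_criteria(0.03, 3, 0.10, 95)

test_that("gamma of identical maps is zero and GPR is 100", {
  g <- detector_geometry()
  m <- smooth_random_map(g, seed = 5)
  res <- gamma_analysis(m, m, crit33)
  expect_equal(max(res$gamma_map, na.rm = TRUE), 0)
  expect_equal(res$gpr, 100)
  expect_true(res$pass)
  expect_lte(res$n_analyzed, g$n_axial * g$n_circ)
})

test_that("uniform dose offsets give the analytic gamma", {
  g <- detector_geometry(5, 8)
  flat <- detector_map(matrix(2, 5, 8), g)
  # dose exactly at tolerance, flat neighbourhood: gamma = 1
  gp <- gamma_point(flat, 2 * 1.03, c(0, 0), crit33)
  expect_equal(gp, 1, tolerance = 1e-9)
  # same dose, same position: gamma = 0
  expect_equal(gamma_point(flat, 2, c(0, 0), crit33), 0)
  # 2% scaling passes 3%/3mm everywhere; 5% on a uniform map fails everywhere
  scaled <- function(f) detector_map(flat$values * f, g)
  expect_equal(gamma_analysis(flat, scaled(1.02), crit33)$gpr, 100)
  expect_equal(gamma_analysis(flat, scaled(1.05), crit33)$gpr, 0)
})

test_that("gamma_point matches the exhaustive fine-lattice oracle on a gradient", {
  g <- detector_geometry(5, 8, radius = 104, axial_pitch = 10)
  ramp <- detector_map(outer(seq(1, 1.4, length.out = 5),
                             seq(1, 1.14, length.out = 8)), g)
  pitch_s <- 2 * pi * g$radius / g$n_circ
  # evaluate one diode offset from where its dose belongs
  eval_dose <- ramp$values[3, 4]
  pos <- c(pitch_s * 4, 0)   # column 5, centre row
  got <- gamma_point(ramp, eval_dose, pos, crit33, step_mm = 0.1)
  eval_map <- ramp
  eval_map$values[3, 5] <- eval_dose
  oracle <- oracle_gamma(ramp, eval_map, 0.03, 3, step_mm = 0.1)
  expect_equal(got, oracle$gamma[3, 5], tolerance = 1e-3)
  # the default dta/10 lattice agrees with its own exhaustive oracle and
  # sits within the discretization envelope of the 0.1 mm answer
  coarse <- gamma_point(ramp, eval_dose, pos, crit33)
  expect_gte(coarse + 1e-12, got)
  expect_lt(coarse - got, 0.05)
})

test_that("gamma_analysis equals the brute-force oracle on random smooth fixtures", {
  g <- detector_geometry()
  for (seed in 1:4) {
    ref <- smooth_random_map(g, seed = seed)
    ev <- detector_map(ref$values * (1 + 0.02 * sin(seed + row(ref$values) / 3)),
                       g)
    res <- gamma_analysis(ref, ev, crit33)
    orc <- oracle_gamma(ref, ev, 0.03, 3, step_mm = 0.3)
    keep <- !is.na(res$gamma_map)
    expect_lt(max(abs(res$gamma_map[keep] - orc$gamma[keep])), 1e-3)
    expect_equal(res$gpr, orc$gpr, tolerance = 1e-9)
  }
})

test_that("the pass rate is stable under candidate-lattice refinement", {
  g <- detector_geometry()
  ref <- smooth_random_map(g, seed = 31)
  ev <- detector_map(ref$values * (1 + 0.02 * sin(row(ref$values) / 3)), g)
  gprs <- vapply(c(0.3, 0.15, 0.075), function(st)
    gamma_analysis(ref, ev, crit33, step_mm = st)$gpr, 0)
  expect_equal(diff(range(gprs)), 0, tolerance = 1e-9)
})

test_that("loosening criteria never decreases the pass rate", {
  g <- detector_geometry()
  ref <- smooth_random_map(g, seed = 9)
  ev <- detector_map(ref$values * 1.04, g)
  gprs <- vapply(list(gamma_criteria(0.02, 2), gamma_criteria(0.03, 2),
                      gamma_criteria(0.03, 3), gamma_criteria(0.05, 3)),
                 function(cr) gamma_analysis(ref, ev, cr)$gpr, 0)
  expect_true(all(diff(gprs) >= 0))
})

test_that("same-position candidate upper-bounds every gamma value", {
  g <- detector_geometry()
  ref <- smooth_random_map(g, seed = 13)
  ev <- smooth_random_map(g, seed = 14)
  res <- gamma_analysis(ref, ev, crit33)
  bound <- abs(ev$values - ref$values) / (0.03 * max(ref$values))
  keep <- !is.na(res$gamma_map)
  expect_true(all(res$gamma_map[keep] <= bound[keep] + 1e-9))
})

test_that("rotating both maps by whole columns leaves the GPR unchanged", {
  g <- detector_geometry()
  ref <- smooth_random_map(g, seed = 21)
  ev <- detector_map(ref$values * (1 + 0.025 * cos(col(ref$values) / 5)), g)
  base <- gamma_analysis(ref, ev, crit33)$gpr
  roll <- function(m, k) m[, c((ncol(m) - k + 1):ncol(m), 1:(ncol(m) - k))]
  for (k in c(1, 13, 40)) {
    res <- gamma_analysis(detector_map(roll(ref$values, k), g),
                          detector_map(roll(ev$values, k), g), crit33)
    expect_equal(res$gpr, base, tolerance = 1e-9)
  }
})

test_that("low-dose diodes are excluded from the analysis", {
  g <- detector_geometry(5, 8)
  vals <- matrix(1, 5, 8); vals[1, ] <- 0.01
  ref <- detector_map(vals, g)
  res <- gamma_analysis(ref, ref, crit33)
  expect_equal(res$n_analyzed, 32)
  expect_true(all(is.na(res$gamma_map[1, ])))
})

test_that("pass requires GPR strictly greater than the bound", {
  fake <- function(gpr, thr) {
    structure(list(gpr = gpr, criteria = gamma_criteria(0.03, 3, 0.1, thr)),
              class = "gamma_result")
  }
  expect_true(gpr_classify(fake(100, 95)))
  expect_false(gpr_classify(fake(95, 95)))
  expect_true(gpr_classify(fake(86, 85)))
})

test_that("degenerate inputs are rejected with the offending field", {
  g <- detector_geometry()
  zero <- detector_map(matrix(0, 21, 66), g)
  m <- smooth_random_map(g, seed = 2)
  expect_error(gamma_analysis(zero, m, crit33), "maximum dose")
  g2 <- detector_geometry(11, 66)
  m2 <- smooth_random_map(g2, seed = 2)
  expect_error(gamma_analysis(m, m2, crit33), "geometry")
  expect_error(gamma_criteria(-0.03, 3), "> 0")
  expect_error(gamma_criteria(0.03, 3, low_dose_threshold = 1.2), "< 1")
})
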