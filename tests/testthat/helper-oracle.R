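# Independent oracles and fixture builders shared across the suite.

# Exhaustive brute-force gamma: for every diode of `eval_map`, enumerate a
# square lattice of candidate reference positions (step `step_mm`, within
# `search_mm`) with its own bilinear interpolation, no search-order tricks.
# Deliberately written without reference to the package internals.
oracle_gamma <- function(ref_map, eval_map, dose_tol, dta,
                         search_mm = 3 * dta, step_mm = dta / 10,
                         low_thresh = 0.10) {
  vals <- ref_map$values
  g <- ref_map$geometry
  R <- nrow(vals); C <- ncol(vals)
  pitch_s <- 2 * pi * g$radius / C
  pitch_z <- g$axial_pitch
  ref_max <- max(vals)
  tol_abs <- dose_tol * ref_max
  bilin <- function(rr, cc) {        # vectorized, columns periodic
    cc <- cc %% C
    r0 <- pmin(floor(rr), R - 2); fr <- rr - r0
    c0 <- floor(cc); c1 <- (c0 + 1) %% C; fc <- cc - c0
    (1 - fr) * ((1 - fc) * vals[cbind(r0 + 1, c0 + 1)] +
                  fc * vals[cbind(r0 + 1, c1 + 1)]) +
      fr * ((1 - fc) * vals[cbind(r0 + 2, c0 + 1)] +
              fc * vals[cbind(r0 + 2, c1 + 1)])
  }
  n <- ceiling(search_mm / step_mm)
  offs <- expand.grid(ds = seq(-n, n) * step_mm, dz = seq(-n, n) * step_mm)
  offs <- offs[offs$ds^2 + offs$dz^2 <= search_mm^2 + 1e-9, ]
  dist2 <- offs$ds^2 + offs$dz^2
  gam <- matrix(NA_real_, R, C)
  for (i in seq_len(R)) {
    for (j in seq_len(C)) {
      de <- eval_map$values[i, j]
      rr <- (i - 1) + offs$dz / pitch_z
      ok <- rr >= 0 & rr <= R - 1
      dref <- bilin(rr[ok], (j - 1) + offs$ds[ok] / pitch_s)
      g2 <- dist2[ok] / dta^2 + (de - dref)^2 / tol_abs^2
      gam[i, j] <- sqrt(min(g2))
    }
  }
  analyzed <- vals >= low_thresh * ref_max
  list(gamma = gam,
       gpr = 100 * sum(gam[analyzed] <= 1) / sum(analyzed))
}

# Mann-Whitney AUC: fraction of (positive, negative) pairs where the
# positive scores higher, ties counting one half.
oracle_auc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  conc <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(conc)
}

# smooth random dose map: superposition of a few broad Gaussian bumps on
# the unwrapped surface (circumferentially periodic)
smooth_random_map <- function(geometry, n_bumps = 4, seed = 1) {
  set.seed(seed)
  R <- geometry$n_axial; C <- geometry$n_circ
  rr <- matrix(seq_len(R), R, C)
  cc <- matrix(seq_len(C), R, C, byrow = TRUE)
  vals <- matrix(0.05, R, C)
  for (b in seq_len(n_bumps)) {
    r0 <- runif(1, 1, R); c0 <- runif(1, 1, C)
    dc <- pmin(abs(cc - c0), C - abs(cc - c0))
    vals <- vals + runif(1, 0.4, 1) *
      exp(-(rr - r0)^2 / (2 * runif(1, 2, 5)^2) - dc^2 / (2 * runif(1, 3, 8)^2))
  }
  detector_map(vals, geometry)
}

# a fixed small beam set for rendering tests
fixture_beams <- function() {
  list(beam_config(0, 10, 1, list(aperture(0, 0, 40, 60))),
       beam_config(120, 0, 0.8, list(aperture(-10, 5, 30, 50))),
       beam_config(240, 45, 1.1, list(aperture(5, -10, 35, 45))))
}

# well-separated toy instances for overfit checks: class k gets a bright
# block at a class-specific location
toy_instances <- function(n_per_class = 4, H = 21, W = 66, seed = 1) {
  set.seed(seed)
  out <- list()
  for (cl in 0:4) {
    for (i in seq_len(n_per_class)) {
      ch <- array(0.1, dim = c(2, H, W))
      rs <- 3 + 3 * cl; cs <- 5 + 12 * cl
      ch[1, rs:(rs + 2), cs:(cs + 4)] <- 1
      ch[2, , ] <- ch[1, , ] + array(rnorm(H * W, 0, 0.01), c(H, W))
      ch <- pmin(pmax(ch, 0), 1)
      onehot <- rep(0, 5); onehot[cl + 1] <- 1
      out[[length(out) + 1]] <- structure(
        list(channels = ch, label = onehot, class = cl,
             plan_id = sprintf("toy%d_%d", cl, i),
             origin = sprintf("toy%d_%d", cl, i), technique = "IMRT"),
        class = "model_instance")
    }
  }
  out
}

# Minimal explicit-VR little-endian DICOM writer for synthetic RT-DOSE
# fixtures (only what read_rtdose needs).
write_fake_rtdose <- function(path, pixels, scaling = 0.01,
                              spacing = c(2.5, 2.5), modality = "RTDOSE",
                              bits = 16L) {
  stopifnot(is.matrix(pixels))
  u16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  el_str <- function(group, elem, vr, s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    u16(group); u16(elem); writeChar(vr, con, 2, eos = NULL)
    u16(nchar(s)); writeChar(s, con, nchar(s), eos = NULL)
  }
  el_us <- function(group, elem, val) {
    u16(group); u16(elem); writeChar("US", con, 2, eos = NULL)
    u16(2); u16(val)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, 4, eos = NULL)
  el_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  el_str(0x0008, 0x0060, "CS", modality)
  el_us(0x0028, 0x0010, nrow(pixels))
  el_us(0x0028, 0x0011, ncol(pixels))
  el_str(0x0028, 0x0008, "IS", "1")
  el_us(0x0028, 0x0100, bits)
  el_us(0x0028, 0x0103, 0L)
  el_str(0x0028, 0x0030, "DS", sprintf("%g\\%g", spacing[1], spacing[2]))
  el_str(0x0020, 0x0032, "DS", "0\\0\\0")
  el_str(0x3004, 0x000E, "DS", sprintf("%.10g", scaling))
  # PixelData, OW with 4-byte length
  u16(0x7FE0); u16(0x0010); writeChar("OW", con, 2, eos = NULL)
  u16(0)
  u32(length(pixels) * bits / 8)
  writeBin(as.integer(t(pixels)), con, bits / 8, endian = "little")
  invisible(path)
}
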