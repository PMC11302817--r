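// Gamma-index kernel on the unwrapped cylinder surface.
//
// The reference dose is treated as a continuous field: bilinear
// interpolation on a sub-lattice of step `step_mm` within a disk of
// `search_mm` around each evaluated diode.  Distance is geodesic on the
// cylinder: circumferential arc length (with wraparound) plus axial
// offset.  Axial positions beyond the first/last ring are not
// extrapolated and are skipped.  Offsets are visited in order of
// increasing distance so the search can stop as soon as the distance term
// alone exceeds the current best Gamma^2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Bilinear interpolation of ref at fractional (row, col) with circular
// columns; caller guarantees 0 <= rr <= n_rows-1.
static inline double interp_ref(const mat& ref, double rr, double cc) {
  const int R = ref.n_rows, C = ref.n_cols;
  int r0 = (int)std::floor(rr);
  if (r0 > R - 2) r0 = R - 2;
  double fr = rr - r0;
  // wrap without fmod (versioned symbol headaches across glibc builds)
  double cw = cc - C * std::floor(cc / C);
  if (cw >= C) cw -= C;
  int c0 = (int)std::floor(cw);
  int c1 = (c0 + 1) % C;
  double fc = cw - c0;
  return (1 - fr) * ((1 - fc) * ref(r0, c0) + fc * ref(r0, c1)) +
         fr * ((1 - fc) * ref(r0 + 1, c0) + fc * ref(r0 + 1, c1));
}

// [[Rcpp::export(name = ".gamma_kernel")]]
arma::mat gamma_kernel(const arma::mat& ref, const arma::mat& eval,
                       double pitch_s, double pitch_z,
                       double dose_tol, double dta,
                       double search_mm, double step_mm,
                       bool local_norm) {
  const int R = ref.n_rows, C = ref.n_cols;
  const double ref_max = ref.max();
  if (ref_max <= 0) Rcpp::stop("reference map maximum dose is zero");
  const double tol_abs_global = dose_tol * ref_max;

  // candidate offsets sorted by distance
  const int N = (int)std::ceil(search_mm / step_mm);
  std::vector<std::array<double, 3>> off;  // {dist2, ds, dz}
  off.reserve((2 * N + 1) * (2 * N + 1));
  for (int a = -N; a <= N; ++a)
    for (int b = -N; b <= N; ++b) {
      double ds = a * step_mm, dz = b * step_mm;
      double d2 = ds * ds + dz * dz;
      if (d2 <= search_mm * search_mm + 1e-9)
        off.push_back({d2, ds, dz});
    }
  std::sort(off.begin(), off.end(),
            [](const std::array<double, 3>& x, const std::array<double, 3>& y) {
              return x[0] < y[0];
            });

  const double dta2 = dta * dta;
  mat gam(R, C);
  for (int i = 0; i < R; ++i) {
    for (int j = 0; j < C; ++j) {
      const double de = eval(i, j);
      double best = datum::inf;
      for (const auto& o : off) {
        const double dterm = o[0] / dta2;
        if (dterm >= best) break;          // sorted: nothing closer remains
        const double rr = i + o[2] / pitch_z;
        if (rr < 0 || rr > R - 1) continue;
        const double cc = j + o[1] / pitch_s;
        const double dr = interp_ref(ref, rr, cc);
        const double tol = local_norm ? dose_tol * dr : tol_abs_global;
        if (tol <= 0) continue;
        const double dd = (de - dr) / tol;
        const double g2 = dterm + dd * dd;
        if (g2 < best) best = g2;
      }
      gam(i, j) = std::sqrt(best);
    }
  }
  return gam;
}
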