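#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Rayleigh–Sommerfeld sum of a discretized rigid-baffle source:
//   p(r) = (-i k / 2 pi) * sum_j exp(i k R_j) w_j / R_j
// with w_j the surface patch area of source point j and an exp(+ikR)
// outgoing-wave convention.  Pressure is in units of rho * c * u0 (unit
// normal velocity on the source surface).  This pairwise sum is the one
// O(N_src * N_field) kernel in the package, hence C++.
//
// sx, sy, sz : source point coordinates (m)
// sw         : source patch areas (m^2)
// fx, fy, fz : field point coordinates (m)
// k          : wavenumber (rad/m)
// [[Rcpp::export]]
ComplexVector rayleigh_sum(NumericVector sx, NumericVector sy, NumericVector sz,
                           NumericVector sw,
                           NumericVector fx, NumericVector fy, NumericVector fz,
                           double k) {
  const R_xlen_t ns = sx.size(), nf = fx.size();
  if (sy.size() != ns || sz.size() != ns || sw.size() != ns)
    stop("source coordinate/area vectors must have equal length");
  if (fy.size() != nf || fz.size() != nf)
    stop("field coordinate vectors must have equal length");

  ComplexVector out(nf);
  const double c0 = k / (2.0 * M_PI);
  for (R_xlen_t i = 0; i < nf; ++i) {
    double re = 0.0, im = 0.0;
    const double xi = fx[i], yi = fy[i], zi = fz[i];
    for (R_xlen_t j = 0; j < ns; ++j) {
      const double dx = xi - sx[j], dy = yi - sy[j], dz = zi - sz[j];
      const double R = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double a = sw[j] / R, ph = k * R;
      re += a * std::cos(ph);
      im += a * std::sin(ph);
    }
    // multiply by -i * c0: (-i)(re + i im) = im - i re
    out[i].r = c0 * im;
    out[i].i = -c0 * re;
  }
  return out;
}
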