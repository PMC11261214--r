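#include <Rcpp.h>
#include <cmath>

// Thermal performance shape on the mismatch u = T - z: an asymmetric
// double-Gaussian with flank scales tied to the critical-limit offsets
// (sigma = delta / 2.5 on each side), shifted and rescaled so the curve
// is exactly 1 at u = 0 and exactly 0 at u = -dmin and u = +dmax
// (continuous on the whole line, zero outside the thermal window):
//   g0(u) = (exp(-(u/sigma_side)^2) - c) / (1 - c),  c = exp(-2.5^2)
// The gentle cold flank and steep hot flank reproduce the
// characteristic warm-skewed performance of insect vital rates.

static const double kFlank = 2.5;

static inline double shape1(double u, double dmin, double dmax) {
  if (u <= -dmin || u >= dmax) return 0.0;
  double sig = (u < 0.0) ? (dmin / kFlank) : (dmax / kFlank);
  double c = std::exp(-kFlank * kFlank);
  double r = u / sig;
  double v = (std::exp(-r * r) - c) / (1.0 - c);
  return v > 0.0 ? v : 0.0;
}

// [[Rcpp::export]]
Rcpp::NumericVector tpc_shape_cpp(Rcpp::NumericVector u, double dmin,
                                  double dmax) {
  R_xlen_t n = u.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = shape1(u[i], dmin, dmax);
  }
  return out;
}

// Cubic (4-point Lagrange) interpolation of a uniformly tabulated
// function, returning 0 outside the table. Used for the precomputed
// environmentally-smoothed TPC shape, which is analytic (Gaussian
// smoothing removes the critical-limit cusps), so the interpolation
// error is O(du^4) of a gently varying function.
// [[Rcpp::export]]
Rcpp::NumericVector interp_table_cpp(Rcpp::NumericVector table,
                                     double u0, double du,
                                     Rcpp::NumericVector x) {
  R_xlen_t nt = table.size(), n = x.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double pos = (x[i] - u0) / du;
    if (pos < 1.0 || pos > (double)(nt - 3)) { out[i] = 0.0; continue; }
    R_xlen_t k = (R_xlen_t)pos;      // x in [u_k, u_{k+1}]
    double t = pos - (double)k;
    double ym1 = table[k - 1], y0 = table[k], y1 = table[k + 1],
           y2 = table[k + 2];
    double wm1 = -t * (t - 1.0) * (t - 2.0) / 6.0;
    double w0 = (t * t - 1.0) * (t - 2.0) / 2.0;
    double w1 = -t * (t + 1.0) * (t - 2.0) / 2.0;
    double w2 = t * (t * t - 1.0) / 6.0;
    double v = wm1 * ym1 + w0 * y0 + w1 * y1 + w2 * y2;
    out[i] = v > 0.0 ? v : 0.0;
  }
  return out;
}
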