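#include <Rcpp.h>
#include <cmath>

// Arc-length Young-Laplace system for an axisymmetric meniscus, in reduced
// units (lengths / R_pin, pressure * R_pin / gamma). State y = (r, z, psi, V):
//   dr/ds   = cos(psi)
//   dz/ds   = sin(psi)
//   dpsi/ds = p - sin(psi)/r      (p = reduced Laplace pressure = 2H)
//   dV/ds   = pi r^2 sin(psi)     (volume by horizontal slicing)
// psi is the tangent angle from the +r axis, increasing along the profile
// from the substrate (z = 0) toward the pinned rim.

static inline void deriv(double p, const double y[4], double dy[4]) {
  double c = std::cos(y[2]), s = std::sin(y[2]);
  dy[0] = c;
  dy[1] = s;
  dy[2] = p - s / y[0];
  dy[3] = M_PI * y[0] * y[0] * s;
}

// [[Rcpp::export]]
Rcpp::List yl_shoot_cpp(double p, double rb, double S, double theta,
                        int n, bool keep_profile = false) {
  double y[4] = {rb, 0.0, M_PI - theta, 0.0};
  double h = S / n;
  double rmin = rb;
  bool ok = true;
  Rcpp::NumericMatrix prof;
  if (keep_profile) {
    prof = Rcpp::NumericMatrix(n + 1, 3);
    prof(0, 0) = y[0]; prof(0, 1) = y[1]; prof(0, 2) = y[2];
  }
  double k1[4], k2[4], k3[4], k4[4], yt[4];
  for (int i = 0; i < n && ok; ++i) {
    deriv(p, y, k1);
    for (int j = 0; j < 4; ++j) yt[j] = y[j] + 0.5 * h * k1[j];
    if (yt[0] <= 1e-10) { ok = false; break; }
    deriv(p, yt, k2);
    for (int j = 0; j < 4; ++j) yt[j] = y[j] + 0.5 * h * k2[j];
    if (yt[0] <= 1e-10) { ok = false; break; }
    deriv(p, yt, k3);
    for (int j = 0; j < 4; ++j) yt[j] = y[j] + h * k3[j];
    if (yt[0] <= 1e-10) { ok = false; break; }
    deriv(p, yt, k4);
    for (int j = 0; j < 4; ++j)
      y[j] += h * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]) / 6.0;
    if (y[0] <= 1e-10 || !std::isfinite(y[0]) || !std::isfinite(y[2])) {
      ok = false; break;
    }
    if (y[0] < rmin) rmin = y[0];
    if (keep_profile) {
      prof(i + 1, 0) = y[0]; prof(i + 1, 1) = y[1]; prof(i + 1, 2) = y[2];
    }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("r") = y[0], Rcpp::Named("z") = y[1],
    Rcpp::Named("psi") = y[2], Rcpp::Named("V") = y[3],
    Rcpp::Named("rmin") = rmin, Rcpp::Named("ok") = ok);
  if (keep_profile) out["profile"] = prof;
  return out;
}

// Lateral surface area of the discretized profile (sum of frustum areas),
// used for the interfacial-energy bookkeeping of a converged state.
// [[Rcpp::export]]
double frustum_area_cpp(Rcpp::NumericVector r, Rcpp::NumericVector z) {
  int n = r.size();
  double A = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    double dr = r[i + 1] - r[i], dz = z[i + 1] - z[i];
    A += M_PI * (r[i] + r[i + 1]) * std::sqrt(dr * dr + dz * dz);
  }
  return A;
}
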