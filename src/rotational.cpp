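#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Propagate an isotropic rotational Brownian walk of a unit vector.
// Each step rotates the current vector about a random axis perpendicular to
// it by the supplied Gaussian angle (variance 2 D_r dt supplied by caller).
// Randomness (axes, angles) is drawn in R so that R's RNG/seed semantics
// apply; the vector is renormalised every step so |u| stays at 1 to
// machine precision.
// [[Rcpp::export]]
NumericMatrix cpp_rotational_walk(NumericVector u0, NumericVector angles,
                                  NumericMatrix axes) {
  const int n = angles.size();
  if (axes.nrow() != n || axes.ncol() != 3)
    stop("axes must be an n x 3 matrix matching length(angles)");
  NumericMatrix out(n + 1, 3);
  double ux = u0[0], uy = u0[1], uz = u0[2];
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  if (nrm <= 0.0) stop("initial vector has zero norm");
  ux /= nrm; uy /= nrm; uz /= nrm;
  out(0, 0) = ux; out(0, 1) = uy; out(0, 2) = uz;
  for (int i = 0; i < n; ++i) {
    double ax = axes(i, 0), ay = axes(i, 1), az = axes(i, 2);
    // project the random axis into the plane perpendicular to u
    double dot = ax * ux + ay * uy + az * uz;
    ax -= dot * ux; ay -= dot * uy; az -= dot * uz;
    double an = std::sqrt(ax * ax + ay * ay + az * az);
    if (an < 1e-12) {
      // degenerate draw (axis parallel to u): pick any perpendicular
      if (std::fabs(ux) < 0.9) { ax = 0.0; ay = -uz; az = uy; }
      else                     { ax = -uz; ay = 0.0; az = ux; }
      an = std::sqrt(ax * ax + ay * ay + az * az);
    }
    ax /= an; ay /= an; az /= an;
    const double c = std::cos(angles[i]), s = std::sin(angles[i]);
    // Rodrigues rotation with k perpendicular to u: u' = u cos(phi) + (k x u) sin(phi)
    const double cx = ay * uz - az * uy;
    const double cy = az * ux - ax * uz;
    const double cz = ax * uy - ay * ux;
    double nx = ux * c + cx * s;
    double ny = uy * c + cy * s;
    double nz = uz * c + cz * s;
    const double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    ux = nx / nn; uy = ny / nn; uz = nz / nn;
    out(i + 1, 0) = ux; out(i + 1, 1) = uy; out(i + 1, 2) = uz;
  }
  return out;
}

// Time-origin-averaged autocorrelation of the second Legendre polynomial of
// the angle between u(t) and u(t + lag): C(lag) = < P2(u(t) . u(t+lag)) >.
// [[Rcpp::export]]
NumericVector cpp_p2_acf(NumericMatrix u, int max_lag) {
  const int n = u.nrow();
  if (u.ncol() != 3) stop("u must be an n x 3 matrix");
  if (n < 2) stop("need at least 2 orientations");
  if (max_lag >= n) max_lag = n - 1;
  NumericVector C(max_lag + 1);
  for (int k = 0; k <= max_lag; ++k) {
    double acc = 0.0;
    const int m = n - k;
    for (int t = 0; t < m; ++t) {
      const double d = u(t, 0) * u(t + k, 0) + u(t, 1) * u(t + k, 1) +
                       u(t, 2) * u(t + k, 2);
      acc += 1.5 * d * d - 0.5;
    }
    C[k] = acc / m;
  }
  return C;
}
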