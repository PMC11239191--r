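#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration of dx = -D U'(x) dt + sqrt(2 D dt) xi on a
// uniform grid. The drift -D U'(x) is supplied at the grid points (central
// differences, precomputed in R) and linearly interpolated.
//
// Absorption at a boundary is detected either by landing at/beyond it or by a
// Brownian-bridge crossing test within the step (crossing probability
// exp(-(b - x)(b - x') / (D dt)) for boundary b), which removes the leading
// O(sqrt(dt)) first-passage bias of end-of-step detection. The x = L boundary
// is absorbing or specularly reflecting depending on reflect_L; the reflecting
// wall keeps plain end-of-step reflection.
//
// Returns side (0 = retraction, 1 = translocation, NA = hit max_steps) and
// escape time per trajectory. Uses R's RNG, so results are seed-reproducible.

// [[Rcpp::export]]
List langevin_paths(double x0, double L, double h, NumericVector drift,
                    double D, double dt, int n_traj, double max_steps,
                    bool reflect_L) {
  const int n = drift.size();
  const double sd = std::sqrt(2.0 * D * dt);
  const double inv_Ddt = 1.0 / (D * dt);
  IntegerVector side(n_traj);
  NumericVector time(n_traj);
  for (int k = 0; k < n_traj; ++k) {
    double x = x0;
    double steps = 0.0;
    int out = NA_INTEGER;
    while (steps < max_steps) {
      // linear interpolation of the drift
      double u = x / h;
      int i = (int)u;
      if (i < 0) i = 0;
      if (i > n - 2) i = n - 2;
      double w = u - i;
      double f = drift[i] * (1.0 - w) + drift[i + 1] * w;
      double xprev = x;
      x += f * dt + sd * norm_rand();
      steps += 1.0;
      if (x <= 0.0) { out = 0; break; }
      if (x >= L) {
        if (reflect_L) {
          x = 2.0 * L - x;
          if (x <= 0.0) { out = 0; break; }
        } else {
          out = 1; break;
        }
      }
      // Brownian-bridge crossing tests for unobserved excursions
      double p0 = std::exp(-xprev * x * inv_Ddt);
      if (unif_rand() < p0) { out = 0; break; }
      if (!reflect_L) {
        double pL = std::exp(-(L - xprev) * (L - x) * inv_Ddt);
        if (unif_rand() < pL) { out = 1; break; }
      }
    }
    side[k] = out;
    time[k] = steps * dt;
  }
  return List::create(_["side"] = side, _["time"] = time);
}
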