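#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-thinning rupture simulation of a Bell bond loaded through a WLC
// tether retracted at constant velocity. At each step the extension is
// x = v * t, the tether force follows the WLC interpolation formula, the
// per-step rupture probability is P_u = k_u(f) * dt (or 1 - exp(-k_u dt)
// when exp_prob is set), and rupture occurs when P_u exceeds a uniform
// draw. Uses R's RNG stream so results are reproducible under set.seed().
//
// f_beta = kBT / x_t in pN; pass R_PosInf for a force-independent rate.
// Returns rupture force (pN) and time (s) per event; errors if the
// extension reaches x_max_frac * L without rupture.

// [[Rcpp::export]]
List mc_rupture_cpp(double velocity, double l_app, double L, double kBT,
                    double k_off, double f_beta, double dt, int n_events,
                    bool exp_prob, double x_max_frac) {
  NumericVector f_r(n_events), t_r(n_events);
  const double scale = kBT / l_app;
  const double x_max = x_max_frac * L;
  const bool finite_beta = R_FINITE(f_beta);
  for (int e = 0; e < n_events; ++e) {
    double t = 0.0, f = 0.0;
    for (;;) {
      t += dt;
      double x = velocity * t;
      if (x >= x_max) {
        stop("extension reached %g of the contour length (L = %g nm) without rupture; bond parameters are inconsistent with the tether length", x_max_frac, L);
      }
      double s = x / L;
      double om = 1.0 - s;
      f = scale * (s + 0.25 / (om * om) - 0.25);
      double k = finite_beta ? k_off * std::exp(f / f_beta) : k_off;
      double P = exp_prob ? -std::expm1(-k * dt) : k * dt;
      if (P > R::unif_rand()) break;
    }
    f_r[e] = f;
    t_r[e] = t;
  }
  return List::create(_["f_r"] = f_r, _["t_r"] = t_r);
}
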