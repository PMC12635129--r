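#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coupled infant-mobile system:
//   x'' + x'(gamma + alpha x^2) + x(omega0^2 + delta x^2) = 0   (limb)
//   y'' + eps y' + Omega0^2 y = c x                             (mobile)
//   delta' = a y^2 - kappa delta                                (feedback)
// State vector s = (x, x', y, y', delta).
static inline void deriv(const double s[5], const double c,
                         const double gamma, const double alpha,
                         const double omega0sq, const double eps,
                         const double Omega0sq, const double a,
                         const double kappa, double out[5]) {
  const double x = s[0], xd = s[1], y = s[2], yd = s[3], d = s[4];
  out[0] = xd;
  out[1] = -xd * (gamma + alpha * x * x) - x * (omega0sq + d * x * x);
  out[2] = yd;
  out[3] = c * x - eps * yd - Omega0sq * y;
  out[4] = a * y * y - kappa * d;
}

// Classical fixed-step RK4 over a piecewise-constant coupling schedule.
// Returns states at every reporting step (t = 0, dt, 2*dt, ...), state
// carried over across schedule segments.
// [[Rcpp::export(name = ".rk4_mobile")]]
NumericMatrix rk4_mobile(NumericVector state0, NumericVector durations,
                         NumericVector cvals, double gamma, double alpha,
                         double omega0, double eps, double Omega0, double a,
                         double kappa, double dt) {
  if (state0.size() != 5) stop("state0 must have length 5");
  if (durations.size() != cvals.size()) stop("schedule lengths differ");
  if (dt <= 0) stop("dt must be positive");

  const double omega0sq = omega0 * omega0;
  const double Omega0sq = Omega0 * Omega0;

  long total_steps = 0;
  std::vector<long> seg_steps(durations.size());
  for (int i = 0; i < durations.size(); ++i) {
    if (durations[i] <= 0) stop("segment durations must be positive");
    long ns = (long)std::lround(durations[i] / dt);
    if (std::fabs(ns * dt - durations[i]) > 1e-8 * std::max(1.0, durations[i]))
      stop("dt must divide each segment duration");
    seg_steps[i] = ns;
    total_steps += ns;
  }

  NumericMatrix out(total_steps + 1, 6);
  double s[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int j = 0; j < 5; ++j) s[j] = state0[j];

  double t = 0.0;
  long row = 0;
  out(0, 0) = 0.0;
  for (int j = 0; j < 5; ++j) out(0, j + 1) = s[j];

  for (int seg = 0; seg < durations.size(); ++seg) {
    const double c = cvals[seg];
    for (long step = 0; step < seg_steps[seg]; ++step) {
      deriv(s, c, gamma, alpha, omega0sq, eps, Omega0sq, a, kappa, k1);
      for (int j = 0; j < 5; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
      deriv(tmp, c, gamma, alpha, omega0sq, eps, Omega0sq, a, kappa, k2);
      for (int j = 0; j < 5; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
      deriv(tmp, c, gamma, alpha, omega0sq, eps, Omega0sq, a, kappa, k3);
      for (int j = 0; j < 5; ++j) tmp[j] = s[j] + dt * k3[j];
      deriv(tmp, c, gamma, alpha, omega0sq, eps, Omega0sq, a, kappa, k4);
      for (int j = 0; j < 5; ++j)
        s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      t += dt;
      ++row;
      for (int j = 0; j < 5; ++j) {
        if (!std::isfinite(s[j]))
          stop("integration blew up (non-finite state) at t = %f", t);
        out(row, j + 1) = s[j];
      }
      out(row, 0) = t;
    }
  }
  colnames(out) = CharacterVector::create("t", "x", "xdot", "y", "ydot",
                                          "delta");
  return out;
}
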