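#include <Rcpp.h>
using namespace Rcpp;

// First-passage time of overdamped (Brownian) dynamics in a piecewise
// parabolic metastable well:
//   V(x) = 0.5*wa2*x^2                 for x <= xjoin
//   V(x) = dV - 0.5*wb2*(x - b)^2      for x >  xjoin
// (C1-continuous by construction of xjoin/b in the R constructor).
// Euler-Maruyama: dx = -V'(x)/gamma dt + sqrt(2*T*dt/gamma) * N(0,1).
// The particle starts in the well (x = 0) and is absorbed at x >= absorb;
// returns the crossing time, or NA if still bound at t_max. Uses R's RNG,
// so reproducibility is controlled by set.seed() at the call site.
// [[Rcpp::export]]
double langevin_escape_time(double wa2, double wb2, double dV, double b,
                            double xjoin, double absorb, double temperature,
                            double friction, double dt, double t_max) {
  const double inv_gamma = 1.0 / friction;
  const double noise = std::sqrt(2.0 * temperature * dt * inv_gamma);
  const long n_steps = (long)std::ceil(t_max / dt);
  double x = 0.0;
  for (long i = 0; i < n_steps; ++i) {
    double force = (x <= xjoin) ? (-wa2 * x) : (wb2 * (x - b));
    x += force * inv_gamma * dt + noise * norm_rand();
    if (x >= absorb) return (i + 1) * dt;
  }
  return NA_REAL;
}

// Trajectory of the same dynamics, subsampled every `stride` steps
// (position after steps stride, 2*stride, ...). Used for the in-memory
// diagnostic path; escape detection is done by the caller.
// [[Rcpp::export]]
NumericVector langevin_positions(double wa2, double wb2, double dV, double b,
                                 double xjoin, double temperature,
                                 double friction, double dt, int n_out,
                                 int stride) {
  const double inv_gamma = 1.0 / friction;
  const double noise = std::sqrt(2.0 * temperature * dt * inv_gamma);
  NumericVector out(n_out);
  double x = 0.0;
  for (int i = 0; i < n_out; ++i) {
    for (int s = 0; s < stride; ++s) {
      double force = (x <= xjoin) ? (-wa2 * x) : (wb2 * (x - b));
      x += force * inv_gamma * dt + noise * norm_rand();
    }
    out[i] = x;
  }
  return out;
}
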