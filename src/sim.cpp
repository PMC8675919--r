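#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama simulation of dx/dt = A + xi to first passage through
// |x| = theta, starting from x = m*theta.  Uses R's RNG so results are
// reproducible under set.seed().
//
// With `bridge = true` each non-crossing step additionally performs the
// exact Brownian-bridge crossing test: given endpoints x0, x1 strictly
// inside the interval, the within-step maximum exceeds theta with
// probability exp(-2 (theta - x0)(theta - x1) / (c2 * dt)) (and
// symmetrically for -theta).  This removes the O(sqrt(dt)) first-passage
// bias of the plain Euler scheme; the remaining bias is O(dt).

// [[Rcpp::export]]
List cpp_sim_fp(int n, double drift, double diffusion_var, double threshold,
                double start_bias, double step, bool bridge,
                double max_steps) {
  NumericVector decision_time(n);
  IntegerVector upper(n);
  const double sd = std::sqrt(diffusion_var * step);
  const double mu = drift * step;
  const double x0 = start_bias * threshold;
  const double denom = 2.0 / (diffusion_var * step);

  for (int i = 0; i < n; ++i) {
    double x = x0;
    double nsteps = 0.0;
    int hit = NA_INTEGER;
    while (nsteps < max_steps) {
      const double xprev = x;
      x += mu + sd * norm_rand();
      nsteps += 1.0;
      if (x >= threshold) { hit = 1; break; }
      if (x <= -threshold) { hit = 0; break; }
      if (bridge) {
        // crossing probabilities for the upper and lower boundary;
        // skip the uniform draw when the exponent is negligible
        const double eu = -(threshold - xprev) * (threshold - x) * denom;
        if (eu > -30.0 && unif_rand() < std::exp(eu)) { hit = 1; break; }
        const double el = -(threshold + xprev) * (threshold + x) * denom;
        if (el > -30.0 && unif_rand() < std::exp(el)) { hit = 0; break; }
      }
    }
    if (hit == NA_INTEGER) {
      upper[i] = NA_INTEGER;
      decision_time[i] = NA_REAL;
    } else {
      upper[i] = hit;
      decision_time[i] = nsteps * step;
    }
  }
  return List::create(_["upper"] = upper, _["decision_time"] = decision_time);
}
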