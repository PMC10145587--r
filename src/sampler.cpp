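#include <Rcpp.h>
using namespace Rcpp;

// Analytic 1-D potentials mirrored from R/potentials.R.
// form: 0 flat, 1 harmonic, 2 double_well, 3 piecewise_pmf
static inline double pot_energy(int form, double k, double x0, double h,
                                double a, const NumericVector &kx,
                                const NumericVector &kw, double x) {
  switch (form) {
  case 0:
    return 0.0;
  case 1:
    return 0.5 * k * (x - x0) * (x - x0);
  case 2: {
    double d = (x - x0) * (x - x0) - a * a;
    return h * d * d / (a * a * a * a);
  }
  case 3: {
    int n = kx.size();
    if (x < kx[0] || x > kx[n - 1]) return R_PosInf;
    // binary search for the knot interval
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (kx[mid] <= x) lo = mid; else hi = mid;
    }
    double t = (x - kx[lo]) / (kx[hi] - kx[lo]);
    return kw[lo] + t * (kw[hi] - kw[lo]);
  }
  }
  return R_PosInf;
}

// Metropolis random-walk chain with uniform proposals of half-width `step`.
// Uses R's RNG so runs are reproducible under set.seed(). Returns the
// retained samples (every `stride`-th state after `burn_in`) and the
// acceptance count over all attempted moves.
// [[Rcpp::export]]
List metropolis_chain_cpp(int form, double k, double x0, double h, double a,
                          NumericVector knots_x, NumericVector knots_w,
                          double lower, double upper,
                          bool has_bias, double bias_center, double bias_k,
                          double kt, double x_init, double step,
                          int n_samples, int burn_in, int stride) {
  RNGScope scope;
  NumericVector out(n_samples);
  double x = x_init;
  double u = pot_energy(form, k, x0, h, a, knots_x, knots_w, x);
  if (has_bias) u += 0.5 * bias_k * (x - bias_center) * (x - bias_center);
  if (!R_finite(u))
    stop("initial coordinate has infinite energy");
  long n_steps = (long)burn_in + (long)n_samples * stride;
  long n_accept = 0;
  int kept = 0;
  long next_keep = burn_in + stride; // record after completing each stride block
  for (long i = 1; i <= n_steps; ++i) {
    double xp = x + (unif_rand() * 2.0 - 1.0) * step;
    double up;
    if (xp < lower || xp > upper) {
      up = R_PosInf;
    } else {
      up = pot_energy(form, k, x0, h, a, knots_x, knots_w, xp);
      if (has_bias)
        up += 0.5 * bias_k * (xp - bias_center) * (xp - bias_center);
    }
    if (R_finite(up) && (up <= u || unif_rand() < exp(-(up - u) / kt))) {
      x = xp;
      u = up;
      ++n_accept;
    }
    if (i == next_keep && kept < n_samples) {
      out[kept++] = x;
      next_keep += stride;
    }
  }
  return List::create(_["samples"] = out, _["n_accept"] = (double)n_accept,
                      _["n_steps"] = (double)n_steps);
}
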