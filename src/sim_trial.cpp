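#include <Rcpp.h>
using namespace Rcpp;

// Simulate one trial of gaze positions over the 4 zones.
//
// td, bu: n_steps x 4 matrices of top-down and bottom-up distributions
// (rows = steps). The memory belief starts uniform, assimilates the initial
// position (Eyes), and each step is diluted (uniform leak epsilon), fused
// with the current step's top-down and bottom-up rows through the
// selection-history inversion (1 - b) / 3, the next position is drawn from
// the fused distribution using R's RNG, and the memory observes it.
// Returns 1-based zone indices of length n_steps; element 1 is the initial
// position.
// [[Rcpp::export(name = ".sim_trial_cpp")]]
IntegerVector sim_trial_cpp(NumericMatrix td, NumericMatrix bu,
                            double epsilon, double p_hit, int start_zone) {
  const int z = 4;
  const int n = td.nrow();
  if (bu.nrow() != n || td.ncol() != z || bu.ncol() != z)
    stop("td and bu must be n-by-4 matrices of equal length");
  if (start_zone < 1 || start_zone > z) stop("invalid start zone");

  IntegerVector out(n);
  double m[4] = {0.25, 0.25, 0.25, 0.25};
  const double miss = (1.0 - p_hit) / (z - 1);

  int x = start_zone - 1;
  out[0] = x + 1;
  // assimilate the initial position (dilution of uniform is uniform)
  {
    double s = 0.0;
    for (int i = 0; i < z; ++i) { m[i] *= (i == x ? p_hit : miss); s += m[i]; }
    for (int i = 0; i < z; ++i) m[i] /= s;
  }

  RNGScope scope;
  for (int t = 0; t < n - 1; ++t) {
    double f[4];
    double s = 0.0;
    for (int i = 0; i < z; ++i) {
      double inv = (1.0 - m[i]) / (z - 1);
      f[i] = td(t, i) * bu(t, i) * inv;
      s += f[i];
    }
    if (s <= 0.0)
      stop("degenerate fusion: component distributions have disjoint supports");
    double u = unif_rand() * s;
    double acc = 0.0;
    int nx = z - 1;
    for (int i = 0; i < z; ++i) {
      acc += f[i];
      if (u <= acc) { nx = i; break; }
    }
    x = nx;
    out[t + 1] = x + 1;
    // memory update: dilute then observe the just-drawn position
    double sm = 0.0;
    for (int i = 0; i < z; ++i) {
      double d = (1.0 - z * epsilon) * m[i] + epsilon;
      d *= (i == x ? p_hit : miss);
      m[i] = d;
      sm += d;
    }
    for (int i = 0; i < z; ++i) m[i] /= sm;
  }
  return out;
}
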