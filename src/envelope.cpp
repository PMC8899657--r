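#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric one-pole envelope follower, column-wise over a matrix.
// y[0] = x[0]; y[i] = y[i-1] + a*(x[i]-y[i-1]) with a = alpha_att when the
// input is rising, alpha_rel when falling. Each column is an independent
// signal (state resets per column), so token batches can be smoothed in one
// call. Works on any monotone level representation (power, amplitude, dB).
// [[Rcpp::export(name = ".env_follow")]]
NumericMatrix env_follow(NumericMatrix x, double alpha_att, double alpha_rel) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix y(n, m);
  for (int j = 0; j < m; ++j) {
    double state = n > 0 ? x(0, j) : 0.0;
    if (n > 0) y(0, j) = state;
    for (int i = 1; i < n; ++i) {
      const double xi = x(i, j);
      const double a = xi > state ? alpha_att : alpha_rel;
      state += a * (xi - state);
      y(i, j) = state;
    }
  }
  return y;
}
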