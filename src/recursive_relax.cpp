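#include <Rcpp.h>
using namespace Rcpp;

// First-order relaxation recurrence with per-sample coefficients:
//   y[0] = init
//   y[k] = target[k] + (y[k-1] - target[k]) * decay[k],   k = 1..n-1
// where decay[k] = exp(-dt / tau[k]). Exact for coefficients constant over a
// step, unconditionally stable for decay in [0, 1].
// [[Rcpp::export]]
NumericVector recursive_relax(NumericVector target, NumericVector decay,
                              double init) {
  R_xlen_t n = target.size();
  if (decay.size() != n)
    stop("'target' and 'decay' must have the same length");
  NumericVector y(n);
  if (n == 0) return y;
  y[0] = init;
  for (R_xlen_t k = 1; k < n; ++k) {
    y[k] = target[k] + (y[k - 1] - target[k]) * decay[k];
  }
  return y;
}
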