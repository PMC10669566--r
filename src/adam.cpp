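// In-place Adam update. The trainer owns deep copies of the parameter and
// moment arrays, so mutating them here is safe and avoids reallocating
// millions of doubles per step.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
void cpp_adam_step(NumericVector p, NumericVector m, NumericVector v,
                   NumericVector g, double lr, double b1, double b2,
                   double eps, double corr) {
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * corr * m[i] / (std::sqrt(v[i]) + eps);
  }
}
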