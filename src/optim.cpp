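#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fused in-place Adam update for one parameter tensor.  w, m and v are
// owned exclusively by the training loop (deep-copied at entry), so
// updating them in place is safe and avoids the per-step allocation churn
// of a vectorized R implementation.
// [[Rcpp::export(name = ".adam_update_inplace")]]
void adam_update_inplace(NumericVector w, NumericVector m, NumericVector v,
                         NumericVector g, double lr, double beta1,
                         double beta2, double eps, double bc1, double bc2) {
  const R_xlen_t n = w.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam state size mismatch");
  double *pw = w.begin(), *pm = m.begin(), *pv = v.begin(), *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = pg[i];
    pm[i] = beta1 * pm[i] + (1 - beta1) * gi;
    pv[i] = beta2 * pv[i] + (1 - beta2) * gi * gi;
    pw[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
  }
}
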