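#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update over a two-level parameter list (layers of W/b
// arrays). The caller owns every leaf (freshly allocated at training start),
// so updating in place is safe and avoids reallocating millions of doubles
// per optimization step.
// [[Rcpp::export]]
void adam_update_inplace(List params, List grads, List m, List v,
                         double lr, double beta1, double beta2,
                         double eps, int t) {
  const double c1 = 1.0 / (1.0 - std::pow(beta1, (double) t));
  const double c2 = 1.0 / (1.0 - std::pow(beta2, (double) t));
  for (R_xlen_t l = 0; l < params.size(); ++l) {
    List pl = params[l], gl = grads[l], ml = m[l], vl = v[l];
    for (R_xlen_t k = 0; k < pl.size(); ++k) {
      NumericVector p = pl[k], g = gl[k], mm = ml[k], vv = vl[k];
      const R_xlen_t n = p.size();
      for (R_xlen_t i = 0; i < n; ++i) {
        const double gi = g[i];
        const double mi = beta1 * mm[i] + (1.0 - beta1) * gi;
        const double vi = beta2 * vv[i] + (1.0 - beta2) * gi * gi;
        mm[i] = mi;
        vv[i] = vi;
        p[i] -= lr * (mi * c1) / (std::sqrt(vi * c2) + eps);
      }
    }
  }
}
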