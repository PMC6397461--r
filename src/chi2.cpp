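#include <Rcpp.h>
using namespace Rcpp;

// 0.5 * sum_k (hi_k - hj_k)^2 / (hi_k + hj_k) between all row pairs of two
// histogram matrices; zero-denominator terms contribute 0.
// [[Rcpp::export]]
NumericMatrix chi2_cost_matrix_cpp(NumericMatrix H1, NumericMatrix H2) {
  const int n = H1.nrow(), m = H2.nrow(), K = H1.ncol();
  NumericMatrix C(n, m);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        const double a = H1(i, k), b = H2(j, k);
        const double den = a + b;
        if (den > 0) { const double d = a - b; acc += d * d / den; }
      }
      C(i, j) = 0.5 * acc;
    }
  }
  return C;
}
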