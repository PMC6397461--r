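#include <Rcpp.h>
using namespace Rcpp;

// Truncated L1 data cost of matching pixel p = (y, x) in image 1 to
// p + (u, v) in image 2. Descriptor matrices are (h*w) x D with pixels in
// column-major order (index = y + (x-1)*h). Out-of-bounds targets cost t.
// [[Rcpp::export]]
NumericVector flow_data_cost_cpp(NumericMatrix d1, NumericMatrix d2,
                                 NumericVector u, NumericVector v,
                                 int h, int w, double t) {
  const int n = h * w;
  const int D = d1.ncol();
  NumericVector out(n);
  for (int x = 1; x <= w; ++x) {
    for (int y = 1; y <= h; ++y) {
      const int p = (y - 1) + (x - 1) * h;
      const double tx = x + u[p], ty = y + v[p];
      if (tx < 1 || tx > w || ty < 1 || ty > h) { out[p] = t; continue; }
      const int q = ((int)ty - 1) + ((int)tx - 1) * h;
      double acc = 0.0;
      for (int k = 0; k < D; ++k) {
        const double dif = d1(p, k) - d2(q, k);
        acc += dif >= 0 ? dif : -dif;
        if (acc >= t) { acc = t; break; }
      }
      out[p] = acc;
    }
  }
  return out;
}
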