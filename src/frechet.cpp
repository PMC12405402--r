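#include <Rcpp.h>
using namespace Rcpp;

// Discrete Frechet distance between two point sequences in the (t, v)
// plane, by the standard O(n*m) dynamic program on the coupling lattice
// (Eiter & Mannila recursion), kept in two rolling rows.
// [[Rcpp::export(name = ".frechet_dp")]]
double frechet_dp(NumericVector xt, NumericVector xv,
                  NumericVector yt, NumericVector yv) {
  const int n = xt.size(), m = yt.size();
  if (n == 0 || m == 0) stop("empty curve");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double dt = xt[i] - yt[j], dv = xv[i] - yv[j];
      const double d = std::sqrt(dt * dt + dv * dv);
      double reach;
      if (i == 0 && j == 0)      reach = d;
      else if (i == 0)           reach = std::max(cur[j - 1], d);
      else if (j == 0)           reach = std::max(prev[0], d);
      else reach = std::max(std::min(std::min(prev[j], prev[j - 1]),
                                     cur[j - 1]), d);
      cur[j] = reach;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
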