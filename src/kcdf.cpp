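#include <Rcpp.h>
using namespace Rcpp;

// Gaussian-kernel cumulative density estimate per gene (row) across samples:
// z[i, j] = (1/n) * sum_k Phi((x[i, j] - x[i, k]) / h[i]).
// [[Rcpp::export(name = ".kcdfGauss")]]
NumericMatrix kcdfGauss(NumericMatrix x, NumericVector h) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix z(p, n);
  for (int i = 0; i < p; ++i) {
    const double hi = h[i];
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      const double xij = x(i, j);
      for (int k = 0; k < n; ++k)
        acc += R::pnorm((xij - x(i, k)) / hi, 0.0, 1.0, 1, 0);
      z(i, j) = acc / n;
    }
  }
  return z;
}
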