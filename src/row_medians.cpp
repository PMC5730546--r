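#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-row median of a numeric matrix. Used for per-pixel temporal medians
// over frame stacks, where one R-level median() call per pixel is too slow.
// [[Rcpp::export]]
NumericVector row_medians(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector out(n);
  std::vector<double> buf(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) buf[j] = x(i, j);
    const int h = m / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (m % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = 0.5 * (med + lo);
    }
    out[i] = med;
  }
  return out;
}
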