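// Adaptive (locally Gaussian-weighted) binarization.  The smoothed image
// is computed with a separable Gaussian window; borders use symmetric
// reflection (the edge pixel is repeated).  A pixel binarizes to 1 iff
// its intensity strictly exceeds the smoothed value plus the offset.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else i = 2 * n - i - 1;
  }
  return i;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_adaptive_binarize(NumericMatrix x, int window,
                                    double sigma, double offset) {
  const int nr = x.nrow(), nc = x.ncol();
  const int half = window / 2;
  std::vector<double> g(window);
  double gsum = 0.0;
  for (int k = 0; k < window; ++k) {
    const double d = k - half;
    g[k] = std::exp(-(d * d) / (2.0 * sigma * sigma));
    gsum += g[k];
  }
  for (int k = 0; k < window; ++k) g[k] /= gsum;

  NumericMatrix tmp(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < window; ++k)
        s += g[k] * x(reflect(i + k - half, nr), j);
      tmp(i, j) = s;
    }
  }
  IntegerMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double s = 0.0;
      for (int k = 0; k < window; ++k)
        s += g[k] * tmp(i, reflect(j + k - half, nc));
      out(i, j) = (x(i, j) > s + offset) ? 1 : 0;
    }
  }
  return out;
}
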