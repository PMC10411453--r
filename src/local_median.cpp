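#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflective (symmetric, edge-inclusive) index: -1 -> 0, n -> n-1.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Exact sliding-window median of a numeric matrix. `window` must be odd;
// borders are handled by reflective padding so every output pixel sees a
// full window x window neighbourhood.
// [[Rcpp::export]]
NumericMatrix local_median_cpp(NumericMatrix img, int window) {
  const int nr = img.nrow(), nc = img.ncol(), r = window / 2;
  const int wsz = window * window, k = wsz / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(wsz);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int m = 0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect_idx(j + dj, nc);
        const double *col = &img(0, jj);
        for (int di = -r; di <= r; ++di)
          buf[m++] = col[reflect_idx(i + di, nr)];
      }
      std::nth_element(buf.begin(), buf.begin() + k, buf.end());
      out(i, j) = buf[k];
    }
  }
  return out;
}
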