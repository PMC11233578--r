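#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Per-frame q-th percentile of x over a centered window of half-width
// `halfwin` frames; truncated windows at the edges.  Linear interpolation
// between order statistics (R quantile type 7) so that an R-level
// sort-and-index oracle reproduces the values exactly.
// [[Rcpp::export(name = ".run_percentile_cpp")]]
NumericVector run_percentile_cpp(NumericVector x, int halfwin, double q) {
  const int n = x.size();
  if (n == 0) stop("empty trace");
  if (halfwin < 0) stop("halfwin must be >= 0");
  if (q < 0.0 || q > 100.0) stop("percentile out of range");
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * halfwin + 1);
  for (int i = 0; i < n; ++i) {
    const int lo = std::max(0, i - halfwin);
    const int hi = std::min(n - 1, i + halfwin);
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    std::sort(buf.begin(), buf.end());
    const int m = static_cast<int>(buf.size());
    const double h = (m - 1) * q / 100.0;
    const int fl = static_cast<int>(std::floor(h));
    const double frac = h - fl;
    double v = buf[fl];
    if (fl + 1 < m) v += frac * (buf[fl + 1] - buf[fl]);
    out[i] = v;
  }
  return out;
}
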