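#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Rolling percentile over a centred window truncated at the trace edges.
// Quantile definition is linear interpolation between order statistics
// (type 7, matching stats::quantile's default), evaluated on the window
// [i - halfwidth, i + halfwidth] intersected with [0, n).
// A sorted window is maintained by binary-search insert/erase: O(n * w).
// [[Rcpp::export]]
NumericVector roll_quantile_trunc(NumericVector x, int halfwidth, double p) {
  const int n = x.size();
  if (n == 0) return NumericVector(0);
  if (halfwidth < 0) stop("halfwidth must be >= 0");
  if (p < 0.0 || p > 1.0) stop("p must be in [0, 1]");
  NumericVector out(n);

  std::vector<double> win;
  win.reserve(2 * (size_t)halfwidth + 2);
  int hi = std::min(n - 1, halfwidth);
  for (int i = 0; i <= hi; ++i)
    win.insert(std::upper_bound(win.begin(), win.end(), x[i]), x[i]);

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      int add = i + halfwidth;
      if (add < n)
        win.insert(std::upper_bound(win.begin(), win.end(), x[add]), x[add]);
      int drop = i - halfwidth - 1;
      if (drop >= 0)
        win.erase(std::lower_bound(win.begin(), win.end(), x[drop]));
    }
    const int m = (int)win.size();
    const double h = (m - 1) * p;
    const int k = (int)std::floor(h);
    const double frac = h - k;
    out[i] = (k + 1 < m) ? win[k] + frac * (win[k + 1] - win[k]) : win[k];
  }
  return out;
}
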