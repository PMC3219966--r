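#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Sliding-window median with truncated windows at the sequence ends.
// Window at position i (0-based) is [max(0, i-h), min(n-1, i+h)].
// Median of an even-size window is the mean of the two middle order
// statistics (matching stats::median).
//
// Maintains the window as two multisets (low: max-half, high: min-half)
// with |low| == |high| or |low| == |high| + 1.

class MedianWindow {
  std::multiset<double> low, high;

  void rebalance() {
    if (low.size() > high.size() + 1) {
      auto it = std::prev(low.end());
      high.insert(*it);
      low.erase(it);
    } else if (high.size() > low.size()) {
      auto it = high.begin();
      low.insert(*it);
      high.erase(it);
    }
  }

public:
  void insert(double x) {
    if (low.empty() || x <= *low.rbegin()) low.insert(x);
    else high.insert(x);
    rebalance();
  }
  void erase(double x) {
    if (!low.empty() && x <= *low.rbegin()) {
      auto it = low.find(x);
      if (it != low.end()) low.erase(it);
      else high.erase(high.find(x));
    } else {
      auto it = high.find(x);
      if (it != high.end()) high.erase(it);
      else low.erase(low.find(x));
    }
    rebalance();
  }
  double median() const {
    size_t m = low.size() + high.size();
    if (m == 0) return NA_REAL;
    if (m % 2 == 1) return *low.rbegin();
    return (*low.rbegin() + *high.begin()) / 2.0;
  }
};

// [[Rcpp::export]]
NumericVector rolling_median_trunc(NumericVector x, int halfwidth) {
  int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  MedianWindow w;
  int h = halfwidth;
  for (int j = 0; j <= std::min(h, n - 1); ++j) w.insert(x[j]);
  out[0] = w.median();
  for (int i = 1; i < n; ++i) {
    int add = i + h;
    if (add <= n - 1) w.insert(x[add]);
    int drop = i - h - 1;
    if (drop >= 0) w.erase(x[drop]);
    out[i] = w.median();
  }
  return out;
}
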