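#include <Rcpp.h>
#include <set>

using namespace Rcpp;

// Sliding-window median over contiguous windows of length w:
// out[i] = median(x[i .. i+w-1]) (1-based), length(out) = n - w + 1.
// Two balanced multisets (low = max-half, high = min-half); O(n log w).
// [[Rcpp::export(name = ".sliding_median")]]
NumericVector sliding_median(NumericVector x, int w) {
  int n = x.size();
  if (w <= 0) stop("window must be positive");
  if (n < w) return NumericVector(0);
  int m = n - w + 1;
  NumericVector out(m);
  std::multiset<double> low, high;  // low: <= median half, high: >= half

  auto rebalance = [&]() {
    while (low.size() > high.size() + 1) {
      auto it = std::prev(low.end());
      high.insert(*it);
      low.erase(it);
    }
    while (high.size() > low.size()) {
      auto it = high.begin();
      low.insert(*it);
      high.erase(it);
    }
  };
  auto insert_val = [&](double v) {
    if (low.empty() || v <= *std::prev(low.end())) low.insert(v);
    else high.insert(v);
    rebalance();
  };
  auto erase_val = [&](double v) {
    auto it = low.find(v);
    if (it != low.end()) low.erase(it);
    else {
      it = high.find(v);
      high.erase(it);
    }
    rebalance();
  };
  auto med = [&]() -> double {
    if (w % 2 == 1) return *std::prev(low.end());
    return (*std::prev(low.end()) + *high.begin()) / 2.0;
  };

  for (int i = 0; i < w; ++i) insert_val(x[i]);
  out[0] = med();
  for (int i = 1; i < m; ++i) {
    erase_val(x[i - 1]);
    insert_val(x[i + w - 1]);
    out[i] = med();
  }
  return out;
}
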