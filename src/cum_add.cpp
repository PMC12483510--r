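#include <Rcpp.h>

using namespace Rcpp;

// In-place scatter-add: acc[idx] += val (idx 1-based). acc must be a
// freshly allocated numeric vector owned by the caller.
// [[Rcpp::export(name = ".cum_add")]]
void cum_add(NumericVector acc, IntegerVector idx, NumericVector val) {
  int n = idx.size();
  if (val.size() != n) stop("idx and val lengths differ");
  int m = acc.size();
  for (int i = 0; i < n; ++i) {
    int j = idx[i] - 1;
    if (j < 0 || j >= m) stop("index out of range");
    acc[j] += val[i];
  }
}
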