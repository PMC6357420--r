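#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact 1-D k-means on sorted (unique) values with weights, by dynamic
// programming over contiguous partitions. The within-cluster cost is
// totally monotone, so each DP layer is filled by divide and conquer on
// the argmin, giving O(k n log n) overall.

namespace {

struct Prefix {
  std::vector<long double> w, wx, wx2;
  explicit Prefix(const NumericVector& x, const NumericVector& wt)
      : w(x.size() + 1, 0.0L), wx(x.size() + 1, 0.0L),
        wx2(x.size() + 1, 0.0L) {
    for (int i = 0; i < x.size(); ++i) {
      w[i + 1] = w[i] + (long double)wt[i];
      wx[i + 1] = wx[i] + (long double)wt[i] * x[i];
      wx2[i + 1] = wx2[i] + (long double)wt[i] * x[i] * x[i];
    }
  }
  // SSE of one cluster over sorted indices [i, j] (0-based, inclusive)
  long double cost(int i, int j) const {
    long double W = w[j + 1] - w[i];
    if (W <= 0.0L) return 0.0L;
    long double S = wx[j + 1] - wx[i];
    long double Q = wx2[j + 1] - wx2[i];
    long double c = Q - S * S / W;
    return c > 0.0L ? c : 0.0L;
  }
};

void fill_layer(const Prefix& pre, const std::vector<long double>& prev,
                std::vector<long double>& cur, std::vector<int>& from,
                int layer, int lo, int hi, int opt_lo, int opt_hi) {
  if (lo > hi) return;
  int mid = (lo + hi) / 2;
  long double best = std::numeric_limits<long double>::infinity();
  int best_i = -1;
  int i_max = std::min(mid, opt_hi);
  // first element of this cluster: at least `layer` (0-based layer index)
  int i_min = std::max(layer, opt_lo);
  for (int i = i_min; i <= i_max; ++i) {
    long double cand = prev[i - 1] + pre.cost(i, mid);
    if (cand < best) {  // strict: ties keep the lowest split index
      best = cand;
      best_i = i;
    }
  }
  cur[mid] = best;
  from[mid] = best_i;
  fill_layer(pre, prev, cur, from, layer, lo, mid - 1, opt_lo, best_i);
  fill_layer(pre, prev, cur, from, layer, mid + 1, hi, best_i, opt_hi);
}

}  // namespace

// [[Rcpp::export(name = ".kmeans1d_dp")]]
List kmeans1d_dp(NumericVector x, NumericVector w, int k) {
  int n = x.size();
  if (k < 1 || k > n) stop("k must be between 1 and the number of values");
  Prefix pre(x, w);
  std::vector<long double> prev(n), cur(n);
  std::vector<std::vector<int> > from(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) prev[j] = pre.cost(0, j);
  for (int q = 1; q < k; ++q) {
    fill_layer(pre, prev, cur, from[q], q, q, n - 1, q, n - 1);
    for (int j = 0; j < q; ++j)
      cur[j] = std::numeric_limits<long double>::infinity();
    prev.swap(cur);
  }
  // backtrack cluster boundaries
  IntegerVector assign(n);
  NumericVector centers(k), sizes(k);
  int j = n - 1;
  for (int q = k - 1; q >= 0; --q) {
    int i = (q == 0) ? 0 : from[q][j];
    long double W = pre.w[j + 1] - pre.w[i];
    long double S = pre.wx[j + 1] - pre.wx[i];
    centers[q] = (double)(S / W);
    sizes[q] = (double)W;
    for (int t = i; t <= j; ++t) assign[t] = q + 1;
    j = i - 1;
  }
  return List::create(_["assignment"] = assign, _["centers"] = centers,
                      _["weights"] = sizes, _["sse"] = (double)prev[n - 1]);
}
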