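#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Weighted Fisher optimal partitioning: split `x` (distinct, ascending, with
// positive weights `w`) into at most k contiguous classes minimising the total
// within-class weighted sum of squared deviations.
//
// The within-class SSD cost satisfies the quadrangle (concave-Monge)
// inequality, so per-layer argmins are monotone in the right endpoint and
// each DP layer can be filled by divide-and-conquer in O(n log n); total
// O(k n log n). Ties in the objective break toward the earliest split
// (deterministic).
//
// Returns the 1-based index of the last element of each class, plus the
// optimal within-class SSD.

static std::vector<long double> W, S, S2;

static inline long double seg_cost(int j, int i) {  // segment j..i, 0-based
  long double ww = W[i + 1] - W[j];
  long double s  = S[i + 1] - S[j];
  long double c  = (S2[i + 1] - S2[j]) - s * s / ww;
  return c > 0 ? c : 0.0L;
}

// fill D_cur[i] = min_{j in [m-1, i]} D_prev[j-1] + cost(j, i) for i in
// [lo, hi], knowing the optimal j lies in [jlo, jhi]
static void dc_layer(const std::vector<long double>& D_prev,
                     std::vector<long double>& D_cur,
                     std::vector<int>& B_cur,
                     int m, int lo, int hi, int jlo, int jhi) {
  if (lo > hi) return;
  int mid = lo + (hi - lo) / 2;
  long double best = std::numeric_limits<long double>::infinity();
  int arg = jlo;
  int jmax = std::min(mid, jhi);
  for (int j = std::max(jlo, m - 1); j <= jmax; ++j) {
    long double v = D_prev[j - 1] + seg_cost(j, mid);
    if (v < best) { best = v; arg = j; }
  }
  D_cur[mid] = best;
  B_cur[mid] = arg;
  dc_layer(D_prev, D_cur, B_cur, m, lo, mid - 1, jlo, arg);
  dc_layer(D_prev, D_cur, B_cur, m, mid + 1, hi, arg, jhi);
}

// [[Rcpp::export(name = ".fisher_partition_dp")]]
List fisher_partition_dp(NumericVector x, NumericVector w, int k) {
  const int n = x.size();
  if (n == 0) stop("empty input");
  if (k < 1) stop("k must be >= 1");
  if (k > n) k = n;

  W.assign(n + 1, 0.0L); S.assign(n + 1, 0.0L); S2.assign(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    W[i + 1]  = W[i] + (long double)w[i];
    S[i + 1]  = S[i] + (long double)w[i] * x[i];
    S2[i + 1] = S2[i] + (long double)w[i] * x[i] * x[i];
  }

  std::vector<long double> D_prev(n), D_cur(n);
  std::vector<std::vector<int> > B(k + 1, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i) D_prev[i] = seg_cost(0, i);
  for (int m = 2; m <= k; ++m) {
    dc_layer(D_prev, D_cur, B[m], m, m - 1, n - 1, m - 1, n - 1);
    std::swap(D_prev, D_cur);
  }

  IntegerVector last(k);
  int i = n - 1;
  for (int m = k; m >= 1; --m) {
    last[m - 1] = i + 1;           // 1-based last index of class m
    i = (m > 1 ? B[m][i] : 0) - 1;
  }
  double ssd = (double)D_prev[n - 1];
  W.clear(); S.clear(); S2.clear();
  return List::create(_["last_index"] = last, _["ssd"] = ssd);
}
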