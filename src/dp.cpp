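#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Two-part MDL segmentation: per-segment data-cost table and dynamic program.
//
// The data cost of a segment is evaluated with exactly the same floating-point
// operation order as the reference R implementation (segment_class_cost /
// segment_data_cost): per class, the block values are accumulated column-major
// in extended ("long double") precision, matching R's sum(); the Gaussian code
// length is then formed with the identical double-precision expression.  The
// incremental extension over segment ends preserves that order, so the DP
// optimum agrees bit-for-bit with exhaustive enumeration built on the R
// cost functions.

// [[Rcpp::export]]
List cpp_mdl_dp(NumericMatrix D, List class_rows, int beta,
                double tau, double var_floor, NumericVector model_cost_k) {
  const int n = D.ncol();
  const int K = class_rows.size();
  const int kmax = model_cost_k.size();
  const double NEG = std::numeric_limits<double>::infinity();

  std::vector<std::vector<int> > rows(K);
  std::vector<double> wts(K);
  for (int k = 0; k < K; ++k) {
    IntegerVector r = class_rows[k];
    rows[k].resize(r.size());
    for (int i = 0; i < r.size(); ++i) rows[k][i] = r[i] - 1; // to 0-based
    wts[k] = (double) r.size();
  }

  const double inv_ln2 = 1.0 / std::log(2.0);
  const double log2tau = std::log2(tau);

  // segdc[i * n + j]: data cost of segment covering columns i..j (0-based),
  // defined for j - i + 1 >= beta.
  std::vector<double> segdc((size_t) n * n, NEG);
  std::vector<long double> acc1(K), acc2(K);

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) { acc1[k] = 0.0L; acc2[k] = 0.0L; }
    for (int j = i; j < n; ++j) {
      for (int k = 0; k < K; ++k) {
        const std::vector<int>& rk = rows[k];
        long double a1 = acc1[k], a2 = acc2[k];
        for (size_t t = 0; t < rk.size(); ++t) {
          double x = D(rk[t], j);
          a1 += x;
          double xx = x * x;
          a2 += xx;
        }
        acc1[k] = a1; acc2[k] = a2;
      }
      int len = j - i + 1;
      if (len < beta) continue;
      double seg = 0.0;
      for (int k = 0; k < K; ++k) {
        double cnt = (double) len * wts[k];
        double s1 = (double) acc1[k];
        double s2 = (double) acc2[k];
        double mu = s1 / cnt;
        double sig2 = s2 / cnt - mu * mu;
        if (!(sig2 > var_floor)) sig2 = var_floor;
        double cost = (cnt / 2.0) * (inv_ln2 + std::log2(2.0 * M_PI * sig2))
          + cnt * log2tau;
        seg = seg + cost / wts[k];
      }
      segdc[(size_t) i * n + j] = seg;
    }
  }

  // dp[k][j]: minimal data cost of covering columns 0..j with exactly k+1
  // segments, each of length >= beta.  Ties resolved toward the earliest
  // previous boundary (strict < while scanning t in ascending order).
  std::vector<double> prev(n, NEG), cur(n, NEG);
  std::vector<std::vector<int> > parent(kmax, std::vector<int>(n, -2));

  for (int j = beta - 1; j < n; ++j) {
    prev[j] = segdc[(size_t) 0 * n + j];
    parent[0][j] = -1;
  }
  std::vector<double> best_data(kmax, NEG);
  best_data[0] = prev[n - 1];

  for (int k = 1; k < kmax; ++k) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int j = (k + 1) * beta - 1; j < n; ++j) {
      double best = NEG; int arg = -2;
      // t = 0-based end column of the previous segment
      for (int t = k * beta - 1; t <= j - beta; ++t) {
        if (!std::isfinite(prev[t])) continue;
        double cand = prev[t] + segdc[(size_t)(t + 1) * n + j];
        if (cand < best) { best = cand; arg = t; }
      }
      cur[j] = best;
      parent[k][j] = arg;
    }
    best_data[k] = cur[n - 1];
    std::swap(prev, cur);
  }

  // choose the number of segments: minimal total, ties toward fewer segments
  int best_k = -1; double best_total = NEG;
  for (int k = 0; k < kmax; ++k) {
    if (!std::isfinite(best_data[k])) continue;
    double total = best_data[k] + model_cost_k[k];
    if (total < best_total) { best_total = total; best_k = k; }
  }
  if (best_k < 0) stop("no feasible segmentation (n < beta?)");

  // backtrack segment boundaries
  std::vector<int> starts;
  int j = n - 1, k = best_k;
  while (k >= 0) {
    int t = parent[k][j];
    starts.push_back(t + 2); // 1-based start column of segment ending at j
    j = t; --k;
  }
  std::reverse(starts.begin(), starts.end());

  return List::create(
    _["n_segments"] = best_k + 1,
    _["data_bits"] = best_data[best_k],
    _["total_bits"] = best_total,
    _["starts"] = wrap(starts));
}
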