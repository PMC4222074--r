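#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Circular binary segmentation scan: maximal mean-shift statistic over
// circular arcs (i, j] of a probe sequence, with a permutation p-value.
//
// The statistic for arc (i, j] against its complement is
//   T = |mean(arc) - mean(complement)| * sqrt(k * (n - k) / n),
// i.e. the two-sample t numerator with the pooled-variance factor held
// fixed; since the overall variance is permutation-invariant it cancels
// from the permutation test.
//
// Constraints: the arc needs >= min_width probes and every linear piece
// the split would create ([1,i], (i,j], (j,n]) is either empty or has
// >= min_width probes. The full sequence (i==0 && j==n) is excluded.

static double max_arc_stat(const std::vector<double>& x, int min_width,
                           int* best_i, int* best_j) {
  const int n = (int)x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double total = S[n];
  // squared statistic: T^2 = (meanA - meanB)^2 * k (n-k) / n; the width
  // factor and the 1/k, 1/(n-k) divisions depend only on k, so hoist them
  std::vector<double> w(n + 1, 0.0), invk(n + 1, 0.0);
  for (int k = 1; k < n; ++k) {
    w[k] = (double)k * (double)(n - k) / (double)n;
    invk[k] = 1.0 / k;
  }
  double best = -1.0;
  int bi = -1, bj = -1;
  for (int i = 0; i <= n - 1; ++i) {
    if (i != 0 && i < min_width) continue;
    const double Si = S[i];
    for (int j = i + 1; j <= n; ++j) {
      if (i == 0 && j == n) continue;
      const int k = j - i;
      if (k < min_width) continue;
      if (j != n && (n - j) < min_width) continue;
      const double sumA = S[j] - Si;
      const double diff = sumA * invk[k] - (total - sumA) * invk[n - k];
      const double T2 = diff * diff * w[k];
      if (T2 > best) { best = T2; bi = i; bj = j; }
    }
  }
  *best_i = bi;
  *best_j = bj;
  return best <= 0.0 ? best : std::sqrt(best);
}

// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x, int n_perm = 1000, int min_width = 2) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  int bi = -1, bj = -1;
  double obs = max_arc_stat(v, min_width, &bi, &bj);
  if (obs <= 0.0 || bi < 0) {
    return List::create(_["stat"] = 0.0, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER, _["p"] = 1.0);
  }
  RNGScope scope;  // permutations draw from R's RNG -> set.seed() reproducible
  int count = 0;
  std::vector<double> perm(v);
  const double eps = 1e-12 * (1.0 + obs);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates shuffle
    for (int t = n - 1; t > 0; --t) {
      int u = (int)std::floor(unif_rand() * (t + 1));
      if (u > t) u = t;
      double tmp = perm[t]; perm[t] = perm[u]; perm[u] = tmp;
    }
    int pi, pj;
    double stat = max_arc_stat(perm, min_width, &pi, &pj);
    if (stat >= obs - eps) ++count;
  }
  const double p = (1.0 + count) / (double)(n_perm + 1);
  return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj, _["p"] = p);
}
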