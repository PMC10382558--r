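#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Most probable level sequence for a trace under Gaussian emissions and a
// sticky uniform transition prior: log P(stay) = stay_logp on the diagonal,
// log P(switch to a given other level) = switch_logp. Returns 1-based level
// indices. Standard Viterbi dynamic programme with backtracking.
// [[Rcpp::export]]
IntegerVector viterbi_gaussian(NumericVector x, NumericVector mu,
                               NumericVector sd, double stay_logp,
                               double switch_logp) {
  const int n = x.size(), m = mu.size();
  if (n == 0 || m == 0) stop("empty input");
  std::vector<double> inv2v(m), lconst(m);
  for (int j = 0; j < m; ++j) {
    double s = sd[j];
    if (s <= 0) stop("emission sd must be positive");
    inv2v[j] = 0.5 / (s * s);
    lconst[j] = -std::log(s);
  }
  std::vector<double> prev(m), cur(m);
  IntegerMatrix back(n, m);
  for (int j = 0; j < m; ++j) {
    double d = x[0] - mu[j];
    prev[j] = lconst[j] - d * d * inv2v[j];
  }
  for (int t = 1; t < n; ++t) {
    // best predecessor overall (for switch moves)
    int argbest = 0;
    for (int j = 1; j < m; ++j) if (prev[j] > prev[argbest]) argbest = j;
    for (int j = 0; j < m; ++j) {
      double stay = prev[j] + stay_logp;
      double sw = prev[argbest] + switch_logp;
      int from;
      if (argbest == j) {
        // best switch source must exclude j itself
        double best2 = -INFINITY; int arg2 = j;
        for (int i = 0; i < m; ++i)
          if (i != j && prev[i] > best2) { best2 = prev[i]; arg2 = i; }
        sw = best2 + switch_logp;
        from = (stay >= sw) ? j : arg2;
      } else {
        from = (stay >= sw) ? j : argbest;
      }
      double base = (stay >= sw) ? stay : sw;
      double d = x[t] - mu[j];
      cur[j] = base + lconst[j] - d * d * inv2v[j];
      back(t, j) = from;
    }
    std::swap(prev, cur);
  }
  IntegerVector path(n);
  int j = 0;
  for (int i = 1; i < m; ++i) if (prev[i] > prev[j]) j = i;
  path[n - 1] = j + 1;
  for (int t = n - 1; t > 0; --t) {
    j = back(t, j);
    path[t - 1] = j + 1;
  }
  return path;
}
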