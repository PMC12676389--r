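#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Optimal partitioning for a piecewise-constant Gaussian mean model with a
// per-changepoint penalty, with PELT pruning (exact). Segment cost is the
// within-segment SSE up to a term independent of the partition, i.e.
// -(segment sum)^2 / length. Returns 1-based first frames of new segments.
// [[Rcpp::export]]
Rcpp::IntegerVector pelt_mean_cpp(Rcpp::NumericVector x, double penalty) {
  const int n = x.size();
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  std::vector<double> F(n + 1);
  std::vector<int> last(n + 1, 0);
  F[0] = -penalty;
  std::vector<int> cand;
  cand.push_back(0);
  std::vector<int> next_cand;
  std::vector<double> buf;
  for (int t = 1; t <= n; ++t) {
    double best = R_PosInf;
    int bs = 0;
    buf.resize(cand.size());
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      const int s = cand[ci];
      const double seg = cs[t] - cs[s];
      const double base = F[s] - seg * seg / (t - s);
      buf[ci] = base;
      if (base + penalty < best) { best = base + penalty; bs = s; }
    }
    F[t] = best;
    last[t] = bs;
    next_cand.clear();
    for (size_t ci = 0; ci < cand.size(); ++ci)
      if (buf[ci] <= F[t]) next_cand.push_back(cand[ci]);
    next_cand.push_back(t);
    cand.swap(next_cand);
  }
  std::vector<int> cps;
  int t = n;
  while (t > 0) {
    const int s = last[t];
    if (s > 0) cps.push_back(s + 1);
    t = s;
  }
  std::reverse(cps.begin(), cps.end());
  return Rcpp::wrap(cps);
}
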