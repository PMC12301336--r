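#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Second-order biased random walks (node2vec). `nbrs` is a 1-based
// adjacency list with each neighbour vector sorted ascending; `starts` is
// the full, already-shuffled sequence of start nodes. Transition weights
// from state (prev t, current v) to candidate x: 1/p if x == t, 1 if x is
// adjacent to t, 1/q otherwise. Uses R's RNG, so walks are reproducible
// under set.seed.
// [[Rcpp::export]]
List biased_walks_cpp(List nbrs, IntegerVector starts, int walk_length,
                      double p, double q) {
  RNGScope scope;
  int n = nbrs.size();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbrs[i];
    adj[i].assign(v.begin(), v.end());  // 1-based, sorted
  }
  List walks(starts.size());
  std::vector<double> w;
  for (int s = 0; s < starts.size(); ++s) {
    std::vector<int> walk;
    walk.reserve(walk_length);
    int cur = starts[s];  // 1-based
    int prev = -1;
    walk.push_back(cur);
    while ((int)walk.size() < walk_length) {
      const std::vector<int>& cand = adj[cur - 1];
      if (cand.empty()) break;
      int nxt;
      if (prev < 0) {
        nxt = cand[(int)(unif_rand() * cand.size())];
      } else {
        const std::vector<int>& pn = adj[prev - 1];
        w.resize(cand.size());
        double tot = 0.0;
        for (size_t k = 0; k < cand.size(); ++k) {
          double wk;
          if (cand[k] == prev) {
            wk = 1.0 / p;
          } else if (std::binary_search(pn.begin(), pn.end(), cand[k])) {
            wk = 1.0;
          } else {
            wk = 1.0 / q;
          }
          tot += wk;
          w[k] = tot;
        }
        double u = unif_rand() * tot;
        size_t k = std::lower_bound(w.begin(), w.end(), u) - w.begin();
        if (k >= cand.size()) k = cand.size() - 1;
        nxt = cand[k];
      }
      prev = cur;
      cur = nxt;
      walk.push_back(cur);
    }
    walks[s] = wrap(walk);
  }
  return walks;
}
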