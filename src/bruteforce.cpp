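#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Exact minimum number of parallel steps for child-before-parent
// elimination of a rooted tree with k unit-speed threads.
//
// States are bitmasks over the non-root nodes (bit set = processed);
// breadth-first search over states, where one transition processes a
// subset of the current candidate set. Taking fewer than min(k, |cand|)
// nodes can never help (processing more nodes only enlarges later
// candidate sets), so only maximal-size selections are enumerated.
//
// parent0: for non-root nodes in topological order, the 0-based index of
// the parent within {root=-1, nonroot 0..m-1}; i.e. parent0[i] == -1 when
// the parent is the root, otherwise the non-root index of the parent.
// [[Rcpp::export]]
int bf_min_steps_cpp(IntegerVector parent0, int k) {
  const int m = parent0.size();
  if (m == 0) return 0;
  if (m > 14) stop("exhaustive search limited to 14 non-root nodes");

  // children (non-root indices) of each non-root node
  std::vector<std::vector<int>> kids(m);
  for (int i = 0; i < m; ++i) {
    int p = parent0[i] - 1; // parent0 is 1-based node index minus 1 == 0-based
    // parent0 passed as (tree$parent[-1]) - 1: value 0 means root
    if (p >= 0) kids[p].push_back(i);
  }

  const int full = (1 << m) - 1;
  std::vector<int> dist(1 << m, -1);
  std::queue<int> q;
  dist[0] = 0;
  q.push(0);

  while (!q.empty()) {
    int s = q.front();
    q.pop();
    if (s == full) return dist[s];
    // candidate set: unprocessed nodes whose children are all processed
    std::vector<int> cand;
    for (int i = 0; i < m; ++i) {
      if (s & (1 << i)) continue;
      bool ok = true;
      for (int c : kids[i]) {
        if (!(s & (1 << c))) { ok = false; break; }
      }
      if (ok) cand.push_back(i);
    }
    int take = std::min<int>(k, cand.size());
    int c = cand.size();
    // Gosper's hack over the candidate positions: all c-choose-take picks
    unsigned comb = (1u << take) - 1u;
    while (comb < (1u << c)) {
      int nxt = s;
      for (int b = 0; b < c; ++b) {
        if (comb & (1u << b)) nxt |= (1 << cand[b]);
      }
      if (dist[nxt] < 0) {
        dist[nxt] = dist[s] + 1;
        if (nxt == full) return dist[nxt];
        q.push(nxt);
      }
      unsigned x = comb & (unsigned)(-(int)comb);
      unsigned y = comb + x;
      comb = (((comb & ~y) / x) >> 1) | y;
      if (take == 0) break;
    }
  }
  return dist[full];
}
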