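// Exhaustive Wheeler-ordering search over all node permutations, used as
// the ground-truth recognizer for small graphs. Independent of the other
// recognition paths: re-implements the Wheeler conditions directly.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".brute_force_cpp")]]
List brute_force_cpp(int n,
                     IntegerVector from,   // 1-based node indices
                     IntegerVector to,
                     IntegerVector lab) {  // 1-based label indices
  const int e = from.size();
  std::vector<int> indeg(n + 1, 0);
  for (int k = 0; k < e; ++k) indeg[to[k]]++;

  // rank[v] for node v; enumerate rank vectors in lexicographic order of
  // (rank[1], ..., rank[n]), i.e. identifier-lexicographic order.
  std::vector<int> rank(n + 1);
  for (int v = 1; v <= n; ++v) rank[v] = v;
  double tried = 0;
  do {
    ++tried;
    bool ok = true;
    // (a) 0-indegree nodes strictly before positive-indegree nodes
    int max_root = 0, min_other = n + 1;
    for (int v = 1; v <= n && ok; ++v) {
      if (indeg[v] == 0) { if (rank[v] > max_root) max_root = rank[v]; }
      else               { if (rank[v] < min_other) min_other = rank[v]; }
    }
    if (max_root > min_other) ok = false;
    // (b) and (c) over all edge pairs
    for (int a = 0; a < e && ok; ++a) {
      for (int b = a + 1; b < e && ok; ++b) {
        int la = lab[a], lb = lab[b];
        if (la == lb) {
          int ua = rank[from[a]], ub = rank[from[b]];
          int va = rank[to[a]], vb = rank[to[b]];
          if ((ua < ub && va > vb) || (ub < ua && vb > va)) ok = false;
        } else {
          int lo = (la < lb) ? a : b, hi = (la < lb) ? b : a;
          if (rank[to[lo]] >= rank[to[hi]]) ok = false;
        }
      }
    }
    if (ok) {
      IntegerVector res(n);
      for (int v = 1; v <= n; ++v) res[v - 1] = rank[v];
      return List::create(_["found"] = true, _["rank"] = res,
                          _["tried"] = tried);
    }
  } while (std::next_permutation(rank.begin() + 1, rank.end()));
  return List::create(_["found"] = false, _["rank"] = R_NilValue,
                      _["tried"] = tried);
}
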