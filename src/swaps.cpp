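#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline long long ekey(int a, int b, int n) {
  return static_cast<long long>(a) * n + b;
}

// Degree-preserving randomization by attempted pairwise edge swaps:
// (r1->t1, r2->t2) => (r1->t2, r2->t1). A swap is rejected when it would
// duplicate an existing edge, or create a self-edge in a network that had
// none. Node indices are 0-based over the full node set; only the target
// endpoints move, so every out- and in-degree is conserved exactly.
// Uses R's RNG (unif_rand) so results follow set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_edge_swap(IntegerVector from, IntegerVector to, int n_nodes,
                            int attempts, bool allow_loops) {
  int ne = from.size();
  std::vector<int> f(from.begin(), from.end());
  std::vector<int> t(to.begin(), to.end());
  if (ne >= 2) {
    std::unordered_set<long long> edges;
    edges.reserve(static_cast<size_t>(ne) * 2);
    for (int i = 0; i < ne; ++i) edges.insert(ekey(f[i], t[i], n_nodes));
    for (int a = 0; a < attempts; ++a) {
      int i = static_cast<int>(unif_rand() * ne);
      int j = static_cast<int>(unif_rand() * ne);
      if (i >= ne) i = ne - 1;
      if (j >= ne) j = ne - 1;
      if (i == j) continue;
      int f1 = f[i], t1 = t[i], f2 = f[j], t2 = t[j];
      if (f1 == f2 || t1 == t2) continue;  // swap would be the identity
      if (!allow_loops && (f1 == t2 || f2 == t1)) continue;
      if (edges.count(ekey(f1, t2, n_nodes)) ||
          edges.count(ekey(f2, t1, n_nodes)))
        continue;
      edges.erase(ekey(f1, t1, n_nodes));
      edges.erase(ekey(f2, t2, n_nodes));
      edges.insert(ekey(f1, t2, n_nodes));
      edges.insert(ekey(f2, t1, n_nodes));
      t[i] = t2;
      t[j] = t1;
    }
  }
  IntegerMatrix out(ne, 2);
  for (int i = 0; i < ne; ++i) {
    out(i, 0) = f[i];
    out(i, 1) = t[i];
  }
  return out;
}

// Shared-target counts for every unordered regulator pair, accumulated by
// walking each target's regulator list (cost sum over targets of d^2,
// small for the sparse in-degrees of regulatory networks). reg/tgt are
// 1-based role indices per edge; returns a dense m x m matrix with counts
// in the upper triangle (i < j).
// [[Rcpp::export]]
NumericMatrix cpp_pair_counts(IntegerVector reg, IntegerVector tgt, int m,
                              int n_tgt) {
  int ne = reg.size();
  std::vector<std::vector<int> > by_tgt(n_tgt);
  for (int e = 0; e < ne; ++e) by_tgt[tgt[e] - 1].push_back(reg[e] - 1);
  NumericMatrix out(m, m);
  for (int t = 0; t < n_tgt; ++t) {
    const std::vector<int>& rs = by_tgt[t];
    int d = rs.size();
    for (int a = 0; a < d; ++a) {
      for (int b = a + 1; b < d; ++b) {
        int i = rs[a], j = rs[b];
        if (i < j)
          out(i, j) += 1;
        else
          out(j, i) += 1;
      }
    }
  }
  return out;
}
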