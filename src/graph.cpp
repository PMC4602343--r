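// Cycle bookkeeping primitives shared by the breakpoint-graph module and the
// simulator hot loop.  Matchings arrive as 1-based mate vectors.

#include <Rcpp.h>
using namespace Rcpp;

// Lengths of the alternating cycles of the union of two perfect matchings,
// measured in adjacencies of the first matching (trivial cycle = 1).
// [[Rcpp::export]]
IntegerVector union_cycle_lengths_cpp(IntegerVector m1, IntegerVector m2) {
  int nv = m1.size();
  if (m2.size() != nv) stop("matchings must be on the same vertex set");
  std::vector<bool> visited(nv, false);
  std::vector<int> lengths;
  for (int v = 0; v < nv; ++v) {
    if (visited[v]) continue;
    int len = 0, w = v;
    do {
      visited[w] = true;
      int u = m1[w] - 1;
      visited[u] = true;
      ++len;
      w = m2[u] - 1;
    } while (w != v);
    lengths.push_back(len);
  }
  return wrap(lengths);
}

// Component (alternating-cycle) id per vertex, 1-based.
// [[Rcpp::export]]
IntegerVector union_cycle_membership_cpp(IntegerVector m1, IntegerVector m2) {
  int nv = m1.size();
  IntegerVector comp(nv, 0);
  int id = 0;
  for (int v = 0; v < nv; ++v) {
    if (comp[v] != 0) continue;
    ++id;
    int w = v;
    do {
      comp[w] = id;
      int u = m1[w] - 1;
      comp[u] = id;
      w = m2[u] - 1;
    } while (w != v);
  }
  return comp;
}

// Are elements x and y on the same cycle of permutation pi?
// [[Rcpp::export]]
bool perm_same_cycle_cpp(IntegerVector pi, int x, int y) {
  int w = pi[x - 1];
  while (w != x) {
    if (w == y) return true;
    w = pi[w - 1];
  }
  return x == y;
}

// Logical mask of the elements on x's cycle of permutation pi.
// [[Rcpp::export]]
LogicalVector perm_cycle_members_cpp(IntegerVector pi, int x) {
  LogicalVector out(pi.size(), false);
  int w = x;
  do {
    out[w - 1] = true;
    w = pi[w - 1];
  } while (w != x);
  return out;
}
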