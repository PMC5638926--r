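#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Weighted-parsimony (Sankoff) reconstruction of ancestral codon states
// over the 61 sense codons, vectorized over alignment columns.
//
// leaf_states: ntip x ncol matrix of 1-based codon indices.
// edge_parent/edge_child: postorder edge list (children before parents),
//   1-based node ids; tips are 1..ntip, internal nodes ntip+1..nnode.
// cost: 61 x 61 integer matrix. The caller encodes the primary criterion
//   (nucleotide differences) and the secondary tie-break (non-synonymous
//   change count) into one integer, so a single min-sum DP realizes the
//   lexicographic objective; remaining ties go to the smallest codon index.
//
// Returns nnode x ncol matrix of reconstructed states (tips echoed back).
// [[Rcpp::export(name = ".sankoff_reconstruct")]]
IntegerMatrix sankoff_reconstruct(const IntegerMatrix leaf_states,
                                  const IntegerVector edge_parent,
                                  const IntegerVector edge_child,
                                  const int nnode,
                                  const int root,
                                  const IntegerMatrix cost) {
  const int ntip = leaf_states.nrow();
  const int ncol = leaf_states.ncol();
  const int nedge = edge_parent.size();
  const int NS = 61;
  const int INF = INT_MAX / 4;

  IntegerMatrix out(nnode, ncol);
  std::vector<int> S((size_t)nnode * NS);

  // children lists for the down-pass
  std::vector<std::vector<int>> kids(nnode + 1);
  for (int e = 0; e < nedge; ++e) kids[edge_parent[e] - 1].push_back(edge_child[e] - 1);

  std::vector<int> state(nnode);

  for (int col = 0; col < ncol; ++col) {
    // init
    for (int v = 0; v < nnode; ++v) {
      int* Sv = &S[(size_t)v * NS];
      if (v < ntip) {
        for (int s = 0; s < NS; ++s) Sv[s] = INF;
        Sv[leaf_states(v, col) - 1] = 0;
      } else {
        for (int s = 0; s < NS; ++s) Sv[s] = 0;
      }
    }
    // up-pass over postorder edges
    for (int e = 0; e < nedge; ++e) {
      const int p = edge_parent[e] - 1, c = edge_child[e] - 1;
      int* Sp = &S[(size_t)p * NS];
      const int* Sc = &S[(size_t)c * NS];
      for (int i = 0; i < NS; ++i) {
        int best = INF;
        const int* Ci = &cost[(size_t)i];  // column-major: cost(i, j) = cost[i + 61*j]
        for (int j = 0; j < NS; ++j) {
          const int v = Sc[j] + Ci[(size_t)j * NS];
          if (v < best) best = v;
        }
        Sp[i] += best;
      }
    }
    // root choice: minimal score, ties -> smallest codon index
    {
      const int* Sr = &S[(size_t)(root - 1) * NS];
      int bi = 0;
      for (int s = 1; s < NS; ++s) if (Sr[s] < Sr[bi]) bi = s;
      state[root - 1] = bi;
    }
    // down-pass (preorder = reversed postorder edges)
    for (int e = nedge - 1; e >= 0; --e) {
      const int p = edge_parent[e] - 1, c = edge_child[e] - 1;
      const int i = state[p];
      const int* Sc = &S[(size_t)c * NS];
      int bj = 0, best = INF;
      for (int j = 0; j < NS; ++j) {
        const int v = Sc[j] + cost[i + (size_t)j * NS];
        if (v < best) { best = v; bj = j; }
      }
      state[c] = bj;
    }
    for (int v = 0; v < nnode; ++v) out(v, col) = state[v] + 1;
  }
  return out;
}
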