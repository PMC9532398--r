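#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Edge-level path census. For every ordered edge (i, j):
//   T   : triangles containing the edge, = |N(i) & N(j)|
//   tW  : wedge triples (k, i, j)          = d_i - 1
//   tH  : head triples  (i, j, k)          = d_j - 1
//   Q   : chordless quadrangles i-j-k-l-i with (i,k), (j,l) absent
//   qW  : wedge quadruples (j, i, k, l)    = qH of the reversed edge
//   qH  : head quadruples  (i, j, k, l)    = sum_{k in N(j)\{i}} (d_k - 1 - a_ik)
// Adjacency arrives as a list of sorted 1-based neighbor vectors.
// [[Rcpp::export]]
List census_edges_cpp(List adj) {
  const int n = adj.size();
  std::vector<int> ptr(n + 1, 0);
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    ptr[i + 1] = ptr[i] + nb.size();
    for (int k = 0; k < nb.size(); ++k) idx.push_back(nb[k] - 1);
  }
  const int ne = ptr[n]; // number of ordered edges = 2m

  IntegerVector ei(ne), ej(ne);
  NumericVector T(ne), tW(ne), tH(ne), Q(ne), qW(ne), qH(ne);

  std::vector<char> mark_i(n, 0), mark_j(n, 0);
  std::vector<int> rev(ne, -1);

  for (int i = 0; i < n; ++i) {
    const int di = ptr[i + 1] - ptr[i];
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) mark_i[idx[e]] = 1;

    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      const int j = idx[e];
      const int dj = ptr[j + 1] - ptr[j];
      ei[e] = i + 1;
      ej[e] = j + 1;
      tW[e] = di - 1;
      tH[e] = dj - 1;

      // position of i within N(j) -> reversed edge index (sorted adjacency)
      const int *lo = &idx[ptr[j]];
      const int *hi = lo + dj;
      rev[e] = ptr[j] + (int)(std::lower_bound(lo, hi, i) - lo);

      // triangles: sorted-merge intersection of N(i) and N(j)
      int a = ptr[i], b = ptr[j], tri = 0;
      while (a < ptr[i + 1] && b < ptr[j + 1]) {
        if (idx[a] < idx[b]) ++a;
        else if (idx[a] > idx[b]) ++b;
        else { ++tri; ++a; ++b; }
      }
      T[e] = tri;

      for (int f = ptr[j]; f < ptr[j + 1]; ++f) mark_j[idx[f]] = 1;

      double qh = 0.0, qq = 0.0;
      for (int f = ptr[j]; f < ptr[j + 1]; ++f) {
        const int k = idx[f];
        if (k == i) continue;
        const int dk = ptr[k + 1] - ptr[k];
        qh += dk - 1 - (mark_i[k] ? 1 : 0);
        if (!mark_i[k]) {
          // chordless 4-cycles i-j-k-l-i: l in N(k) & N(i), l != j, (j,l) absent
          for (int g = ptr[k]; g < ptr[k + 1]; ++g) {
            const int l = idx[g];
            if (l != j && mark_i[l] && !mark_j[l]) qq += 1.0;
          }
        }
      }
      qH[e] = qh;
      Q[e] = qq;

      for (int f = ptr[j]; f < ptr[j + 1]; ++f) mark_j[idx[f]] = 0;
    }
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) mark_i[idx[e]] = 0;
  }

  for (int e = 0; e < ne; ++e) qW[e] = qH[rev[e]];

  return List::create(_["i"] = ei, _["j"] = ej, _["T"] = T, _["tW"] = tW,
                      _["tH"] = tH, _["Q"] = Q, _["qW"] = qW, _["qH"] = qH);
}
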