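#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving double-edge swaps on a symmetric weighted adjacency
// matrix. Each attempt draws two distinct edges (a-b, c-d), randomly orients
// the second, and proposes (a-d, c-b). Proposals creating self-loops or
// duplicating existing edges are rejected, so the degree sequence and the
// multiset of edge weights are both preserved exactly. Randomness comes from
// R's RNG stream (reproducible under set.seed()).
// [[Rcpp::export]]
NumericMatrix rewire_weighted_cpp(NumericMatrix w, int n_attempts) {
  int n = w.nrow();
  NumericMatrix m(clone(w));
  std::vector<int> ei, ej;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (m(i, j) > 0) {
        ei.push_back(i);
        ej.push_back(j);
      }
  int ne = (int)ei.size();
  if (ne < 2) return m;
  GetRNGstate();
  for (int att = 0; att < n_attempts; ++att) {
    int e1 = (int)(unif_rand() * ne);
    int e2 = (int)(unif_rand() * ne);
    if (e1 >= ne) e1 = ne - 1;
    if (e2 >= ne) e2 = ne - 1;
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a-d, c-b)
    if (a == d || c == b || a == c || b == d) continue;
    if (m(a, d) > 0 || m(c, b) > 0) continue;
    double w1 = m(a, b), w2 = m(c, d);
    m(a, b) = m(b, a) = 0;
    m(c, d) = m(d, c) = 0;
    m(a, d) = m(d, a) = w1;
    m(c, b) = m(b, c) = w2;
    ei[e1] = std::min(a, d);
    ej[e1] = std::max(a, d);
    ei[e2] = std::min(c, b);
    ej[e2] = std::max(c, b);
  }
  PutRNGstate();
  return m;
}
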