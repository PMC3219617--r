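#include <Rcpp.h>
#include <set>
#include <map>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Stratified Maslov-Sneppen double-edge swaps. Edges are 1-based integer
// node indices; `stratum` partitions the edges (edge type, and sign within
// type in signed mode); `dup_scope` identifies the scope within which
// duplicate (source, target) pairs are forbidden (the edge type, so that a
// positive and a negative copy of the same directed pair cannot coexist).
// Swaps that would create a self-loop or a duplicate are rejected and the
// attempt redrawn. Per-stratum in/out degree sequences are preserved
// exactly by construction. Uses R's RNG, so results are reproducible under
// set.seed().
// [[Rcpp::export]]
List cpp_rewire_strata(IntegerVector src, IntegerVector tgt,
                       IntegerVector stratum, IntegerVector dup_scope,
                       int q) {
  int m = src.size();
  std::vector<int> s(src.begin(), src.end()), t(tgt.begin(), tgt.end());
  std::map<int, std::vector<int> > groups;
  for (int i = 0; i < m; i++) groups[stratum[i]].push_back(i);
  std::set<std::tuple<int, int, int> > seen;
  for (int i = 0; i < m; i++)
    seen.insert(std::make_tuple(dup_scope[i], s[i], t[i]));
  std::vector<int> skipped;
  for (std::map<int, std::vector<int> >::iterator it = groups.begin();
       it != groups.end(); ++it) {
    std::vector<int> &idx = it->second;
    int n = (int)idx.size();
    if (n < 2) { skipped.push_back(it->first); continue; }
    long attempts = (long)q * n;
    for (long a = 0; a < attempts; a++) {
      int i = idx[(int)(unif_rand() * n)];
      int j = idx[(int)(unif_rand() * n)];
      if (i == j) continue;
      int a1 = s[i], b1 = t[i], a2 = s[j], b2 = t[j];
      // identical endpoints make the swap a no-op
      if (b1 == b2 || a1 == a2) continue;
      // proposed edges a1->b2, a2->b1: no new self-loops
      if (a1 == b2 || a2 == b1) continue;
      if (seen.count(std::make_tuple(dup_scope[i], a1, b2)) ||
          seen.count(std::make_tuple(dup_scope[j], a2, b1))) continue;
      seen.erase(std::make_tuple(dup_scope[i], a1, b1));
      seen.erase(std::make_tuple(dup_scope[j], a2, b2));
      seen.insert(std::make_tuple(dup_scope[i], a1, b2));
      seen.insert(std::make_tuple(dup_scope[j], a2, b1));
      t[i] = b2;
      t[j] = b1;
    }
  }
  return List::create(_["src"] = wrap(s), _["tgt"] = wrap(t),
                      _["skipped_strata"] = wrap(skipped));
}
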