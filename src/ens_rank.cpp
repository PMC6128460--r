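#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Efficient non-dominated sort (ENS with binary search over fronts,
// Zhang et al. 2015). Rows of X must be unique and finite; the R wrapper
// deduplicates identical criteria vectors beforehand, so a row that is
// elementwise <= a lexicographically later row strictly dominates it.
//
// Processing rows in lexicographic order guarantees any dominator of a row
// has already been placed, and "dominated somewhere in front f implies
// dominated in every earlier front" (dominance is transitive through the
// member of front f-1 that dominated the dominator), so the first
// admissible front can be found by binary search.

static inline bool all_leq(const NumericMatrix& X, int a, int b, int M) {
  for (int m = 0; m < M; ++m) {
    if (X(a, m) > X(b, m)) return false;
  }
  return true;
}

// [[Rcpp::export]]
IntegerVector ens_pareto_rank(NumericMatrix X) {
  const int K = X.nrow(), M = X.ncol();
  IntegerVector rank(K);
  if (K == 0) return rank;

  std::vector<int> ord(K);
  for (int i = 0; i < K; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    for (int m = 0; m < M; ++m) {
      if (X(a, m) < X(b, m)) return true;
      if (X(a, m) > X(b, m)) return false;
    }
    return false;
  });

  std::vector< std::vector<int> > fronts;
  for (int s = 0; s < K; ++s) {
    const int i = ord[s];
    int lo = 0, hi = static_cast<int>(fronts.size());
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      const std::vector<int>& fr = fronts[mid];
      bool dominated = false;
      // most recently inserted members are checked first: they are
      // lexicographically closest and most likely to dominate
      for (int t = static_cast<int>(fr.size()) - 1; t >= 0; --t) {
        if (all_leq(X, fr[t], i, M)) { dominated = true; break; }
      }
      if (dominated) lo = mid + 1; else hi = mid;
    }
    if (lo == static_cast<int>(fronts.size()))
      fronts.push_back(std::vector<int>());
    fronts[lo].push_back(i);
    rank[i] = lo + 1;
  }
  return rank;
}
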