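#include <Rcpp.h>
using namespace Rcpp;

// Compact box burning: one covering pass over a graph given its full
// shortest-path distance matrix. A box is grown by drawing uniformly from
// the candidate set (uncovered nodes whose distance to every current member
// is < box_size) until no candidate remains. Uses R's RNG so results follow
// set.seed().
//
// dist: n x n matrix of hop distances (R_PosInf across components).
// Returns 1-based box assignment per node.
// [[Rcpp::export]]
IntegerVector cbb_cover_cpp(NumericMatrix dist, double box_size) {
  const int n = dist.nrow();
  IntegerVector assignment(n, 0);
  std::vector<int> uncovered(n);
  for (int i = 0; i < n; ++i) uncovered[i] = i;
  std::vector<int> cand, next;
  cand.reserve(n);
  next.reserve(n);
  int box = 0;
  while (!uncovered.empty()) {
    ++box;
    cand = uncovered;
    while (!cand.empty()) {
      int pos = (int)(unif_rand() * cand.size());
      if (pos == (int)cand.size()) pos = cand.size() - 1;
      int pick = cand[pos];
      assignment[pick] = box;
      next.clear();
      const double *dcol = &dist(0, pick);
      for (size_t j = 0; j < cand.size(); ++j) {
        int c = cand[j];
        if (c != pick && dcol[c] < box_size) next.push_back(c);
      }
      cand.swap(next);
    }
    next.clear();
    for (size_t j = 0; j < uncovered.size(); ++j) {
      if (assignment[uncovered[j]] == 0) next.push_back(uncovered[j]);
    }
    uncovered.swap(next);
  }
  return assignment;
}
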