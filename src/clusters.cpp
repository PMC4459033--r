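#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected components of a logical matrix under 4-adjacency (row and column
// neighbours, no diagonals). Labels are 1..k in discovery order; 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix label_clusters(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(64);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        const int di[4] = {-1, 1, 0, 0};
        const int dj[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Largest 4-adjacent cluster size among points with t > crit or t < -crit
// (the two signs clustered separately, maximum over both). Used inside the
// permutation loop where only the maximum size is needed.
// [[Rcpp::export]]
int max_cluster_size(NumericMatrix t, double crit) {
  int nr = t.nrow(), nc = t.ncol(), n = nr * nc;
  std::vector<signed char> state(n, 0);  // 0 untouched, 1 visited
  int best = 0;
  std::vector<int> stack;
  stack.reserve(64);
  for (int start = 0; start < n; ++start) {
    if (state[start]) continue;
    double v = t[start];
    int sgn = v > crit ? 1 : (v < -crit ? -1 : 0);
    if (sgn == 0) { state[start] = 1; continue; }
    int size = 0;
    state[start] = 1;
    stack.push_back(start);
    while (!stack.empty()) {
      int idx = stack.back(); stack.pop_back();
      ++size;
      int ci = idx % nr, cj = idx / nr;
      const int di[4] = {-1, 1, 0, 0};
      const int dj[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int ni = ci + di[k], nj = cj + dj[k];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        int nidx = ni + nj * nr;
        if (state[nidx]) continue;
        double w = t[nidx];
        if ((sgn == 1 && w > crit) || (sgn == -1 && w < -crit)) {
          state[nidx] = 1;
          stack.push_back(nidx);
        }
      }
    }
    if (size > best) best = size;
  }
  return best;
}
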