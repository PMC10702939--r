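#include <Rcpp.h>
using namespace Rcpp;

// Deterministic k-nearest-neighbour vote given a distance matrix.
//
// `dist` is train-rows x queries (column-major, so one query's distances
// are contiguous). Tie rules: equal distances resolve by training-row
// order; an even vote split resolves to the nearest neighbour's label.
// [[Rcpp::export(name = ".knn_vote_cpp")]]
IntegerVector knn_vote_cpp(NumericMatrix dist, IntegerVector labels, int k) {
  const int nt = dist.nrow(), nq = dist.ncol();
  const double *pd = REAL(dist);
  const int *plab = INTEGER(labels);
  IntegerVector out(nq);
  std::vector<char> used(nt);
  std::vector<int> picked(k);
  for (int q = 0; q < nq; ++q) {
    const double *col = pd + (size_t)q * nt;
    std::fill(used.begin(), used.end(), 0);
    for (int s = 0; s < k; ++s) {       // O(n k) keeps tie-breaking explicit
      int best = -1;
      double bd = 0;
      for (int i = 0; i < nt; ++i) {
        if (used[i]) continue;
        if (best < 0 || col[i] < bd) { best = i; bd = col[i]; }
      }
      used[best] = 1;
      picked[s] = best;
    }
    int votes1 = 0;
    for (int s = 0; s < k; ++s) votes1 += (plab[picked[s]] == 1);
    if (2 * votes1 > k) out[q] = 1;
    else if (2 * votes1 < k) out[q] = 0;
    else out[q] = plab[picked[0]];
  }
  return out;
}
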