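// Brute-force nearest-neighbor search used by the convergence test and the
// Kullback-Leibler ensemble distance. Self is excluded; exact ties (which
// arise from duplicated particles after resampling) are broken uniformly at
// random using R's RNG so the choice is reproducible under set.seed().
//
// When the nearest distance is exactly zero the query point belongs to a
// group of identical particles; the copies are exchangeable, so the tie
// group includes the query itself and the reported neighbor is drawn
// uniformly over all copies. This keeps the run/cell-identity statistics
// unbiased when whole particles are duplicated (e.g. a permuted copy of a
// run must look convergent, not maximally divergent).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Returns the 1-based index of each row's nearest neighbor in X (n x d).
// [[Rcpp::export]]
IntegerVector nn_index_cpp(NumericMatrix X) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 2) stop("need at least 2 points");
  IntegerVector out(n);
  std::vector<int> ties;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    ties.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - X(j, k);
        d2 += diff * diff;
      }
      if (d2 < best * (1.0 - 1e-12)) {
        best = d2;
        ties.clear();
        ties.push_back(j);
      } else if (d2 <= best * (1.0 + 1e-12) ||
                 (best == 0.0 && d2 == 0.0)) {
        if (d2 < best) best = d2;
        ties.push_back(j);
      }
    }
    if (best == 0.0) ties.push_back(i);   // exchangeable duplicate group
    int pick = ties[0];
    if (ties.size() > 1)
      pick = ties[(int)std::floor(unif_rand() * ties.size()) % ties.size()];
    out[i] = pick + 1;
  }
  return out;
}

// For each row, the probability that its nearest neighbor shares its
// identity, averaging uniformly over exact ties (the query joins its own
// zero-distance duplicate group). Deterministic: summing gives the expected
// same-identity count under the uniform tie-break, which is exact for the
// degenerate all-duplicates case and identical to the hard count when
// nearest neighbors are unique.
// [[Rcpp::export]]
NumericVector nn_same_prob_cpp(NumericMatrix X, IntegerVector ids) {
  const int n = X.nrow(), d = X.ncol();
  if (n < 2) stop("need at least 2 points");
  if (ids.size() != n) stop("ids must match rows");
  NumericVector out(n);
  std::vector<int> ties;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    ties.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - X(j, k);
        d2 += diff * diff;
      }
      if (d2 < best * (1.0 - 1e-12)) {
        best = d2;
        ties.clear();
        ties.push_back(j);
      } else if (d2 <= best * (1.0 + 1e-12) ||
                 (best == 0.0 && d2 == 0.0)) {
        if (d2 < best) best = d2;
        ties.push_back(j);
      }
    }
    if (best == 0.0) ties.push_back(i);
    int same = 0;
    for (size_t t = 0; t < ties.size(); ++t)
      if (ids[ties[t]] == ids[i]) ++same;
    out[i] = (double)same / (double)ties.size();
  }
  return out;
}
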