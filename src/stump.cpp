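#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exhaustive best regression stump for a residual vector r over the columns
// of X. Candidate thresholds are the midpoints between consecutive distinct
// sorted values of each column; the split maximising the least-squares
// improvement w1*w2/(w1+w2) * (g1-g2)^2 wins, with ties broken by lowest
// column index then lowest threshold (columns and thresholds are scanned in
// ascending order and only a strictly larger improvement replaces the
// incumbent). Returns feature = 0 when no column admits a valid split.
// [[Rcpp::export(name = ".cpp_best_stump")]]
List cpp_best_stump(NumericMatrix X, NumericVector r) {
  const int M = X.nrow();
  const int Q = X.ncol();
  if (r.size() != M) stop("length of residuals must match rows of X");

  double rsum = 0.0;
  for (int i = 0; i < M; ++i) rsum += r[i];
  const double rmean = (M > 0) ? rsum / M : 0.0;

  int best_col = 0;  // 1-based; 0 = degenerate
  double best_imp = -1.0, best_thr = NA_REAL;
  double best_g1 = rmean, best_g2 = rmean;

  std::vector<int> ord(M);
  for (int q = 0; q < Q; ++q) {
    NumericMatrix::Column x = X(_, q);
    for (int i = 0; i < M; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return x[a] < x[b]; });
    double lsum = 0.0;
    for (int i = 0; i < M - 1; ++i) {
      lsum += r[ord[i]];
      if (x[ord[i + 1]] == x[ord[i]]) continue;  // not between distinct values
      const double w1 = i + 1;
      const double w2 = M - i - 1;
      const double g1 = lsum / w1;
      const double g2 = (rsum - lsum) / w2;
      const double d = g1 - g2;
      const double imp = (w1 * w2 / (w1 + w2)) * d * d;
      if (imp > best_imp) {
        best_imp = imp;
        best_col = q + 1;
        best_thr = (x[ord[i]] + x[ord[i + 1]]) / 2.0;
        best_g1 = g1;
        best_g2 = g2;
      }
    }
  }

  if (best_col == 0) best_imp = 0.0;  // every column constant
  return List::create(_["feature"] = best_col, _["threshold"] = best_thr,
                      _["gamma_left"] = best_g1, _["gamma_right"] = best_g2,
                      _["improvement"] = best_imp);
}
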