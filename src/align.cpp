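#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Needleman-Wunsch global alignment score of two force profiles under the
// bounded match/mismatch scoring: M = 1 - |dF|/F_scoring when |dF| < F_scoring,
// otherwise -|dF|/F_scoring. Linear gap penalty (0 by default upstream).
// [[Rcpp::export]]
double nw_align_score(NumericVector fa, NumericVector fb,
                      double f_scoring, double gap_penalty) {
  const int n = fa.size(), m = fb.size();
  if (n == 0 || m == 0) stop("empty trace in alignment");
  std::vector<double> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap_penalty;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap_penalty;
    const double a = fa[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double diff = std::fabs(a - fb[j - 1]);
      const double match =
          (diff < f_scoring) ? 1.0 - diff / f_scoring : -diff / f_scoring;
      double best = prev[j - 1] + match;
      const double up = prev[j] + gap_penalty;
      if (up > best) best = up;
      const double left = cur[j - 1] + gap_penalty;
      if (left > best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
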