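#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive circular arc scan used by CBS: over all arcs (i, j] with
// 0 <= i < j <= n, compute the pooled two-sample t statistic between the
// arc and its complement and return the arc maximizing |t|.  Arcs and
// complements shorter than min_width are skipped.  Zero pooled variance
// with distinct means yields t = +/-Inf (a forced split on noiseless data).
// [[Rcpp::export]]
List cbs_max_arc(NumericVector x, int min_width) {
  int n = x.size();
  std::vector<double> S(n + 1, 0.0), S2(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    S[k + 1] = S[k] + x[k];
    S2[k + 1] = S2[k] + x[k] * x[k];
  }
  double best = -1.0;      // best |t|
  double best_t = NA_REAL;
  int best_i = -1, best_j = -1;
  if (n >= 2 * min_width) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j <= n; ++j) {
        int n1 = j - i, n2 = n - n1;
        if (n1 < min_width || n2 < min_width) continue;
        double m1 = (S[j] - S[i]) / n1;
        double m2 = (S[n] - S[j] + S[i]) / n2;
        double ss1 = (S2[j] - S2[i]) - n1 * m1 * m1;
        double ss2 = (S2[n] - S2[j] + S2[i]) - n2 * m2 * m2;
        double s2 = (ss1 + ss2) / (n - 2);
        double t, at;
        if (s2 <= 0.0) {
          if (m1 == m2) { t = 0.0; at = 0.0; }
          else { t = (m1 > m2) ? R_PosInf : R_NegInf; at = R_PosInf; }
        } else {
          t = (m1 - m2) / std::sqrt(s2 * (1.0 / n1 + 1.0 / n2));
          at = std::fabs(t);
        }
        if (at > best) {
          best = at;
          best_t = t;
          best_i = i;
          best_j = j;
        }
      }
    }
  }
  return List::create(_["i"] = best_i, _["j"] = best_j, _["t"] = best_t,
                      _["abs_t"] = (best_i < 0) ? NA_REAL : best);
}

// Max |t| only, for permutation replicates.
// [[Rcpp::export]]
double cbs_max_abs_t(NumericVector x, int min_width) {
  List res = cbs_max_arc(x, min_width);
  return as<double>(res["abs_t"]);
}
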