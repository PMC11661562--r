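#include <Rcpp.h>
using namespace Rcpp;

// Standardized two-sample log-rank statistic |O - E| / sqrt(V) for every
// candidate cutpoint of one numeric covariate within a tree node.
//
// `y` must be sorted ascending with `delta` and `x` in the same order;
// `cuts` ascending. A cut is invalid (score -Inf) when a child violates the
// node-size constraint, a child holds fewer than `min_events` unique event
// times, or the log-rank variance is zero.
// [[Rcpp::export]]
NumericVector lr_all_cuts_cpp(NumericVector y, IntegerVector delta,
                              NumericVector x, NumericVector cuts,
                              int min_node, int min_events) {
  int n = y.size(), K = cuts.size();
  NumericVector out(K, R_NegInf);
  for (int k = 0; k < K; ++k) {
    double c = cuts[k];
    int nL = 0;
    for (int i = 0; i < n; ++i) if (x[i] <= c) ++nL;
    if (nL < min_node || n - nL < min_node) continue;
    double num = 0.0, var = 0.0;
    int evL = 0, evR = 0;
    int atRisk = 0, atRisk1 = 0;
    int i = n - 1;
    while (i >= 0) {
      int j = i, d = 0, d1 = 0;
      while (j >= 0 && y[j] == y[i]) {
        ++atRisk;
        bool left = (x[j] <= c);
        if (left) ++atRisk1;
        if (delta[j] == 1) { ++d; if (left) ++d1; }
        --j;
      }
      if (d > 0) {
        double Y = atRisk, Y1 = atRisk1;
        num += d1 - d * Y1 / Y;
        if (atRisk > 1)
          var += d * (Y1 / Y) * (1.0 - Y1 / Y) * (Y - d) / (Y - 1.0);
        if (d1 > 0) ++evL;
        if (d - d1 > 0) ++evR;
      }
      i = j;
    }
    if (evL < min_events || evR < min_events || var <= 0.0) continue;
    out[k] = std::fabs(num) / std::sqrt(var);
  }
  return out;
}
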