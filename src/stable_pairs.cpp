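#include <Rcpp.h>
using namespace Rcpp;

// Streaming stable-pair scan. Rows of x must already be in canonical
// (sorted gene-id) order; only pairs whose winning ordering fraction
// strictly exceeds `threshold` are materialized, so a 20k-gene universe
// never allocates the ~2e8 candidate pair records.
//
// Ties (x(i,s) == x(j,s)) count in the denominator but in neither
// direction's numerator.
//
// Returns 1-based row indices, direction +1 (gene i > gene j) or -1
// (gene i < gene j), and the winning support fraction.
// [[Rcpp::export]]
List stable_pairs_scan(NumericMatrix x, double threshold) {
  const int g = x.nrow(), n = x.ncol();
  std::vector<int> pi, pj, dir;
  std::vector<double> sup;
  for (int i = 0; i < g - 1; ++i) {
    for (int j = i + 1; j < g; ++j) {
      int gt = 0, lt = 0;
      for (int s = 0; s < n; ++s) {
        const double a = x(i, s), b = x(j, s);
        if (a > b) ++gt; else if (a < b) ++lt;
      }
      const double fgt = (double)gt / n, flt = (double)lt / n;
      if (fgt > threshold) {
        pi.push_back(i + 1); pj.push_back(j + 1);
        dir.push_back(1); sup.push_back(fgt);
      } else if (flt > threshold) {
        pi.push_back(i + 1); pj.push_back(j + 1);
        dir.push_back(-1); sup.push_back(flt);
      }
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["i"] = pi, _["j"] = pj,
                      _["dir"] = dir, _["support"] = sup);
}
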