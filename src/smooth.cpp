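#include <Rcpp.h>
using namespace Rcpp;

// Tricube-distance-weighted local mean (degree-0 local regression).
// For each position p_i the fitted value is the weighted mean of raw values
// at positions within +/- halfwidth, with weights (1 - (d/h)^3)^3 and the
// centre point receiving weight 1. Windows truncate at the ends of the
// track, so the fit is always a convex combination of in-window raw values.
// Positions must be sorted ascending.
// [[Rcpp::export]]
NumericVector tricube_window_mean(NumericVector pos, NumericVector raw,
                                  double halfwidth) {
  int n = pos.size();
  if (raw.size() != n) stop("pos and raw must have equal length");
  if (halfwidth < 0) stop("halfwidth must be non-negative");
  NumericVector out(n);
  int lo = 0, hi = 0;
  for (int i = 0; i < n; ++i) {
    while (lo < n && pos[lo] < pos[i] - halfwidth) ++lo;
    if (hi < i) hi = i;
    while (hi + 1 < n && pos[hi + 1] <= pos[i] + halfwidth) ++hi;
    double sw = 0.0, swx = 0.0;
    for (int j = lo; j <= hi; ++j) {
      double w;
      if (halfwidth == 0.0) {
        w = (pos[j] == pos[i]) ? 1.0 : 0.0;
      } else {
        double u = std::abs(pos[j] - pos[i]) / halfwidth;
        if (u > 1.0) continue;
        double t = 1.0 - u * u * u;
        w = t * t * t;
      }
      sw += w;
      swx += w * raw[j];
    }
    out[i] = (sw > 0.0) ? swx / sw : raw[i];
  }
  return out;
}
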