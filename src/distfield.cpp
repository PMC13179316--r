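#include <Rcpp.h>
using namespace Rcpp;

// Squared Euclidean distance from every pixel (0-based centers, x = column,
// y = row) to the nearest of a set of points. Brute force over centers is
// exact and fast enough for the few hundred vessel centers of a slide.
// [[Rcpp::export(name = ".min_dist2_field_cpp")]]
NumericMatrix min_dist2_field_cpp(int nr, int nc, NumericMatrix centers) {
  NumericMatrix out(nr, nc);
  int k = centers.nrow();
  std::vector<double> cx(k), cy(k);
  for (int i = 0; i < k; ++i) {
    cx[i] = centers(i, 0);
    cy[i] = centers(i, 1);
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double best = R_PosInf;
      for (int i = 0; i < k; ++i) {
        double dx = c - cx[i];
        double dy = r - cy[i];
        double d = dx * dx + dy * dy;
        if (d < best) best = d;
      }
      out(r, c) = best;
    }
  }
  return out;
}
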