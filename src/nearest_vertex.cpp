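#include <Rcpp.h>
using namespace Rcpp;

// Brute-force nearest-vertex search. Vertices are ordered left hemisphere
// first, so keeping the first strict minimum implements the documented
// tie-break (lowest vertex id, left before right). At the package's scale
// (tens of thousands of points vs ~10^4 vertices) this is faster to run
// than a tree is to build, and it is exactly auditable.
// [[Rcpp::export]]
List nearest_vertex_cpp(NumericMatrix points, NumericMatrix vertices) {
  const int n = points.nrow(), m = vertices.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  std::vector<double> vx(m), vy(m), vz(m);
  for (int j = 0; j < m; ++j) {
    vx[j] = vertices(j, 0); vy[j] = vertices(j, 1); vz[j] = vertices(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double best = R_PosInf;
    int bestj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = px - vx[j], dy = py - vy[j], dz = pz - vz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bestj = j; }
    }
    idx[i] = bestj + 1;            // 1-based
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
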