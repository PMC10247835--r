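#include <Rcpp.h>
using namespace Rcpp;

// Even-odd (crossing-number) point-in-ring test. The ring is an open list of
// vertices (closure implicit). Points exactly on the boundary may land on
// either side; callers needing boundary semantics must handle that themselves.
// [[Rcpp::export(name = ".pip_ring")]]
LogicalVector pip_ring(NumericVector px, NumericVector py,
                       NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  LogicalVector inside(n);
  for (int i = 0; i < n; ++i) {
    const double x = px[i], y = py[i];
    bool in = false;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      if (((vy[j] > y) != (vy[k] > y)) &&
          (x < (vx[k] - vx[j]) * (y - vy[j]) / (vy[k] - vy[j]) + vx[j]))
        in = !in;
    }
    inside[i] = in;
  }
  return inside;
}

// Number of times the ray from (cx, cy) in direction theta (radians) crosses
// the ring boundary at radius > rmin. Used by the ray-sampling angular oracle.
// [[Rcpp::export(name = ".ray_crossings")]]
IntegerVector ray_crossings(double cx, double cy, NumericVector theta,
                            NumericVector vx, NumericVector vy,
                            double rmin = 1e-12) {
  const int n = theta.size(), m = vx.size();
  IntegerVector cnt(n);
  for (int i = 0; i < n; ++i) {
    const double c = std::cos(theta[i]), s = std::sin(theta[i]);
    int k = 0;
    for (int j = 0, jp = m - 1; j < m; jp = j++) {
      const double x1 = vx[jp] - cx, y1 = vy[jp] - cy;
      const double x2 = vx[j] - cx, y2 = vy[j] - cy;
      const double p1 = x1 * s - y1 * c;  // perpendicular offset from ray line
      const double p2 = x2 * s - y2 * c;
      if ((p1 > 0.0) == (p2 > 0.0)) continue;  // does not straddle the ray line
      const double t = p1 / (p1 - p2);
      const double r = (x1 + t * (x2 - x1)) * c + (y1 + t * (y2 - y1)) * s;
      if (r > rmin) ++k;
    }
    cnt[i] = k;
  }
  return cnt;
}
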