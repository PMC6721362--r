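#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// An integer offset (dx, dy) from a candidate center lies on the rasterized
// boundary of the ellipse (a, b, tau) when the radial distance from the
// center to the ellipse along the offset direction differs from |(dx, dy)|
// by at most tol pixels. For a = b = r this reduces to | |(dx,dy)| - r |
// <= tol; tol sets the vote-band width of the accumulator.
static inline bool on_boundary(double dx, double dy, double a, double b,
                               double ct, double st, double tol) {
  if (a == b) {
    // circle: compare squared distances, exact for integer offsets
    double dd = dx * dx + dy * dy;
    if (dd == 0.0) return false;
    double lo = a > tol ? (a - tol) * (a - tol) : 0.0;
    return dd >= lo && dd <= (a + tol) * (a + tol);
  }
  double d = std::sqrt(dx * dx + dy * dy);
  if (d == 0.0) return false;
  double u = dx * ct + dy * st;
  double v = -dx * st + dy * ct;
  double s = std::sqrt((u / a) * (u / a) + (v / b) * (v / b));
  double rho = d / s;  // boundary distance along this direction
  return std::fabs(d - rho) <= tol;
}

// Hough voting over (a, b, tau) triplets. Edge pixels vote for all integer
// centers whose parameterized ellipse passes through them. Returns the
// global accumulator peak; ties are broken by smallest y, then x, then
// earliest triplet (grids are supplied in ascending parameter order).
// [[Rcpp::export]]
List hough_vote(IntegerVector ex, IntegerVector ey,
                NumericVector a, NumericVector b, NumericVector tau,
                int width, int height, double tol) {
  const int ne = ex.size(), nt = a.size();
  if (ne == 0) stop("no edge pixels to vote with");
  std::vector<int> acc((size_t)width * height);
  int best_v = -1, best_x = 0, best_y = 0, best_t = -1;

  std::vector<int> offx, offy;
  for (int t = 0; t < nt; ++t) {
    const double at = a[t], bt = b[t];
    const double ct = std::cos(tau[t]), st = std::sin(tau[t]);
    const int R = (int)std::ceil(std::max(at, bt) + tol + 0.5);
    offx.clear(); offy.clear();
    for (int dy = -R; dy <= R; ++dy)
      for (int dx = -R; dx <= R; ++dx)
        if (on_boundary(dx, dy, at, bt, ct, st, tol)) {
          offx.push_back(dx); offy.push_back(dy);
        }
    std::fill(acc.begin(), acc.end(), 0);
    const int no = (int)offx.size();
    for (int i = 0; i < ne; ++i) {
      const int px = ex[i], py = ey[i];
      for (int k = 0; k < no; ++k) {
        const int cx = px - offx[k], cy = py - offy[k];
        if (cx >= 1 && cx <= width && cy >= 1 && cy <= height)
          ++acc[(size_t)(cx - 1) * height + (cy - 1)];
      }
    }
    for (int y = 1; y <= height; ++y)
      for (int x = 1; x <= width; ++x) {
        const int v = acc[(size_t)(x - 1) * height + (y - 1)];
        if (v > best_v ||
            (v == best_v && (y < best_y ||
                             (y == best_y && x < best_x)))) {
          best_v = v; best_x = x; best_y = y; best_t = t;
        }
      }
  }
  return List::create(_["cx"] = best_x, _["cy"] = best_y,
                      _["votes"] = best_v, _["triplet"] = best_t + 1);
}
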