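// Exact area of overlap between two triangle soups in the plane, via
// Sutherland-Hodgman clipping of each triangle pair (convex-convex clip).
// Used for Dice/Jaccard areas after ear-clipping triangulation of the
// simple polygons being compared.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct P2 { double x, y; };

static inline double cross(const P2& o, const P2& a, const P2& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

static double polyArea(const std::vector<P2>& p) {
  double a = 0;
  int n = (int)p.size();
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    a += p[i].x * p[j].y - p[j].x * p[i].y;
  }
  return 0.5 * a;
}

// clip convex polygon by half-plane left of (a -> b)
static void clipHalf(const std::vector<P2>& in, const P2& a, const P2& b,
                     std::vector<P2>& out) {
  out.clear();
  int n = (int)in.size();
  for (int i = 0; i < n; ++i) {
    const P2& cur = in[i];
    const P2& nxt = in[(i + 1) % n];
    double dc = cross(a, b, cur), dn = cross(a, b, nxt);
    if (dc >= 0) out.push_back(cur);
    if ((dc > 0 && dn < 0) || (dc < 0 && dn > 0)) {
      double t = dc / (dc - dn);
      P2 q; q.x = cur.x + t * (nxt.x - cur.x); q.y = cur.y + t * (nxt.y - cur.y);
      out.push_back(q);
    }
  }
}

}  // namespace

// A, B: n x 6 matrices (x1,y1,x2,y2,x3,y3), any vertex order per triangle.
// [[Rcpp::export]]
double cpp_tri_overlap_area(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  std::vector<double> bx0(nb), bx1(nb), by0(nb), by1(nb);
  for (int j = 0; j < nb; ++j) {
    bx0[j] = std::min(B(j,0), std::min(B(j,2), B(j,4)));
    bx1[j] = std::max(B(j,0), std::max(B(j,2), B(j,4)));
    by0[j] = std::min(B(j,1), std::min(B(j,3), B(j,5)));
    by1[j] = std::max(B(j,1), std::max(B(j,3), B(j,5)));
  }
  double total = 0;
  std::vector<P2> poly, tmp;
  for (int i = 0; i < na; ++i) {
    P2 t1[3] = {{A(i,0),A(i,1)},{A(i,2),A(i,3)},{A(i,4),A(i,5)}};
    if (cross(t1[0], t1[1], t1[2]) < 0) std::swap(t1[1], t1[2]);  // CCW
    double ax0 = std::min(t1[0].x, std::min(t1[1].x, t1[2].x));
    double ax1 = std::max(t1[0].x, std::max(t1[1].x, t1[2].x));
    double ay0 = std::min(t1[0].y, std::min(t1[1].y, t1[2].y));
    double ay1 = std::max(t1[0].y, std::max(t1[1].y, t1[2].y));
    for (int j = 0; j < nb; ++j) {
      if (bx0[j] > ax1 || bx1[j] < ax0 || by0[j] > ay1 || by1[j] < ay0)
        continue;
      P2 t2[3] = {{B(j,0),B(j,1)},{B(j,2),B(j,3)},{B(j,4),B(j,5)}};
      if (cross(t2[0], t2[1], t2[2]) < 0) std::swap(t2[1], t2[2]);
      poly.assign(t1, t1 + 3);
      for (int e = 0; e < 3 && !poly.empty(); ++e) {
        clipHalf(poly, t2[e], t2[(e + 1) % 3], tmp);
        poly.swap(tmp);
      }
      if (poly.size() >= 3) total += std::fabs(polyArea(poly));
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return total;
}
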