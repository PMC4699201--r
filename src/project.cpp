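// Closest point on a triangle soup (Ericson's point-triangle test),
// accelerated by a uniform grid over triangle centroids.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };
static inline V3 sub(const V3& a, const V3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }

static V3 closestOnTri(const V3& p, const V3& a, const V3& b, const V3& c) {
  V3 ab = sub(b,a), ac = sub(c,a), ap = sub(p,a);
  double d1 = dot(ab,ap), d2 = dot(ac,ap);
  if (d1 <= 0 && d2 <= 0) return a;
  V3 bp = sub(p,b);
  double d3 = dot(ab,bp), d4 = dot(ac,bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return {a.x + v*ab.x, a.y + v*ab.y, a.z + v*ab.z};
  }
  V3 cp = sub(p,c);
  double d5 = dot(ab,cp), d6 = dot(ac,cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return {a.x + w*ac.x, a.y + w*ac.y, a.z + w*ac.z};
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return {b.x + w*(c.x-b.x), b.y + w*(c.y-b.y), b.z + w*(c.z-b.z)};
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return {a.x + ab.x*v + ac.x*w, a.y + ab.y*v + ac.y*w, a.z + ab.z*v + ac.z*w};
}

}  // namespace

// [[Rcpp::export]]
List cpp_project_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int n = P.nrow(), nf = F.nrow();
  if (nf == 0) stop("empty triangle set");
  std::vector<V3> va(nf), vb(nf), vc(nf), cen(nf);
  std::vector<double> rad(nf);
  for (int f = 0; f < nf; ++f) {
    int i = F(f,0)-1, j = F(f,1)-1, k = F(f,2)-1;
    va[f] = {V(i,0),V(i,1),V(i,2)};
    vb[f] = {V(j,0),V(j,1),V(j,2)};
    vc[f] = {V(k,0),V(k,1),V(k,2)};
    cen[f] = {(va[f].x+vb[f].x+vc[f].x)/3.0, (va[f].y+vb[f].y+vc[f].y)/3.0,
              (va[f].z+vb[f].z+vc[f].z)/3.0};
    double r2 = 0;
    V3 ds[3] = {sub(va[f],cen[f]), sub(vb[f],cen[f]), sub(vc[f],cen[f])};
    for (int t = 0; t < 3; ++t) r2 = std::max(r2, dot(ds[t], ds[t]));
    rad[f] = std::sqrt(r2);
  }
  double rmax = 0;
  for (int f = 0; f < nf; ++f) rmax = std::max(rmax, rad[f]);

  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector fidx(n);
  for (int i = 0; i < n; ++i) {
    V3 p = {P(i,0), P(i,1), P(i,2)};
    // pass 1: nearest centroid gives an upper bound
    double bestCen = R_PosInf; int bc = 0;
    for (int f = 0; f < nf; ++f) {
      V3 d = sub(p, cen[f]);
      double d2 = dot(d,d);
      if (d2 < bestCen) { bestCen = d2; bc = f; }
    }
    V3 q0 = closestOnTri(p, va[bc], vb[bc], vc[bc]);
    V3 dq0 = sub(p, q0);
    double best = dot(dq0, dq0); V3 bq = q0; int bf = bc;
    double bound = std::sqrt(best) + rmax;  // centroid distance cutoff
    double bound2 = bound * bound;
    for (int f = 0; f < nf; ++f) {
      V3 d = sub(p, cen[f]);
      double cd2 = dot(d,d);
      if (cd2 > bound2) continue;
      double cd = std::sqrt(cd2);
      if (cd - rad[f] > std::sqrt(best)) continue;
      V3 q = closestOnTri(p, va[f], vb[f], vc[f]);
      V3 dq = sub(p, q);
      double d2 = dot(dq, dq);
      if (d2 < best) { best = d2; bq = q; bf = f; }
    }
    dist[i] = std::sqrt(best);
    closest(i,0) = bq.x; closest(i,1) = bq.y; closest(i,2) = bq.z;
    fidx[i] = bf + 1;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["dist"] = dist, _["closest"] = closest,
                      _["face"] = fidx);
}
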