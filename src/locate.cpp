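// Locate query points inside a tetrahedral mesh (barycentric test, with a
// coarse per-tet bounding-box prefilter). Returns 1-based tet index or 0.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_locate_points(NumericMatrix V, IntegerMatrix T,
                                NumericMatrix Q, double tol = 1e-9) {
  int nt = T.nrow(), nq = Q.nrow();
  std::vector<double> bx0(nt), bx1(nt), by0(nt), by1(nt), bz0(nt), bz1(nt);
  for (int t = 0; t < nt; ++t) {
    double x0=R_PosInf,x1=R_NegInf,y0=R_PosInf,y1=R_NegInf,z0=R_PosInf,z1=R_NegInf;
    for (int c = 0; c < 4; ++c) {
      int v = T(t,c)-1;
      x0=std::min(x0,V(v,0)); x1=std::max(x1,V(v,0));
      y0=std::min(y0,V(v,1)); y1=std::max(y1,V(v,1));
      z0=std::min(z0,V(v,2)); z1=std::max(z1,V(v,2));
    }
    bx0[t]=x0; bx1[t]=x1; by0[t]=y0; by1[t]=y1; bz0[t]=z0; bz1[t]=z1;
  }
  IntegerVector out(nq);
  for (int qi = 0; qi < nq; ++qi) {
    double px = Q(qi,0), py = Q(qi,1), pz = Q(qi,2);
    int found = 0;
    for (int t = 0; t < nt && !found; ++t) {
      if (px < bx0[t]-tol || px > bx1[t]+tol || py < by0[t]-tol ||
          py > by1[t]+tol || pz < bz0[t]-tol || pz > bz1[t]+tol)
        continue;
      int a=T(t,0)-1, b=T(t,1)-1, c=T(t,2)-1, d=T(t,3)-1;
      double m[9] = {V(b,0)-V(a,0), V(c,0)-V(a,0), V(d,0)-V(a,0),
                     V(b,1)-V(a,1), V(c,1)-V(a,1), V(d,1)-V(a,1),
                     V(b,2)-V(a,2), V(c,2)-V(a,2), V(d,2)-V(a,2)};
      double det = m[0]*(m[4]*m[8]-m[5]*m[7]) - m[1]*(m[3]*m[8]-m[5]*m[6])
                 + m[2]*(m[3]*m[7]-m[4]*m[6]);
      if (std::fabs(det) < 1e-300) continue;
      double rx = px-V(a,0), ry = py-V(a,1), rz = pz-V(a,2);
      // adjugate solve: lambda = M^{-1} r
      double l1 = ((m[4]*m[8]-m[5]*m[7])*rx + (m[2]*m[7]-m[1]*m[8])*ry +
                   (m[1]*m[5]-m[2]*m[4])*rz) / det;
      double l2 = ((m[5]*m[6]-m[3]*m[8])*rx + (m[0]*m[8]-m[2]*m[6])*ry +
                   (m[2]*m[3]-m[0]*m[5])*rz) / det;
      double l3 = ((m[3]*m[7]-m[4]*m[6])*rx + (m[1]*m[6]-m[0]*m[7])*ry +
                   (m[0]*m[4]-m[1]*m[3])*rz) / det;
      double l0 = 1.0 - l1 - l2 - l3;
      double e = -1e-10;
      if (l0 >= e && l1 >= e && l2 >= e && l3 >= e) found = t + 1;
    }
    out[qi] = found;
    if ((qi & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
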