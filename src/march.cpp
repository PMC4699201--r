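// Marching tetrahedra over a regular grid (Kuhn 6-tet cube decomposition,
// translation-consistent so the extracted zero level set is watertight).
// Inside convention: f < 0. Triangles oriented with normals pointing
// outward (toward f > 0).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };

// the 6 Kuhn tets of the unit cube, corners indexed bit-wise (x + 2y + 4z)
static const int KUHN[6][4] = {
  {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
  {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, int nx, int ny, int nz,
                       NumericVector origin, NumericVector spacing) {
  auto gidx = [&](int i, int j, int k) -> std::int64_t {
    return ((std::int64_t)k * ny + j) * nx + i;
  };
  auto gval = [&](std::int64_t g) -> double { return vals[(R_xlen_t)g]; };
  auto gpos = [&](std::int64_t g) -> V3 {
    int i = (int)(g % nx); std::int64_t r = g / nx;
    int j = (int)(r % ny); int k = (int)(r / ny);
    return {origin[0] + spacing[0] * i, origin[1] + spacing[1] * j,
            origin[2] + spacing[2] * k};
  };

  std::unordered_map<std::uint64_t, int> edgeVert;
  std::vector<double> VX, VY, VZ;
  std::vector<int> F;

  auto edgePoint = [&](std::int64_t g1, std::int64_t g2) -> int {
    if (g1 > g2) std::swap(g1, g2);
    std::uint64_t key = ((std::uint64_t)g1 << 32) ^ (std::uint64_t)g2;
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double f1 = gval(g1), f2 = gval(g2);
    double t = f1 / (f1 - f2);
    if (!std::isfinite(t)) t = 0.5;
    t = std::min(1.0 - 1e-6, std::max(1e-6, t));
    V3 p1 = gpos(g1), p2 = gpos(g2);
    int id = (int)VX.size();
    VX.push_back(p1.x + t * (p2.x - p1.x));
    VY.push_back(p1.y + t * (p2.y - p1.y));
    VZ.push_back(p1.z + t * (p2.z - p1.z));
    edgeVert[key] = id;
    return id;
  };

  auto addTri = [&](int a, int b, int c, const V3& towardPos) {
    // orient so normal . towardPos > 0
    V3 pa = {VX[a], VY[a], VZ[a]}, pb = {VX[b], VY[b], VZ[b]},
       pc = {VX[c], VY[c], VZ[c]};
    double ux = pb.x-pa.x, uy = pb.y-pa.y, uz = pb.z-pa.z;
    double vx = pc.x-pa.x, vy = pc.y-pa.y, vz = pc.z-pa.z;
    double nxv = uy*vz - uz*vy, nyv = uz*vx - ux*vz, nzv = ux*vy - uy*vx;
    double cxv = (pa.x+pb.x+pc.x)/3.0, cyv = (pa.y+pb.y+pc.y)/3.0,
           czv = (pa.z+pb.z+pc.z)/3.0;
    double d = nxv*(towardPos.x-cxv) + nyv*(towardPos.y-cyv) +
               nzv*(towardPos.z-czv);
    if (d >= 0) { F.push_back(a); F.push_back(b); F.push_back(c); }
    else        { F.push_back(a); F.push_back(c); F.push_back(b); }
  };

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        std::int64_t corn[8];
        for (int b = 0; b < 8; ++b)
          corn[b] = gidx(i + (b & 1), j + ((b >> 1) & 1), k + ((b >> 2) & 1));
        for (int t = 0; t < 6; ++t) {
          std::int64_t tv[4];
          double tf[4];
          int inMask = 0;
          for (int q = 0; q < 4; ++q) {
            tv[q] = corn[KUHN[t][q]];
            tf[q] = gval(tv[q]);
            if (tf[q] < 0) inMask |= (1 << q);
          }
          if (inMask == 0 || inMask == 15) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int q = 0; q < 4; ++q)
            (tf[q] < 0 ? ins[ni++] : outs[no++]) = q;
          // centroid of the outside corners orients the triangles
          V3 pos = {0,0,0};
          for (int q = 0; q < no; ++q) {
            V3 p = gpos(tv[outs[q]]);
            pos.x += p.x / no; pos.y += p.y / no; pos.z += p.z / no;
          }
          if (ni == 1) {
            int a = edgePoint(tv[ins[0]], tv[outs[0]]);
            int b = edgePoint(tv[ins[0]], tv[outs[1]]);
            int c = edgePoint(tv[ins[0]], tv[outs[2]]);
            addTri(a, b, c, pos);
          } else if (ni == 3) {
            int a = edgePoint(tv[outs[0]], tv[ins[0]]);
            int b = edgePoint(tv[outs[0]], tv[ins[1]]);
            int c = edgePoint(tv[outs[0]], tv[ins[2]]);
            addTri(a, b, c, pos);
          } else {  // 2-2: quad split into two triangles
            int e00 = edgePoint(tv[ins[0]], tv[outs[0]]);
            int e01 = edgePoint(tv[ins[0]], tv[outs[1]]);
            int e10 = edgePoint(tv[ins[1]], tv[outs[0]]);
            int e11 = edgePoint(tv[ins[1]], tv[outs[1]]);
            addTri(e00, e01, e11, pos);
            addTri(e00, e11, e10, pos);
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  int nv = (int)VX.size(), nf2 = (int)F.size() / 3;
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) { Vm(i,0)=VX[i]; Vm(i,1)=VY[i]; Vm(i,2)=VZ[i]; }
  IntegerMatrix Fm(nf2, 3);
  for (int f = 0; f < nf2; ++f) {
    Fm(f,0) = F[3*f] + 1; Fm(f,1) = F[3*f+1] + 1; Fm(f,2) = F[3*f+2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}
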