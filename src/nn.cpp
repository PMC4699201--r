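// Nearest-neighbour queries against a fixed 3D point cloud via a uniform
// voxel grid (brute force below a size threshold). Ties broken by lowest
// reference index.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Grid {
  std::vector<int> cellStart, items;
  int nx, ny, nz;
  double ox, oy, oz, cell;

  void build(const NumericMatrix& R, double cellSize) {
    int m = R.nrow();
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < 3; ++j) {
        lo[j] = std::min(lo[j], R(i, j));
        hi[j] = std::max(hi[j], R(i, j));
      }
    cell = cellSize;
    ox = lo[0]; oy = lo[1]; oz = lo[2];
    nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / cell) + 1);
    ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / cell) + 1);
    nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / cell) + 1);
    std::vector<int> count((size_t)nx * ny * nz, 0);
    std::vector<int> ci(m);
    for (int i = 0; i < m; ++i) {
      int ix = std::min(nx - 1, std::max(0, (int)((R(i,0) - ox) / cell)));
      int iy = std::min(ny - 1, std::max(0, (int)((R(i,1) - oy) / cell)));
      int iz = std::min(nz - 1, std::max(0, (int)((R(i,2) - oz) / cell)));
      ci[i] = (ix * ny + iy) * nz + iz;
      count[ci[i]]++;
    }
    cellStart.assign(count.size() + 1, 0);
    for (size_t c = 0; c < count.size(); ++c)
      cellStart[c + 1] = cellStart[c] + count[c];
    items.resize(m);
    std::vector<int> cur(cellStart.begin(), cellStart.end() - 1);
    for (int i = 0; i < m; ++i) items[cur[ci[i]]++] = i;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix ref) {
  int n = query.nrow(), m = ref.nrow();
  if (m == 0) stop("empty reference cloud");
  NumericVector dist(n);
  IntegerVector idx(n);

  if (m <= 256) {
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf; int bi = -1;
      for (int j = 0; j < m; ++j) {
        double dx = query(i,0)-ref(j,0), dy = query(i,1)-ref(j,1),
               dz = query(i,2)-ref(j,2);
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) { best = d2; bi = j; }
      }
      dist[i] = std::sqrt(best); idx[i] = bi + 1;
    }
    return List::create(_["dist"] = dist, _["idx"] = idx);
  }

  // cell size targeting a few points per cell; robust to degenerate
  // (planar / collinear) clouds, with a hard cap on the number of cells
  double lo[3] = {R_PosInf,R_PosInf,R_PosInf}, hi[3] = {R_NegInf,R_NegInf,R_NegInf};
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < 3; ++j) {
      lo[j] = std::min(lo[j], ref(i,j)); hi[j] = std::max(hi[j], ref(i,j));
    }
  double span = std::max(hi[0]-lo[0], std::max(hi[1]-lo[1], hi[2]-lo[2]));
  if (span <= 0) span = 1.0;
  double cell = std::max(1e-9, 2.0 * span / std::cbrt((double)m));
  for (;;) {
    double ncell = 1;
    for (int j = 0; j < 3; ++j)
      ncell *= std::max(1.0, std::floor((hi[j]-lo[j]) / cell) + 1);
    if (ncell <= 8.0 * m + 1024) break;
    cell *= 2.0;
  }
  Grid g; g.build(ref, cell);

  const int RCAP = 24;  // beyond this shell radius, brute force the query
  for (int i = 0; i < n; ++i) {
    double qx = query(i,0), qy = query(i,1), qz = query(i,2);
    int cx = (int)std::floor((qx - g.ox) / g.cell);
    int cy = (int)std::floor((qy - g.oy) / g.cell);
    int cz = (int)std::floor((qz - g.oz) / g.cell);
    double best = R_PosInf; int bi = -1;
    bool done = false;
    for (int r = 0; r <= RCAP && !done; ++r) {
      // a point in shell r' > r is at least (r'-1)*cell away
      if (bi >= 0 && (double)(r - 1) * g.cell > 0 &&
          (double)(r - 1) * g.cell * (double)(r - 1) * g.cell > best) {
        done = true; break;
      }
      bool covered = (cx - r < 0 && cx + r >= g.nx && cy - r < 0 &&
                      cy + r >= g.ny && cz - r < 0 && cz + r >= g.nz);
      for (int ix = cx - r; ix <= cx + r; ++ix) {
        if (ix < 0 || ix >= g.nx) continue;
        for (int iy = cy - r; iy <= cy + r; ++iy) {
          if (iy < 0 || iy >= g.ny) continue;
          for (int iz = cz - r; iz <= cz + r; ++iz) {
            if (iz < 0 || iz >= g.nz) continue;
            int ch = std::max(std::abs(ix - cx),
                     std::max(std::abs(iy - cy), std::abs(iz - cz)));
            if (ch != r) continue;
            size_t c = ((size_t)ix * g.ny + iy) * g.nz + iz;
            for (int k = g.cellStart[c]; k < g.cellStart[c + 1]; ++k) {
              int j = g.items[k];
              double dx = qx-ref(j,0), dy = qy-ref(j,1), dz = qz-ref(j,2);
              double d2 = dx*dx + dy*dy + dz*dz;
              if (d2 < best || (d2 == best && j < bi)) { best = d2; bi = j; }
            }
          }
        }
      }
      if (covered && bi >= 0) done = true;
    }
    if (!done && bi < 0) {
      for (int j = 0; j < m; ++j) {
        double dx = qx-ref(j,0), dy = qy-ref(j,1), dz = qz-ref(j,2);
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best) { best = d2; bi = j; }
      }
    } else if (!done) {
      // candidate found but search radius capped: verify by widening via brute
      double safe = (double)(RCAP - 1) * g.cell;
      if (safe * safe <= best) {
        for (int j = 0; j < m; ++j) {
          double dx = qx-ref(j,0), dy = qy-ref(j,1), dz = qz-ref(j,2);
          double d2 = dx*dx + dy*dy + dz*dz;
          if (d2 < best || (d2 == best && j < bi)) { best = d2; bi = j; }
        }
      }
    }
    dist[i] = std::sqrt(best); idx[i] = bi + 1;
    if ((i & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["dist"] = dist, _["idx"] = idx);
}
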