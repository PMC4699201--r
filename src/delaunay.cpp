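// Incremental Bowyer-Watson Delaunay tetrahedralization.
//
// Points are perturbed internally by a tiny deterministic jitter (predicates
// only; reported vertices are the originals) so that co-spherical inputs --
// regular lattices, evenly resampled circular contours -- fall into general
// position. Predicates accumulate in long double.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tet {
  int v[4];   // vertex indices
  int nb[4];  // nb[i] = tet opposite v[i], -1 none
  bool alive;
};

static inline double orient3d(const double* a, const double* b,
                              const double* c, const double* d) {
  long double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  long double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  long double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  long double det = adx * (bdy * cdz - bdz * cdy)
                  - bdx * (ady * cdz - adz * cdy)
                  + cdx * (ady * bdz - adz * bdy);
  return (double)det;
}

// > 0 iff e strictly inside circumsphere of positively oriented (a,b,c,d)
static inline double insphere(const double* a, const double* b,
                              const double* c, const double* d,
                              const double* e) {
  long double aex = a[0] - e[0], aey = a[1] - e[1], aez = a[2] - e[2];
  long double bex = b[0] - e[0], bey = b[1] - e[1], bez = b[2] - e[2];
  long double cex = c[0] - e[0], cey = c[1] - e[1], cez = c[2] - e[2];
  long double dex = d[0] - e[0], dey = d[1] - e[1], dez = d[2] - e[2];

  long double ab = aex * bey - bex * aey;
  long double bc = bex * cey - cex * bey;
  long double cd = cex * dey - dex * cey;
  long double da = dex * aey - aex * dey;
  long double ac = aex * cey - cex * aey;
  long double bd = bex * dey - dex * bey;

  long double abc = aez * bc - bez * ac + cez * ab;
  long double bcd = bez * cd - cez * bd + dez * bc;
  long double cda = cez * da + dez * ac + aez * cd;
  long double dab = dez * ab + aez * bd + bez * da;

  long double alift = aex * aex + aey * aey + aez * aez;
  long double blift = bex * bex + bey * bey + bez * bez;
  long double clift = cex * cex + cey * cey + cez * cez;
  long double dlift = dex * dex + dey * dey + dez * dez;

  long double det = (dlift * abc - clift * dab) + (blift * cda - alift * bcd);
  return (double)det;
}

static inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline double u01(std::uint64_t h) {
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

struct DT {
  std::vector<double> P;  // jittered working coords, 3 per vertex
  std::vector<Tet> tets;
  int nreal;

  const double* pt(int i) const { return &P[3 * (size_t)i]; }

  // order face opposite corner i so that the inner vertex sees it positively
  void face_of(const Tet& t, int i, int f[3]) const {
    static const int others[4][3] = {{1,2,3},{0,2,3},{0,1,3},{0,1,2}};
    f[0] = t.v[others[i][0]];
    f[1] = t.v[others[i][1]];
    f[2] = t.v[others[i][2]];
    if (orient3d(pt(f[0]), pt(f[1]), pt(f[2]), pt(t.v[i])) < 0)
      std::swap(f[1], f[2]);
  }

  int walk(int start, const double* p, int max_steps) {
    int cur = start;
    for (int step = 0; step < max_steps; ++step) {
      const Tet& t = tets[cur];
      int f[3];
      bool moved = false;
      for (int i = 0; i < 4; ++i) {
        face_of(t, i, f);
        if (orient3d(pt(f[0]), pt(f[1]), pt(f[2]), p) < 0) {
          int nxt = t.nb[i];
          if (nxt >= 0) { cur = nxt; moved = true; break; }
        }
      }
      if (!moved) return cur;
    }
    // fallback: global scan
    for (size_t k = 0; k < tets.size(); ++k) {
      if (!tets[k].alive) continue;
      const Tet& t = tets[k];
      bool inside = true;
      int f[3];
      for (int i = 0; i < 4 && inside; ++i) {
        face_of(t, i, f);
        if (orient3d(pt(f[0]), pt(f[1]), pt(f[2]), p) < 0) inside = false;
      }
      if (inside) return (int)k;
    }
    return start;
  }

  bool conflicts(int ti, const double* p) const {
    const Tet& t = tets[ti];
    return insphere(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]), p) > 0;
  }

  void insert(int vid, int& hint) {
    const double* p = pt(vid);
    int t0 = walk(hint, p, 4096);

    // conflict region (BFS); t0 forced in even if insphere is borderline
    std::vector<int> bad;
    std::vector<char> inbad(tets.size(), 0);
    std::vector<int> stack;
    bad.push_back(t0); inbad[t0] = 1; stack.push_back(t0);
    while (!stack.empty()) {
      int ti = stack.back(); stack.pop_back();
      for (int i = 0; i < 4; ++i) {
        int nb = tets[ti].nb[i];
        if (nb >= 0 && !inbad[nb] && conflicts(nb, p)) {
          inbad[nb] = 1; bad.push_back(nb); stack.push_back(nb);
        }
      }
    }

    // cavity boundary faces; enforce star-shapedness by absorbing neighbours
    // whose boundary face is not positively visible from p
    struct BFace { int f[3]; int outside; };
    std::vector<BFace> bnd;
    for (;;) {
      bnd.clear();
      bool grew = false;
      for (size_t k = 0; k < bad.size() && !grew; ++k) {
        int ti = bad[k];
        for (int i = 0; i < 4; ++i) {
          int nb = tets[ti].nb[i];
          if (nb >= 0 && inbad[nb]) continue;
          int f[3];
          face_of(tets[ti], i, f);  // ordered toward inner vertex
          // p lies inside the cavity, i.e. on the positive side of every
          // boundary face; otherwise the cavity is not star-shaped around p
          // and the outside neighbour must be absorbed
          double o = orient3d(pt(f[0]), pt(f[1]), pt(f[2]), p);
          if (o <= 0 && nb >= 0) {
            inbad[nb] = 1; bad.push_back(nb); grew = true; break;
          }
          BFace bf; bf.f[0] = f[0]; bf.f[1] = f[1]; bf.f[2] = f[2];
          bf.outside = nb;
          bnd.push_back(bf);
        }
      }
      if (!grew) break;
    }

    for (size_t k = 0; k < bad.size(); ++k) tets[bad[k]].alive = false;

    // build new tets (f0,f1,f2,vid), positively oriented by construction
    std::unordered_map<std::uint64_t, std::pair<int,int>> edge2face;
    std::vector<int> newids(bnd.size());
    for (size_t k = 0; k < bnd.size(); ++k) {
      Tet nt;
      nt.v[0] = bnd[k].f[0]; nt.v[1] = bnd[k].f[1];
      nt.v[2] = bnd[k].f[2]; nt.v[3] = vid;
      nt.nb[0] = nt.nb[1] = nt.nb[2] = -1;
      nt.nb[3] = bnd[k].outside;
      nt.alive = true;
      int id = (int)tets.size();
      tets.push_back(nt);
      newids[k] = id;
      if (bnd[k].outside >= 0) {
        Tet& ot = tets[bnd[k].outside];
        // fix outside tet's pointer: find its face matching ours
        for (int i = 0; i < 4; ++i) {
          int of[3];
          static const int others[4][3] = {{1,2,3},{0,2,3},{0,1,3},{0,1,2}};
          of[0]=ot.v[others[i][0]]; of[1]=ot.v[others[i][1]]; of[2]=ot.v[others[i][2]];
          int a=nt.v[0], b=nt.v[1], c=nt.v[2];
          int s1=a+b+c, s2=of[0]+of[1]+of[2];
          if (s1==s2) {
            int mn1=std::min(a,std::min(b,c)), mn2=std::min(of[0],std::min(of[1],of[2]));
            int mx1=std::max(a,std::max(b,c)), mx2=std::max(of[0],std::max(of[1],of[2]));
            if (mn1==mn2 && mx1==mx2) { ot.nb[i] = id; break; }
          }
        }
      }
      // register the three faces containing vid by their base edge
      for (int i = 0; i < 3; ++i) {
        int a = nt.v[i], b = nt.v[(i + 1) % 3];
        if (a > b) std::swap(a, b);
        std::uint64_t key = ((std::uint64_t)a << 32) | (std::uint64_t)b;
        auto it = edge2face.find(key);
        // face opposite corner (i+2)%3 shares edge (a,b) and vid
        int corner = (i + 2) % 3;
        if (it == edge2face.end()) {
          edge2face[key] = std::make_pair(id, corner);
        } else {
          int oid = it->second.first, ocorner = it->second.second;
          tets[id].nb[corner] = oid;
          tets[oid].nb[ocorner] = id;
        }
      }
    }
    if (!bnd.empty()) hint = newids[0];
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_delaunay3d(NumericMatrix pts, double jitter_rel = 1e-9,
                    int seed = 12345) {
  int n = pts.nrow();
  if (n < 5) stop("need at least 5 points");

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j);
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) +
                          (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (diag <= 0) stop("degenerate point set (zero extent)");
  double cx = 0.5*(lo[0]+hi[0]), cy = 0.5*(lo[1]+hi[1]), cz = 0.5*(lo[2]+hi[2]);

  DT dt;
  dt.nreal = n;
  dt.P.resize(3 * (size_t)(n + 4));
  double amp = jitter_rel * diag;
  for (int i = 0; i < n; ++i) {
    std::uint64_t h = splitmix64((std::uint64_t)seed * 2654435761ULL + i);
    dt.P[3*i]   = pts(i,0) + amp * (u01(h) - 0.5);
    dt.P[3*i+1] = pts(i,1) + amp * (u01(splitmix64(h)) - 0.5);
    dt.P[3*i+2] = pts(i,2) + amp * (u01(splitmix64(h ^ 0xabcdefULL)) - 0.5);
  }
  // large enclosing tetrahedron, asymmetric scales to avoid cancellations
  double S = 1e5 * diag;
  double sv[4][3] = {
    {cx - 1.1 * S, cy - 0.9 * S, cz - 1.3 * S},
    {cx + 2.3 * S, cy - 1.1 * S, cz - 0.8 * S},
    {cx + 0.1 * S, cy + 2.9 * S, cz - 1.1 * S},
    {cx - 0.2 * S, cy + 0.3 * S, cz + 3.1 * S}};
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 3; ++j) dt.P[3 * (size_t)(n + i) + j] = sv[i][j];

  Tet st;
  st.v[0] = n; st.v[1] = n + 1; st.v[2] = n + 2; st.v[3] = n + 3;
  if (orient3d(dt.pt(st.v[0]), dt.pt(st.v[1]), dt.pt(st.v[2]),
               dt.pt(st.v[3])) < 0)
    std::swap(st.v[1], st.v[2]);
  st.nb[0] = st.nb[1] = st.nb[2] = st.nb[3] = -1;
  st.alive = true;
  dt.tets.push_back(st);

  // pseudo-random insertion order
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::uint64_t rng = splitmix64((std::uint64_t)seed + 77);
  for (int i = n - 1; i > 0; --i) {
    rng = splitmix64(rng);
    int j = (int)(rng % (std::uint64_t)(i + 1));
    std::swap(order[i], order[j]);
  }

  int hint = 0;
  for (int k = 0; k < n; ++k) {
    dt.insert(order[k], hint);
    if (hint >= (int)dt.tets.size() || !dt.tets[hint].alive) hint = 0;
    if ((k & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // keep tets with all-real vertices
  std::vector<int> keep;
  for (size_t k = 0; k < dt.tets.size(); ++k) {
    if (!dt.tets[k].alive) continue;
    const Tet& t = dt.tets[k];
    if (t.v[0] < n && t.v[1] < n && t.v[2] < n && t.v[3] < n)
      keep.push_back((int)k);
  }
  IntegerMatrix T((int)keep.size(), 4);
  for (size_t k = 0; k < keep.size(); ++k)
    for (int j = 0; j < 4; ++j) T((int)k, j) = dt.tets[keep[k]].v[j] + 1;
  return List::create(_["tets"] = T);
}
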