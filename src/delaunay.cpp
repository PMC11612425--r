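// Incremental Delaunay triangulation (Bowyer-Watson) with a single ghost
// vertex representing the point at infinity, so that hull handling never
// relies on far-away super-triangle coordinates.  Predicates evaluate in
// double precision with an error bound and fall back to long double near
// degeneracy; inputs with exact duplicates or a fully collinear point set
// are rejected at the R level before this code runs.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const double ORIENT_ERR = 3.3306690738754716e-16;  // (3 + 16 eps) eps
const double INCIRCLE_ERR = 8.8817841970012523e-15;

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  const double detl = (bx - ax) * (cy - ay);
  const double detr = (by - ay) * (cx - ax);
  const double det = detl - detr;
  const double bound = ORIENT_ERR * (std::fabs(detl) + std::fabs(detr));
  if (std::fabs(det) > bound) return det;
  const long double d =
      (static_cast<long double>(bx) - ax) * (static_cast<long double>(cy) - ay) -
      (static_cast<long double>(by) - ay) * (static_cast<long double>(cx) - ax);
  if (d > 0) return 1.0;
  if (d < 0) return -1.0;
  return 0.0;
}

inline double incircle(double ax, double ay, double bx, double by,
                       double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  const double det = adx * (bdy * cd - bd * cdy) -
                     ady * (bdx * cd - bd * cdx) +
                     ad * (bdx * cdy - bdy * cdx);
  const double perm = std::fabs(adx) * (std::fabs(bdy) * cd + bd * std::fabs(cdy)) +
                      std::fabs(ady) * (std::fabs(bdx) * cd + bd * std::fabs(cdx)) +
                      ad * (std::fabs(bdx * cdy) + std::fabs(bdy * cdx));
  if (std::fabs(det) > INCIRCLE_ERR * perm) return det;
  // long double fallback
  const long double ladx = static_cast<long double>(ax) - px;
  const long double lady = static_cast<long double>(ay) - py;
  const long double lbdx = static_cast<long double>(bx) - px;
  const long double lbdy = static_cast<long double>(by) - py;
  const long double lcdx = static_cast<long double>(cx) - px;
  const long double lcdy = static_cast<long double>(cy) - py;
  const long double lad = ladx * ladx + lady * lady;
  const long double lbd = lbdx * lbdx + lbdy * lbdy;
  const long double lcd = lcdx * lcdx + lcdy * lcdy;
  const long double ldet = ladx * (lbdy * lcd - lbd * lcdy) -
                           lady * (lbdx * lcd - lbd * lcdx) +
                           lad * (lbdx * lcdy - lbdy * lcdx);
  if (ldet > 0) return 1.0;
  if (ldet < 0) return -1.0;
  return 0.0;
}

struct Tri {
  int v[3];    // vertex ids; -1 encodes the ghost vertex
  int nbr[3];  // neighbour triangle opposite v[k]
  bool alive;
};

struct Mesh {
  const double* x;
  const double* y;
  int n;
  std::vector<Tri> tris;
  std::vector<int> mark;  // cavity stamps, parallel to tris
  int stamp;
  int last;  // walk hint
  uint64_t rng;

  Mesh(const double* px, const double* py, int nn)
      : x(px), y(py), n(nn), stamp(0), last(-1), rng(88172645463325252ULL) {}

  int alloc() {
    tris.push_back(Tri());
    mark.push_back(0);
    return static_cast<int>(tris.size()) - 1;
  }

  inline int ghostIndex(const Tri& t) const {
    if (t.v[0] < 0) return 0;
    if (t.v[1] < 0) return 1;
    if (t.v[2] < 0) return 2;
    return -1;
  }

  bool conflict(int ti, double px, double py) const {
    const Tri& t = tris[ti];
    const int gi = ghostIndex(t);
    if (gi < 0) {
      return incircle(x[t.v[0]], y[t.v[0]], x[t.v[1]], y[t.v[1]],
                      x[t.v[2]], y[t.v[2]], px, py) > 0.0;
    }
    const int u = t.v[(gi + 1) % 3];
    const int w = t.v[(gi + 2) % 3];
    const double o = orient2d(x[u], y[u], x[w], y[w], px, py);
    if (o > 0) return true;
    if (o == 0) {
      const double d1 = (px - x[u]) * (x[w] - x[u]) + (py - y[u]) * (y[w] - y[u]);
      const double d2 = (px - x[w]) * (x[u] - x[w]) + (py - y[w]) * (y[u] - y[w]);
      return d1 > 0 && d2 > 0;  // on the open hull edge itself
    }
    return false;
  }

  int locate(double px, double py) {
    int t = last;
    if (t < 0 || !tris[t].alive) {
      t = -1;
      for (int i = static_cast<int>(tris.size()) - 1; i >= 0; --i)
        if (tris[i].alive) { t = i; break; }
    }
    const int limit = 8 * static_cast<int>(tris.size()) + 64;
    int steps = 0;
    while (t >= 0 && steps++ < limit) {
      if (conflict(t, px, py)) return t;
      const Tri& T = tris[t];
      const int gi = ghostIndex(T);
      if (gi >= 0) { t = T.nbr[gi]; continue; }  // step back inside the hull
      int cand[3];
      int nc = 0;
      for (int k = 0; k < 3; ++k) {
        const int u = T.v[(k + 1) % 3];
        const int w = T.v[(k + 2) % 3];
        if (orient2d(x[u], y[u], x[w], y[w], px, py) < 0) cand[nc++] = k;
      }
      if (nc == 0) return t;  // p inside triangle; take it
      rng = rng * 6364136223846793005ULL + 1442695040888963407ULL;
      t = T.nbr[cand[(rng >> 33) % nc]];
    }
    // exhaustive fallback (degenerate walks only)
    for (int i = 0; i < static_cast<int>(tris.size()); ++i)
      if (tris[i].alive && conflict(i, px, py)) return i;
    return -1;
  }

  void insert(int pid) {
    const double px = x[pid], py = y[pid];
    const int seed = locate(px, py);
    if (seed < 0)
      stop("Delaunay construction failed: point %d is degenerate "
           "(duplicate or collinear input?)", pid + 1);
    ++stamp;
    std::vector<int> cav;
    cav.push_back(seed);
    mark[seed] = stamp;
    // boundary entries: u, w (directed edge), outside tri, cavity tri
    std::vector<std::array<int, 4> > bnd;
    for (size_t i = 0; i < cav.size(); ++i) {
      const int ti = cav[i];
      for (int k = 0; k < 3; ++k) {
        const int nb = tris[ti].nbr[k];
        const int u = tris[ti].v[(k + 1) % 3];
        const int w = tris[ti].v[(k + 2) % 3];
        if (mark[nb] == stamp) continue;
        if (conflict(nb, px, py)) {
          mark[nb] = stamp;
          cav.push_back(nb);
        } else {
          bnd.push_back({{u, w, nb, ti}});
        }
      }
    }
    for (size_t i = 0; i < cav.size(); ++i) tris[cav[i]].alive = false;
    std::unordered_map<int, int> byStart;
    byStart.reserve(bnd.size() * 2);
    std::vector<int> created;
    created.reserve(bnd.size());
    for (size_t i = 0; i < bnd.size(); ++i) {
      const int id = alloc();
      Tri& t = tris[id];
      t.v[0] = bnd[i][0];
      t.v[1] = bnd[i][1];
      t.v[2] = pid;
      t.nbr[0] = -1;
      t.nbr[1] = -1;
      t.nbr[2] = bnd[i][2];
      t.alive = true;
      Tri& o = tris[bnd[i][2]];
      for (int k = 0; k < 3; ++k)
        if (o.nbr[k] == bnd[i][3]) { o.nbr[k] = id; break; }
      byStart[bnd[i][0]] = id;
      created.push_back(id);
    }
    for (size_t i = 0; i < created.size(); ++i) {
      const int id = created[i];
      const int w = tris[id].v[1];
      const int s = byStart[w];     // triangle sharing edge (w, pid)
      tris[id].nbr[0] = s;
      tris[s].nbr[1] = id;
    }
    last = created.empty() ? last : created.back();
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay_edges(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points");

  // spatially coherent (serpentine grid) insertion order
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const int g = std::max(1, static_cast<int>(std::ceil(std::sqrt(n / 4.0))));
  const double xr = (xmax > xmin) ? (xmax - xmin) : 1.0;
  const double yr = (ymax > ymin) ? (ymax - ymin) : 1.0;
  std::vector<int> ord(n);
  std::vector<double> key(n);
  for (int i = 0; i < n; ++i) {
    ord[i] = i;
    int cr = static_cast<int>((y[i] - ymin) / yr * g);
    int cc = static_cast<int>((x[i] - xmin) / xr * g);
    cr = std::min(cr, g - 1);
    cc = std::min(cc, g - 1);
    if (cr % 2 == 1) cc = g - 1 - cc;
    key[i] = static_cast<double>(cr) * g + cc;
  }
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (key[a] != key[b]) return key[a] < key[b];
    if (x[a] != x[b]) return x[a] < x[b];
    if (y[a] != y[b]) return y[a] < y[b];
    return a < b;
  });

  // first three non-collinear points in insertion order
  const int i0 = ord[0];
  const int i1 = ord[1];
  int i2 = -1;
  for (int k = 2; k < n; ++k) {
    if (orient2d(x[i0], y[i0], x[i1], y[i1], x[ord[k]], y[ord[k]]) != 0.0) {
      i2 = ord[k];
      break;
    }
  }
  if (i2 < 0) stop("all points are collinear");

  Mesh M(REAL(x), REAL(y), n);
  {
    int a = i0, b = i1, c = i2;
    if (orient2d(x[a], y[a], x[b], y[b], x[c], y[c]) < 0) std::swap(b, c);
    const int t0 = M.alloc();
    const int g0 = M.alloc();
    const int g1 = M.alloc();
    const int g2 = M.alloc();
    M.tris[t0] = Tri{{a, b, c}, {g1, g2, g0}, true};        // nbr opp a = edge(b,c)
    M.tris[g0] = Tri{{b, a, -1}, {g2, g1, t0}, true};       // edge (b,a)
    M.tris[g1] = Tri{{c, b, -1}, {g0, g2, t0}, true};       // edge (c,b)
    M.tris[g2] = Tri{{a, c, -1}, {g1, g0, t0}, true};       // edge (a,c)
    M.last = t0;
  }
  for (int k = 2; k < n; ++k) {
    const int p = ord[k];
    if (p == i2) continue;
    M.insert(p);
  }

  std::vector<int64_t> edges;
  edges.reserve(3 * n);
  for (size_t t = 0; t < M.tris.size(); ++t) {
    if (!M.tris[t].alive) continue;
    const Tri& T = M.tris[t];
    for (int k = 0; k < 3; ++k) {
      const int u = T.v[k];
      const int w = T.v[(k + 1) % 3];
      if (u < 0 || w < 0) continue;
      const int a = std::min(u, w);
      const int b = std::max(u, w);
      edges.push_back(static_cast<int64_t>(a) * n + b);
    }
  }
  std::sort(edges.begin(), edges.end());
  edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
  IntegerMatrix out(static_cast<int>(edges.size()), 2);
  for (size_t i = 0; i < edges.size(); ++i) {
    out(i, 0) = static_cast<int>(edges[i] / n) + 1;
    out(i, 1) = static_cast<int>(edges[i] % n) + 1;
  }
  return out;
}
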