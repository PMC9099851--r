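// Unstructured triangular meshing kernel: incremental Bowyer-Watson
// Delaunay triangulation with walk-based point location, flood-fill
// domain classification against constrained boundary edges, and
// inversion-safe Laplacian smoothing.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 iff p strictly inside circumcircle of CCW triangle (a,b,c)
static inline double incircle(double ax, double ay, double bx, double by,
                              double cx, double cy, double px, double py) {
  double adx = ax - px, ady = ay - py;
  double bdx = bx - px, bdy = by - py;
  double cdx = cx - px, cdy = cy - py;
  double ad = adx * adx + ady * ady;
  double bd = bdx * bdx + bdy * bdy;
  double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

struct Tri {
  int v[3];
  int adj[3];   // adj[i] across edge opposite vertex i
  bool alive;
};

static inline int64_t ekey(int a, int b, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (int64_t)lo * (int64_t)n + (int64_t)hi;
}

// [[Rcpp::export]]
IntegerMatrix dt_triangulate(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 3) stop("dt_triangulate: need at least 3 points");
  std::vector<double> x(n + 3), y(n + 3);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    x[i] = pts(i, 0); y[i] = pts(i, 1);
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  double scale = std::max(xmax - xmin, ymax - ymin);
  if (scale <= 0) stop("dt_triangulate: degenerate point set");
  // normalize for predicate conditioning
  for (int i = 0; i < n; ++i) {
    x[i] = (x[i] - xmin) / scale;
    y[i] = (y[i] - ymin) / scale;
  }
  // super-triangle (CCW)
  x[n] = -10.0;  y[n] = -10.0;
  x[n + 1] = 20.0; y[n + 1] = -10.0;
  x[n + 2] = 0.5; y[n + 2] = 20.0;

  std::vector<Tri> tris;
  tris.reserve(2 * n + 16);
  Tri t0; t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2;
  t0.adj[0] = t0.adj[1] = t0.adj[2] = -1; t0.alive = true;
  tris.push_back(t0);

  const double eps = 1e-14;
  int last = 0;
  std::vector<int> bad, stack;
  std::vector<int> stamp;   // cavity membership epoch per triangle
  int epoch = 0;

  for (int ip = 0; ip < n; ++ip) {
    double px = x[ip], py = y[ip];
    // locate by walk
    int cur = last, steps = 0, maxsteps = (int)(10 * std::sqrt((double)tris.size())) + 200;
    while (true) {
      if (!tris[cur].alive) { cur = (int)tris.size() - 1; while (!tris[cur].alive) --cur; }
      const Tri &t = tris[cur];
      int moved = -1;
      for (int e = 0; e < 3; ++e) {
        int a = t.v[(e + 1) % 3], b = t.v[(e + 2) % 3];
        if (orient2d(x[a], y[a], x[b], y[b], px, py) < -eps) {
          if (t.adj[e] >= 0) { moved = t.adj[e]; break; }
        }
      }
      if (moved < 0) break;
      cur = moved;
      if (++steps > maxsteps) {  // fallback brute scan
        cur = -1;
        for (int k = (int)tris.size() - 1; k >= 0; --k) {
          if (!tris[k].alive) continue;
          const Tri &tt = tris[k];
          bool in = true;
          for (int e = 0; e < 3 && in; ++e) {
            int a = tt.v[(e + 1) % 3], b = tt.v[(e + 2) % 3];
            if (orient2d(x[a], y[a], x[b], y[b], px, py) < -1e-12) in = false;
          }
          if (in) { cur = k; break; }
        }
        if (cur < 0) stop("dt_triangulate: point location failed");
        break;
      }
    }
    // cavity BFS
    bad.clear(); stack.clear();
    ++epoch;
    if (stamp.size() < tris.size()) stamp.resize(2 * tris.size() + 16, 0);
    stack.push_back(cur); stamp[cur] = epoch;
    while (!stack.empty()) {
      int k = stack.back(); stack.pop_back();
      bad.push_back(k);
      for (int e = 0; e < 3; ++e) {
        int nb = tris[k].adj[e];
        if (nb < 0 || stamp[nb] == epoch || !tris[nb].alive) continue;
        const Tri &tn = tris[nb];
        if (incircle(x[tn.v[0]], y[tn.v[0]], x[tn.v[1]], y[tn.v[1]],
                     x[tn.v[2]], y[tn.v[2]], px, py) > eps) {
          stamp[nb] = epoch; stack.push_back(nb);
        }
      }
    }
    // boundary fan
    std::unordered_map<int, int> byStart, byEnd;
    std::vector<int> created;
    for (size_t bi = 0; bi < bad.size(); ++bi) {
      int k = bad[bi];
      for (int e = 0; e < 3; ++e) {
        int nb = tris[k].adj[e];
        if (nb >= 0 && stamp[nb] == epoch) continue;
        int a = tris[k].v[(e + 1) % 3], b = tris[k].v[(e + 2) % 3];
        Tri nt; nt.v[0] = a; nt.v[1] = b; nt.v[2] = ip;
        nt.adj[2] = nb; nt.adj[0] = -1; nt.adj[1] = -1; nt.alive = true;
        int idx = (int)tris.size();
        tris.push_back(nt);
        created.push_back(idx);
        byStart[a] = idx; byEnd[b] = idx;
        if (nb >= 0) {  // fix outer neighbor's pointer
          for (int e2 = 0; e2 < 3; ++e2) if (tris[nb].adj[e2] == k) tris[nb].adj[e2] = idx;
        }
      }
    }
    for (size_t ci = 0; ci < created.size(); ++ci) {
      int idx = created[ci];
      int a = tris[idx].v[0], b = tris[idx].v[1];
      // edge (b, ip) opposite v[0]=a -> neighbor is triangle starting at b
      tris[idx].adj[0] = byStart.count(b) ? byStart[b] : -1;
      // edge (ip, a) opposite v[1]=b -> neighbor is triangle ending at a
      tris[idx].adj[1] = byEnd.count(a) ? byEnd[a] : -1;
    }
    for (size_t bi = 0; bi < bad.size(); ++bi) tris[bad[bi]].alive = false;
    if (!created.empty()) last = created.back();
  }

  // collect triangles not touching super vertices
  int m = 0;
  for (size_t k = 0; k < tris.size(); ++k) {
    if (!tris[k].alive) continue;
    if (tris[k].v[0] >= n || tris[k].v[1] >= n || tris[k].v[2] >= n) continue;
    ++m;
  }
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t k = 0; k < tris.size(); ++k) {
    if (!tris[k].alive) continue;
    if (tris[k].v[0] >= n || tris[k].v[1] >= n || tris[k].v[2] >= n) continue;
    out(r, 0) = tris[k].v[0] + 1;
    out(r, 1) = tris[k].v[1] + 1;
    out(r, 2) = tris[k].v[2] + 1;
    ++r;
  }
  return out;
}

// Flood fill from a seed point, never crossing barrier edges; returns a
// keep flag per triangle. tri and barrier are 1-based.
// [[Rcpp::export]]
LogicalVector dt_flood_keep(IntegerMatrix tri, NumericMatrix pts,
                            IntegerMatrix barrier, NumericVector seed) {
  const int m = tri.nrow(), n = pts.nrow();
  std::unordered_set<int64_t> bar;
  for (int i = 0; i < barrier.nrow(); ++i)
    bar.insert(ekey(barrier(i, 0) - 1, barrier(i, 1) - 1, n));
  // edge -> adjacent triangles
  std::unordered_map<int64_t, std::pair<int, int> > emap;
  emap.reserve(3 * m);
  for (int k = 0; k < m; ++k) {
    for (int e = 0; e < 3; ++e) {
      int a = tri(k, (e + 1) % 3) - 1, b = tri(k, (e + 2) % 3) - 1;
      int64_t key = ekey(a, b, n);
      std::unordered_map<int64_t, std::pair<int, int> >::iterator it = emap.find(key);
      if (it == emap.end()) emap[key] = std::make_pair(k, -1);
      else it->second.second = k;
    }
  }
  // seed triangle
  double sx = seed[0], sy = seed[1];
  int s = -1;
  for (int k = 0; k < m; ++k) {
    double ax = pts(tri(k, 0) - 1, 0), ay = pts(tri(k, 0) - 1, 1);
    double bx = pts(tri(k, 1) - 1, 0), by = pts(tri(k, 1) - 1, 1);
    double cx = pts(tri(k, 2) - 1, 0), cy = pts(tri(k, 2) - 1, 1);
    if (orient2d(ax, ay, bx, by, sx, sy) >= 0 &&
        orient2d(bx, by, cx, cy, sx, sy) >= 0 &&
        orient2d(cx, cy, ax, ay, sx, sy) >= 0) { s = k; break; }
  }
  if (s < 0) stop("dt_flood_keep: seed point not inside any triangle");
  LogicalVector keep(m, false);
  std::vector<int> stack; stack.push_back(s); keep[s] = true;
  while (!stack.empty()) {
    int k = stack.back(); stack.pop_back();
    for (int e = 0; e < 3; ++e) {
      int a = tri(k, (e + 1) % 3) - 1, b = tri(k, (e + 2) % 3) - 1;
      int64_t key = ekey(a, b, n);
      if (bar.count(key)) continue;
      std::pair<int, int> pr = emap[key];
      int nb = (pr.first == k) ? pr.second : pr.first;
      if (nb >= 0 && !keep[nb]) { keep[nb] = true; stack.push_back(nb); }
    }
  }
  return keep;
}

// Laplacian smoothing with inversion guard. fixed marks immovable nodes.
// [[Rcpp::export]]
NumericMatrix dt_smooth(NumericMatrix pts, IntegerMatrix tri,
                        LogicalVector fixed, int iters, double relax) {
  const int n = pts.nrow(), m = tri.nrow();
  NumericMatrix out = clone(pts);
  std::vector< std::vector<int> > vnbr(n), vtri(n);
  for (int k = 0; k < m; ++k) {
    for (int e = 0; e < 3; ++e) {
      int a = tri(k, e) - 1;
      vtri[a].push_back(k);
      int b = tri(k, (e + 1) % 3) - 1;
      vnbr[a].push_back(b);
      vnbr[b].push_back(a);
    }
  }
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) {
      if (fixed[i] || vnbr[i].empty()) continue;
      double mx = 0, my = 0; int cnt = 0;
      std::unordered_set<int> seen;
      for (size_t j = 0; j < vnbr[i].size(); ++j) {
        int b = vnbr[i][j];
        if (seen.count(b)) continue;
        seen.insert(b);
        mx += out(b, 0); my += out(b, 1); ++cnt;
      }
      mx /= cnt; my /= cnt;
      double nx = out(i, 0) + relax * (mx - out(i, 0));
      double ny = out(i, 1) + relax * (my - out(i, 1));
      bool ok = true;
      for (size_t j = 0; j < vtri[i].size() && ok; ++j) {
        int k = vtri[i][j];
        double px[3], py[3];
        for (int e = 0; e < 3; ++e) {
          int vv = tri(k, e) - 1;
          px[e] = (vv == i) ? nx : out(vv, 0);
          py[e] = (vv == i) ? ny : out(vv, 1);
        }
        double a2 = orient2d(px[0], py[0], px[1], py[1], px[2], py[2]);
        if (a2 <= 1e-14) ok = false;
      }
      if (ok) { out(i, 0) = nx; out(i, 1) = ny; }
    }
  }
  return out;
}

// Minimum distance from each point to a set of segments (x1,y1,x2,y2 rows)
// [[Rcpp::export]]
NumericVector dist_to_segments(NumericMatrix pts, NumericMatrix segs) {
  const int n = pts.nrow(), m = segs.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      double ax = segs(k, 0), ay = segs(k, 1), bx = segs(k, 2), by = segs(k, 3);
      double dx = bx - ax, dy = by - ay;
      double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((px - ax) * dx + (py - ay) * dy) / L2 : 0.0;
      if (t < 0) t = 0; if (t > 1) t = 1;
      double qx = ax + t * dx - px, qy = ay + t * dy - py;
      double d = qx * qx + qy * qy;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Locate query points in a triangulation using a uniform-grid index
// over triangle bounding boxes. Returns 1-based triangle index or 0,
// plus barycentric coordinates.
// [[Rcpp::export]]
List locate_points(NumericMatrix pts, IntegerMatrix tri, NumericMatrix query) {
  const int m = tri.nrow(), q = query.nrow();
  IntegerVector idx(q);
  NumericMatrix bary(q, 3);
  if (m == 0 || q == 0) return List::create(_["tri"] = idx, _["bary"] = bary);
  // triangle bounding boxes and grid sizing
  std::vector<double> bxmin(m), bxmax(m), bymin(m), bymax(m);
  double gxmin = R_PosInf, gxmax = R_NegInf, gymin = R_PosInf, gymax = R_NegInf;
  double maxext = 0;
  for (int k = 0; k < m; ++k) {
    double x0 = pts(tri(k, 0) - 1, 0), y0 = pts(tri(k, 0) - 1, 1);
    double x1 = pts(tri(k, 1) - 1, 0), y1 = pts(tri(k, 1) - 1, 1);
    double x2 = pts(tri(k, 2) - 1, 0), y2 = pts(tri(k, 2) - 1, 1);
    bxmin[k] = std::min(x0, std::min(x1, x2));
    bxmax[k] = std::max(x0, std::max(x1, x2));
    bymin[k] = std::min(y0, std::min(y1, y2));
    bymax[k] = std::max(y0, std::max(y1, y2));
    gxmin = std::min(gxmin, bxmin[k]); gxmax = std::max(gxmax, bxmax[k]);
    gymin = std::min(gymin, bymin[k]); gymax = std::max(gymax, bymax[k]);
    maxext = std::max(maxext, std::max(bxmax[k] - bxmin[k], bymax[k] - bymin[k]));
  }
  double cell = std::max(maxext, 1e-12);
  int nx = std::max(1, (int)((gxmax - gxmin) / cell) + 1);
  int ny = std::max(1, (int)((gymax - gymin) / cell) + 1);
  std::vector< std::vector<int> > bins((size_t)nx * ny);
  for (int k = 0; k < m; ++k) {
    int cx0 = (int)((bxmin[k] - gxmin) / cell), cx1 = (int)((bxmax[k] - gxmin) / cell);
    int cy0 = (int)((bymin[k] - gymin) / cell), cy1 = (int)((bymax[k] - gymin) / cell);
    for (int cx = cx0; cx <= cx1 && cx < nx; ++cx)
      for (int cy = cy0; cy <= cy1 && cy < ny; ++cy)
        if (cx >= 0 && cy >= 0) bins[(size_t)cx * ny + cy].push_back(k);
  }
  for (int i = 0; i < q; ++i) {
    double px = query(i, 0), py = query(i, 1);
    idx[i] = 0;
    int cx = (int)((px - gxmin) / cell), cy = (int)((py - gymin) / cell);
    if (px < gxmin || py < gymin || cx >= nx || cy >= ny) continue;
    const std::vector<int> &cand = bins[(size_t)cx * ny + cy];
    for (size_t c = 0; c < cand.size(); ++c) {
      int k = cand[c];
      if (px < bxmin[k] || px > bxmax[k] || py < bymin[k] || py > bymax[k]) continue;
      double ax = pts(tri(k, 0) - 1, 0), ay = pts(tri(k, 0) - 1, 1);
      double bx = pts(tri(k, 1) - 1, 0), by = pts(tri(k, 1) - 1, 1);
      double cxx = pts(tri(k, 2) - 1, 0), cyy = pts(tri(k, 2) - 1, 1);
      double A = orient2d(ax, ay, bx, by, cxx, cyy);
      if (A <= 0) continue;
      double w0 = orient2d(bx, by, cxx, cyy, px, py) / A;
      double w1 = orient2d(cxx, cyy, ax, ay, px, py) / A;
      double w2 = 1.0 - w0 - w1;
      double tol = -1e-10;
      if (w0 >= tol && w1 >= tol && w2 >= tol) {
        idx[i] = k + 1;
        bary(i, 0) = w0; bary(i, 1) = w1; bary(i, 2) = w2;
        break;
      }
    }
  }
  return List::create(_["tri"] = idx, _["bary"] = bary);
}
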