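// Persistence engine: flag (Vietoris-Rips) and Cech filtrations by explicit
// simplex enumeration up to a radius threshold, plus an alpha-complex path
// for planar point sets (Delaunay triangles supplied by the caller).
// All filtration values are RADII. Homology is computed over GF(2) with the
// standard column reduction (union-find for degree 0).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <array>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// small geometric helpers
// ---------------------------------------------------------------------------

// circumscribing ball of k (2..4) affinely independent points in R^d,
// centre returned through `centre`; radius < 0 flags a degenerate subset
static double circumball(const std::vector<const double*>& P, int d,
                         std::vector<double>& centre) {
  const int k = (int)P.size();
  const int m = k - 1;
  double G[3][3], h[3], x[3];
  std::vector<std::vector<double>> U(m, std::vector<double>(d));
  double scale = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int c = 0; c < d; ++c) U[i][c] = P[i + 1][c] - P[0][c];
  }
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) s += U[i][c] * U[j][c];
      G[i][j] = s;
    }
    h[i] = 0.5 * G[i][i];
    scale = std::max(scale, G[i][i]);
  }
  // Gaussian elimination with partial pivoting (m <= 3)
  for (int col = 0; col < m; ++col) {
    int best = col;
    double bv = std::fabs(G[col][col]);
    for (int r = col + 1; r < m; ++r)
      if (std::fabs(G[r][col]) > bv) { bv = std::fabs(G[r][col]); best = r; }
    if (bv <= 1e-14 * scale) return -1.0;
    if (best != col) {
      for (int c = 0; c < m; ++c) std::swap(G[col][c], G[best][c]);
      std::swap(h[col], h[best]);
    }
    for (int r = col + 1; r < m; ++r) {
      double f = G[r][col] / G[col][col];
      for (int c = col; c < m; ++c) G[r][c] -= f * G[col][c];
      h[r] -= f * h[col];
    }
  }
  for (int r = m - 1; r >= 0; --r) {
    double s = h[r];
    for (int c = r + 1; c < m; ++c) s -= G[r][c] * x[c];
    x[r] = s / G[r][r];
  }
  centre.assign(d, 0.0);
  double r2 = 0;
  for (int c = 0; c < d; ++c) {
    double v = 0;
    for (int i = 0; i < m; ++i) v += x[i] * U[i][c];
    centre[c] = P[0][c] + v;
    r2 += v * v;
  }
  return std::sqrt(r2);
}

// minimum enclosing ball radius of 2..4 points in R^d (support-set search)
static double miniball_radius(const std::vector<const double*>& pts, int d) {
  const int k = (int)pts.size();
  double best = INF;
  std::vector<const double*> sub;
  std::vector<double> centre;
  for (int mask = 1; mask < (1 << k); ++mask) {
    int sz = __builtin_popcount(mask);
    if (sz < 2 || sz > k) continue;
    sub.clear();
    for (int i = 0; i < k; ++i)
      if (mask & (1 << i)) sub.push_back(pts[i]);
    double r = circumball(sub, d, centre);
    if (r < 0 || r >= best) continue;
    bool ok = true;
    for (int i = 0; i < k && ok; ++i) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double df = pts[i][c] - centre[c];
        s += df * df;
      }
      if (s > r * r * (1.0 + 1e-9) + 1e-30) ok = false;
    }
    if (ok) best = r;
  }
  return best;
}

// min enclosing ball radius of a triangle from its squared edge lengths
static double cech_tri_radius(double a2, double b2, double c2) {
  // a2 >= b2 >= c2 after sort
  if (a2 < b2) std::swap(a2, b2);
  if (a2 < c2) std::swap(a2, c2);
  if (b2 < c2) std::swap(b2, c2);
  if (a2 >= b2 + c2) return 0.5 * std::sqrt(a2);  // obtuse/right: diametral
  double a = std::sqrt(a2), b = std::sqrt(b2), c = std::sqrt(c2);
  double s = 0.5 * (a + b + c);
  double K2 = s * (s - a) * (s - b) * (s - c);
  if (K2 <= 0) return 0.5 * a;
  return a * b * c / (4.0 * std::sqrt(K2));
}

// ---------------------------------------------------------------------------
// GF(2) column reduction; columns are sorted ascending row-index vectors.
// Columns are reduced in place; pairOfCol[j] = pivot row or -1 (zero column).
// ---------------------------------------------------------------------------
static void reduce_columns(std::vector<std::vector<int>>& cols, int nrows,
                           std::vector<int>& pairOfCol) {
  std::vector<int> owner(nrows, -1);
  std::vector<int> tmp;
  pairOfCol.assign(cols.size(), -1);
  for (size_t j = 0; j < cols.size(); ++j) {
    std::vector<int>& cur = cols[j];
    while (!cur.empty()) {
      int piv = cur.back();
      int own = owner[piv];
      if (own < 0) {
        owner[piv] = (int)j;
        pairOfCol[j] = piv;
        break;
      }
      const std::vector<int>& o = cols[own];
      tmp.clear();
      std::set_symmetric_difference(cur.begin(), cur.end(), o.begin(), o.end(),
                                    std::back_inserter(tmp));
      cur.swap(tmp);
    }
  }
}

// Memory-lean variant for very large column sets: columns are materialised
// on demand through `boundary(j, out)`, and only columns whose reduced form
// differs from their boundary (i.e. that absorbed additions) are cached —
// in flag filtrations of random data the vast majority pair immediately.
template <class BoundaryFn>
static void reduce_columns_lazy(size_t ncols, int nrows, BoundaryFn boundary,
                                std::vector<int>& pairOfCol) {
  std::vector<int> owner(nrows, -1);
  std::unordered_map<size_t, std::vector<int>> cache;
  std::vector<int> cur, other, tmp;
  pairOfCol.assign(ncols, -1);
  for (size_t j = 0; j < ncols; ++j) {
    boundary(j, cur);
    bool touched = false;
    while (!cur.empty()) {
      int piv = cur.back();
      int own = owner[piv];
      if (own < 0) {
        owner[piv] = (int)j;
        pairOfCol[j] = piv;
        if (touched) cache.emplace(j, cur);
        break;
      }
      auto it = cache.find((size_t)own);
      const std::vector<int>* o;
      if (it != cache.end()) o = &it->second;
      else { boundary((size_t)own, other); o = &other; }
      tmp.clear();
      std::set_symmetric_difference(cur.begin(), cur.end(), o->begin(), o->end(),
                                    std::back_inserter(tmp));
      cur.swap(tmp);
      touched = true;
    }
  }
}

// union-find with path compression
struct UF {
  std::vector<int> parent;
  explicit UF(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[std::max(a, b)] = std::min(a, b);
    return true;
  }
};

struct EdgeRec { double val; int i, j; };
struct TriRec  { double val; int i, j, k; };
struct TetRec  { double val; int i, j, k, l; };

// ---------------------------------------------------------------------------
// main entry: explicit Rips/Cech persistence up to `maxdim` homology degree,
// filtration truncated at radius `threshold` (may be Inf)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_flag_persistence(NumericMatrix X, bool is_dist,
                                   std::string filtration, int maxdim,
                                   double threshold) {
  const bool cech = (filtration == "cech");
  int n, d = 0;
  std::vector<double> coords;  // row-major, cech only
  std::vector<double> D;       // n x n distances
  if (is_dist) {
    n = X.nrow();
    D.assign((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) D[(size_t)i * n + j] = X(i, j);
  } else {
    n = X.nrow();
    d = X.ncol();
    coords.resize((size_t)n * d);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < d; ++c) coords[(size_t)i * d + c] = X(i, c);
    D.assign((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double s = 0;
        for (int c = 0; c < d; ++c) {
          double df = coords[(size_t)i * d + c] - coords[(size_t)j * d + c];
          s += df * df;
        }
        double dist = std::sqrt(s);
        D[(size_t)i * n + j] = dist;
        D[(size_t)j * n + i] = dist;
      }
  }
  if (cech && is_dist) stop("Cech filtration requires point coordinates");

  const double tau = threshold;  // radius scale
  std::vector<double> births, deaths;
  std::vector<int> degs;

  // ---- edges ----
  std::vector<EdgeRec> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double v = 0.5 * D[(size_t)i * n + j];
      if (v <= tau) edges.push_back({v, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const EdgeRec& a, const EdgeRec& b) {
    if (a.val != b.val) return a.val < b.val;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int nE = (int)edges.size();

  // ---- H0 by union-find ----
  std::vector<char> edgeNegative(nE, 0);
  {
    UF uf(n);
    for (int e = 0; e < nE; ++e) {
      if (uf.unite(edges[e].i, edges[e].j)) {
        edgeNegative[e] = 1;
        degs.push_back(0);
        births.push_back(0.0);
        deaths.push_back(edges[e].val);
      }
    }
    int roots = 0;
    for (int i = 0; i < n; ++i)
      if (uf.find(i) == i) ++roots;
    for (int r = 0; r < roots; ++r) {
      degs.push_back(0);
      births.push_back(0.0);
      deaths.push_back(INF);
    }
  }

  std::vector<char> triPositive;
  std::vector<TriRec> tris;

  if (maxdim >= 1) {
    // adjacency lists restricted to included edges
    std::vector<std::vector<int>> adj(n);
    for (int e = 0; e < nE; ++e) {
      adj[edges[e].i].push_back(edges[e].j);
      adj[edges[e].j].push_back(edges[e].i);
    }
    for (int i = 0; i < n; ++i) std::sort(adj[i].begin(), adj[i].end());

    // ---- triangles ----
    for (int i = 0; i < n; ++i) {
      const std::vector<int>& ai = adj[i];
      for (size_t a = 0; a < ai.size(); ++a) {
        int j = ai[a];
        if (j <= i) continue;
        const std::vector<int>& aj = adj[j];
        // intersect ai, aj for k > j
        size_t p = a + 1, q = 0;
        while (q < aj.size() && aj[q] <= j) ++q;
        while (p < ai.size() && q < aj.size()) {
          if (ai[p] < aj[q]) ++p;
          else if (ai[p] > aj[q]) ++q;
          else {
            int k = ai[p];
            double dij = D[(size_t)i * n + j], dik = D[(size_t)i * n + k],
                   djk = D[(size_t)j * n + k];
            double v;
            if (cech)
              v = cech_tri_radius(dij * dij, dik * dik, djk * djk);
            else
              v = 0.5 * std::max(dij, std::max(dik, djk));
            if (v <= tau) tris.push_back({v, i, j, k});
            ++p; ++q;
          }
        }
      }
    }
    std::sort(tris.begin(), tris.end(), [](const TriRec& a, const TriRec& b) {
      if (a.val != b.val) return a.val < b.val;
      if (a.i != b.i) return a.i < b.i;
      if (a.j != b.j) return a.j < b.j;
      return a.k < b.k;
    });

    // edge rank lookup
    std::unordered_map<int64_t, int> erank;
    erank.reserve((size_t)nE * 2);
    for (int e = 0; e < nE; ++e)
      erank[(int64_t)edges[e].i * n + edges[e].j] = e;

    std::vector<int> triB(3 * tris.size());
    for (size_t t = 0; t < tris.size(); ++t) {
      int i = tris[t].i, j = tris[t].j, k = tris[t].k;
      int e0 = erank[(int64_t)i * n + j], e1 = erank[(int64_t)i * n + k],
          e2 = erank[(int64_t)j * n + k];
      if (e0 > e1) std::swap(e0, e1);
      if (e1 > e2) std::swap(e1, e2);
      if (e0 > e1) std::swap(e0, e1);
      triB[3 * t] = e0; triB[3 * t + 1] = e1; triB[3 * t + 2] = e2;
    }
    auto triBoundary = [&](size_t t, std::vector<int>& out) {
      out.assign(triB.begin() + 3 * t, triB.begin() + 3 * t + 3);
    };
    std::vector<int> pairOfCol;
    reduce_columns_lazy(tris.size(), nE, triBoundary, pairOfCol);

    std::vector<char> edgePaired(nE, 0);
    triPositive.assign(tris.size(), 0);
    for (size_t t = 0; t < tris.size(); ++t) {
      int piv = pairOfCol[t];
      if (piv < 0) {
        triPositive[t] = 1;
      } else {
        edgePaired[piv] = 1;
        degs.push_back(1);
        births.push_back(edges[piv].val);
        deaths.push_back(tris[t].val);
      }
    }
    for (int e = 0; e < nE; ++e) {
      if (!edgeNegative[e] && !edgePaired[e]) {
        degs.push_back(1);
        births.push_back(edges[e].val);
        deaths.push_back(INF);
      }
    }

    if (maxdim >= 2) {
      // ---- tetrahedra ----
      std::vector<TetRec> tets;
      std::vector<const double*> P(4);
      for (size_t t = 0; t < tris.size(); ++t) {
        int i = tris[t].i, j = tris[t].j, k = tris[t].k;
        // common neighbours l > k of i, j, k
        const std::vector<int>& ai = adj[i];
        const std::vector<int>& aj = adj[j];
        const std::vector<int>& ak = adj[k];
        size_t p = 0, q = 0, r = 0;
        while (p < ai.size() && q < aj.size() && r < ak.size()) {
          int vmax = std::max(ai[p], std::max(aj[q], ak[r]));
          if (ai[p] < vmax) { ++p; continue; }
          if (aj[q] < vmax) { ++q; continue; }
          if (ak[r] < vmax) { ++r; continue; }
          int l = vmax;
          if (l > k) {
            double v;
            if (cech) {
              P[0] = &coords[(size_t)i * d];
              P[1] = &coords[(size_t)j * d];
              P[2] = &coords[(size_t)k * d];
              P[3] = &coords[(size_t)l * d];
              v = miniball_radius(P, d);
              // clamp to the facet values so the filtration stays monotone
              // under the miniball containment tolerance
              int f[4][3] = {{i, j, k}, {i, j, l}, {i, k, l}, {j, k, l}};
              for (int q = 0; q < 4; ++q) {
                double e1 = D[(size_t)f[q][0] * n + f[q][1]],
                       e2 = D[(size_t)f[q][0] * n + f[q][2]],
                       e3 = D[(size_t)f[q][1] * n + f[q][2]];
                v = std::max(v, cech_tri_radius(e1 * e1, e2 * e2, e3 * e3));
              }
            } else {
              v = tris[t].val;
              v = std::max(v, 0.5 * D[(size_t)i * n + l]);
              v = std::max(v, 0.5 * D[(size_t)j * n + l]);
              v = std::max(v, 0.5 * D[(size_t)k * n + l]);
            }
            if (v <= tau) tets.push_back({v, i, j, k, l});
          }
          ++p; ++q; ++r;
        }
      }
      std::sort(tets.begin(), tets.end(), [](const TetRec& a, const TetRec& b) {
        if (a.val != b.val) return a.val < b.val;
        if (a.i != b.i) return a.i < b.i;
        if (a.j != b.j) return a.j < b.j;
        if (a.k != b.k) return a.k < b.k;
        return a.l < b.l;
      });
      std::unordered_map<int64_t, int> trank;
      trank.reserve(tris.size() * 2);
      for (size_t t = 0; t < tris.size(); ++t)
        trank[((int64_t)tris[t].i * n + tris[t].j) * n + tris[t].k] = (int)t;
      std::vector<int> tetB(4 * tets.size());
      for (size_t t = 0; t < tets.size(); ++t) {
        int i = tets[t].i, j = tets[t].j, k = tets[t].k, l = tets[t].l;
        std::array<int, 4> c = {trank[((int64_t)i * n + j) * n + k],
                                trank[((int64_t)i * n + j) * n + l],
                                trank[((int64_t)i * n + k) * n + l],
                                trank[((int64_t)j * n + k) * n + l]};
        std::sort(c.begin(), c.end());
        std::copy(c.begin(), c.end(), tetB.begin() + 4 * t);
      }
      auto tetBoundary = [&](size_t t, std::vector<int>& out) {
        out.assign(tetB.begin() + 4 * t, tetB.begin() + 4 * t + 4);
      };
      std::vector<int> pair3;
      reduce_columns_lazy(tets.size(), (int)tris.size(), tetBoundary, pair3);
      std::vector<char> triPaired(tris.size(), 0);
      for (size_t t = 0; t < tets.size(); ++t) {
        int piv = pair3[t];
        if (piv >= 0) {
          triPaired[piv] = 1;
          degs.push_back(2);
          births.push_back(tris[piv].val);
          deaths.push_back(tets[t].val);
        }
      }
      for (size_t t = 0; t < tris.size(); ++t) {
        if (triPositive[t] && !triPaired[t]) {
          degs.push_back(2);
          births.push_back(tris[t].val);
          deaths.push_back(INF);
        }
      }
    }
  }

  NumericMatrix out((int)degs.size(), 3);
  for (int r = 0; r < (int)degs.size(); ++r) {
    out(r, 0) = degs[r];
    out(r, 1) = births[r];
    out(r, 2) = deaths[r];
  }
  colnames(out) = CharacterVector::create("degree", "birth", "death");
  return out;
}

// largest squared pairwise distance of a coordinate matrix
// [[Rcpp::export]]
double cpp_sq_diameter(NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  double best = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double df = X(i, c) - X(j, c);
        s += df * df;
      }
      if (s > best) best = s;
    }
  return best;
}

// count point pairs within distance 2 * radius (edge count of the flag
// filtration at a given radius) without building the complex
// [[Rcpp::export]]
double cpp_edge_count(NumericMatrix X, double radius) {
  int n = X.nrow(), d = X.ncol();
  double thr2 = 4.0 * radius * radius;
  double cnt = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double df = X(i, c) - X(j, c);
        s += df * df;
      }
      if (s <= thr2) cnt += 1;
    }
  return cnt;
}

// ---------------------------------------------------------------------------
// alpha complex persistence in the plane; Delaunay triangles supplied by the
// caller (1-based vertex index triples). Full filtration (H0 and H1).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_alpha2d_persistence(NumericMatrix X, IntegerMatrix triangles) {
  const int n = X.nrow();
  const int nT = triangles.nrow();
  if (X.ncol() != 2) stop("alpha complex path expects planar coordinates");

  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = X(i, 0); py[i] = X(i, 1); }

  // triangle circumradii
  std::vector<double> triVal(nT);
  std::vector<std::array<int, 3>> triV(nT);
  for (int t = 0; t < nT; ++t) {
    int a = triangles(t, 0) - 1, b = triangles(t, 1) - 1, c = triangles(t, 2) - 1;
    int v[3] = {a, b, c};
    std::sort(v, v + 3);
    triV[t] = {v[0], v[1], v[2]};
    double ax = px[a], ay = py[a], bx = px[b], by = py[b], cx = px[c], cy = py[c];
    double den = 2.0 * ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax));
    double r;
    if (std::fabs(den) < 1e-300) {
      r = INF;  // degenerate sliver; never realised for generic input
    } else {
      double b2 = (bx - ax) * (bx - ax) + (by - ay) * (by - ay);
      double c2 = (cx - ax) * (cx - ax) + (cy - ay) * (cy - ay);
      double ux = (cy - ay) * b2 - (by - ay) * c2;
      double uy = (bx - ax) * c2 - (cx - ax) * b2;
      double ccx = ax + ux / den, ccy = ay + uy / den;
      r = std::hypot(ccx - ax, ccy - ay);
    }
    triVal[t] = r;
  }

  // edges of the triangulation with adjacent-triangle lists
  struct AEdge { int i, j; double val; std::vector<int> tri; };
  std::unordered_map<int64_t, int> eidx;
  std::vector<AEdge> aedges;
  for (int t = 0; t < nT; ++t) {
    int vv[3] = {triV[t][0], triV[t][1], triV[t][2]};
    int pairs[3][2] = {{vv[0], vv[1]}, {vv[0], vv[2]}, {vv[1], vv[2]}};
    for (int e = 0; e < 3; ++e) {
      int i = pairs[e][0], j = pairs[e][1];
      int64_t key = (int64_t)i * n + j;
      auto it = eidx.find(key);
      int id;
      if (it == eidx.end()) {
        id = (int)aedges.size();
        eidx[key] = id;
        aedges.push_back({i, j, 0.0, {}});
      } else id = it->second;
      aedges[id].tri.push_back(t);
    }
  }
  // edge alpha values: half-length if Gabriel w.r.t. opposite Delaunay
  // vertices, otherwise the smallest adjacent triangle circumradius
  for (auto& e : aedges) {
    double mx = 0.5 * (px[e.i] + px[e.j]);
    double my = 0.5 * (py[e.i] + py[e.j]);
    double half = 0.5 * std::hypot(px[e.i] - px[e.j], py[e.i] - py[e.j]);
    bool gabriel = true;
    double minAdj = INF;
    for (int t : e.tri) {
      minAdj = std::min(minAdj, triVal[t]);
      for (int w : triV[t]) {
        if (w == e.i || w == e.j) continue;
        double dd = std::hypot(px[w] - mx, py[w] - my);
        if (dd < half * (1.0 - 1e-12)) gabriel = false;
      }
    }
    e.val = gabriel ? half : minAdj;
  }

  // sort edges and triangles by filtration value
  std::vector<int> eord(aedges.size()), tord(nT);
  for (size_t i = 0; i < aedges.size(); ++i) eord[i] = (int)i;
  for (int i = 0; i < nT; ++i) tord[i] = i;
  std::sort(eord.begin(), eord.end(), [&](int a, int b) {
    if (aedges[a].val != aedges[b].val) return aedges[a].val < aedges[b].val;
    if (aedges[a].i != aedges[b].i) return aedges[a].i < aedges[b].i;
    return aedges[a].j < aedges[b].j;
  });
  std::sort(tord.begin(), tord.end(), [&](int a, int b) {
    if (triVal[a] != triVal[b]) return triVal[a] < triVal[b];
    return triV[a] < triV[b];
  });
  std::vector<int> erankOf(aedges.size());
  for (size_t r = 0; r < eord.size(); ++r) erankOf[eord[r]] = (int)r;

  std::vector<double> births, deaths;
  std::vector<int> degs;

  // H0
  const int nE = (int)aedges.size();
  std::vector<char> edgeNegative(nE, 0);
  {
    UF uf(n);
    for (int r = 0; r < nE; ++r) {
      const AEdge& e = aedges[eord[r]];
      if (uf.unite(e.i, e.j)) {
        edgeNegative[r] = 1;
        degs.push_back(0);
        births.push_back(0.0);
        deaths.push_back(e.val);
      }
    }
    int roots = 0;
    for (int i = 0; i < n; ++i)
      if (uf.find(i) == i) ++roots;
    for (int r = 0; r < roots; ++r) {
      degs.push_back(0);
      births.push_back(0.0);
      deaths.push_back(INF);
    }
  }

  // H1: triangles over edges
  std::vector<std::vector<int>> cols(nT);
  for (int s = 0; s < nT; ++s) {
    int t = tord[s];
    int vv[3][2] = {{triV[t][0], triV[t][1]},
                    {triV[t][0], triV[t][2]},
                    {triV[t][1], triV[t][2]}};
    std::vector<int> c(3);
    for (int e = 0; e < 3; ++e)
      c[e] = erankOf[eidx[(int64_t)vv[e][0] * n + vv[e][1]]];
    std::sort(c.begin(), c.end());
    cols[s] = std::move(c);
  }
  std::vector<int> pairOfCol;
  reduce_columns(cols, nE, pairOfCol);
  std::vector<char> edgePaired(nE, 0);
  for (int s = 0; s < nT; ++s) {
    int piv = pairOfCol[s];
    if (piv >= 0) {
      edgePaired[piv] = 1;
      degs.push_back(1);
      births.push_back(aedges[eord[piv]].val);
      deaths.push_back(triVal[tord[s]]);
    }
  }
  for (int r = 0; r < nE; ++r) {
    if (!edgeNegative[r] && !edgePaired[r]) {
      degs.push_back(1);
      births.push_back(aedges[eord[r]].val);
      deaths.push_back(INF);  // only when the triangulation is degenerate
    }
  }

  NumericMatrix out((int)degs.size(), 3);
  for (int r = 0; r < (int)degs.size(); ++r) {
    out(r, 0) = degs[r];
    out(r, 1) = births[r];
    out(r, 2) = deaths[r];
  }
  colnames(out) = CharacterVector::create("degree", "birth", "death");
  return out;
}
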