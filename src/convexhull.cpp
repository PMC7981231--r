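// Incremental 3D convex hull (randomized insertion with visible-face
// deletion and horizon re-triangulation). Returns hull volume, surface
// area and the triangle list. Adequate and fast for crown point sets
// (tens of thousands of points, hull sizes in the hundreds).
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

struct Face {
  int a, b, c;     // vertex indices, outward orientation
  bool alive;
};

static inline void cross3(const double* u, const double* v, double* w) {
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
}

// signed distance of p above the plane of (a,b,c): orient normalized by
// the face normal, so the visibility tolerance is a length
static inline double plane_dist(const std::vector<double>& X,
                                const std::vector<double>& Y,
                                const std::vector<double>& Z,
                                int a, int b, int c, int p) {
  double u[3] = {X[b] - X[a], Y[b] - Y[a], Z[b] - Z[a]};
  double v[3] = {X[c] - X[a], Y[c] - Y[a], Z[c] - Z[a]};
  double w[3] = {X[p] - X[a], Y[p] - Y[a], Z[p] - Z[a]};
  double n[3];
  cross3(u, v, n);
  double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  if (nn <= 0.0) return 0.0;
  return (n[0] * w[0] + n[1] * w[1] + n[2] * w[2]) / nn;
}

static size_t n_alive(const std::vector<Face>& faces) {
  size_t k = 0;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) ++k;
  return k;
}

static inline double orient(const std::vector<double>& X,
                            const std::vector<double>& Y,
                            const std::vector<double>& Z,
                            int a, int b, int c, int p) {
  double u[3] = {X[b] - X[a], Y[b] - Y[a], Z[b] - Z[a]};
  double v[3] = {X[c] - X[a], Y[c] - Y[a], Z[c] - Z[a]};
  double w[3] = {X[p] - X[a], Y[p] - Y[a], Z[p] - Z[a]};
  double n[3];
  cross3(u, v, n);
  return n[0] * w[0] + n[1] * w[1] + n[2] * w[2];
}

// [[Rcpp::export(name = ".convhull3d")]]
List convhull3d(NumericVector x, NumericVector y, NumericVector z) {
  int n = x.size();
  std::vector<double> X(x.begin(), x.end());
  std::vector<double> Y(y.begin(), y.end());
  std::vector<double> Z(z.begin(), z.end());

  double span = 0.0;
  {
    double mn[3] = {X[0], Y[0], Z[0]}, mx[3] = {X[0], Y[0], Z[0]};
    for (int i = 1; i < n; ++i) {
      mn[0] = std::min(mn[0], X[i]); mx[0] = std::max(mx[0], X[i]);
      mn[1] = std::min(mn[1], Y[i]); mx[1] = std::max(mx[1], Y[i]);
      mn[2] = std::min(mn[2], Z[i]); mx[2] = std::max(mx[2], Z[i]);
    }
    span = std::max(mx[0] - mn[0], std::max(mx[1] - mn[1], mx[2] - mn[2]));
  }
  if (n < 4 || span <= 0.0)
    return List::create(_["volume"] = NA_REAL, _["area"] = NA_REAL,
                        _["faces"] = IntegerMatrix(0, 3),
                        _["reason"] = "fewer than 4 points or zero extent");
  double eps = 1e-10 * span * span * span;  // volume-scale, initial tetra only
  double dtol = 1e-9 * span;                // distance-scale visibility tol

  // initial non-degenerate tetrahedron
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i) {
    double dx = X[i] - X[i0], dy = Y[i] - Y[i0], dz = Z[i] - Z[i0];
    if (dx * dx + dy * dy + dz * dz > 1e-20 * span * span) i1 = i;
  }
  if (i1 >= 0) {
    for (int i = 1; i < n && i2 < 0; ++i) {
      if (i == i1) continue;
      double u[3] = {X[i1] - X[i0], Y[i1] - Y[i0], Z[i1] - Z[i0]};
      double v[3] = {X[i] - X[i0], Y[i] - Y[i0], Z[i] - Z[i0]};
      double c[3];
      cross3(u, v, c);
      if (c[0] * c[0] + c[1] * c[1] + c[2] * c[2] > 1e-20 * span * span * span * span)
        i2 = i;
    }
  }
  if (i2 >= 0) {
    for (int i = 1; i < n && i3 < 0; ++i) {
      if (i == i1 || i == i2) continue;
      if (std::fabs(orient(X, Y, Z, i0, i1, i2, i)) > eps) i3 = i;
    }
  }
  if (i3 < 0)
    return List::create(_["volume"] = NA_REAL, _["area"] = NA_REAL,
                        _["faces"] = IntegerMatrix(0, 3),
                        _["reason"] = "degenerate (coplanar) point set");

  if (orient(X, Y, Z, i0, i1, i2, i3) > 0) std::swap(i1, i2);
  std::vector<Face> faces;
  faces.push_back({i0, i1, i2, true});
  faces.push_back({i0, i3, i1, true});
  faces.push_back({i0, i2, i3, true});
  faces.push_back({i1, i3, i2, true});

  // deterministic shuffle of the insertion order: structured streams
  // (e.g. points marching outward along branches) otherwise trigger the
  // quadratic worst case of incremental insertion
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned long long st = 88172645463325252ULL;
  for (int i = n - 1; i > 0; --i) {
    st ^= st << 13; st ^= st >> 7; st ^= st << 17;
    std::swap(order[i], order[(int)(st % (unsigned long long)(i + 1))]);
  }

  for (int oi = 0; oi < n; ++oi) {
    int p = order[oi];
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // compact dead faces when they dominate the list
    if (faces.size() > 256 && faces.size() > 4 * (size_t)n_alive(faces)) {
      std::vector<Face> keep;
      keep.reserve(n_alive(faces));
      for (size_t f = 0; f < faces.size(); ++f)
        if (faces[f].alive) keep.push_back(faces[f]);
      faces.swap(keep);
    }
    // collect faces visible from p
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (plane_dist(X, Y, Z, faces[f].a, faces[f].b, faces[f].c, p) > dtol)
        vis.push_back((int)f);
    }
    if (vis.empty()) continue;  // inside current hull
    // horizon = directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int, int>, int> edge;
    bool consistent = true;
    for (size_t vi = 0; vi < vis.size(); ++vi) {
      const Face& f = faces[vis[vi]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; ++k)
        if (++edge[std::make_pair(e[k][0], e[k][1])] > 1) consistent = false;
    }
    // a duplicated directed edge means numerically inconsistent
    // visibility (sliver faces from near-coplanar points); such a point
    // lies on the hull boundary within tolerance — skip it
    if (!consistent) continue;
    for (size_t vi = 0; vi < vis.size(); ++vi) faces[vis[vi]].alive = false;
    for (std::map<std::pair<int, int>, int>::iterator it = edge.begin();
         it != edge.end(); ++it) {
      std::pair<int, int> rev(it->first.second, it->first.first);
      if (edge.find(rev) == edge.end())   // boundary (horizon) edge
        faces.push_back({it->first.first, it->first.second, p, true});
    }
  }

  double vol = 0.0, area = 0.0;
  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].alive) ++nf;
  IntegerMatrix fm(nf, 3);
  int r = 0;
  // reference point inside the hull: centroid of the initial tetrahedron
  double rx = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
  double ry = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
  double rz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    const Face& fc = faces[f];
    double u[3] = {X[fc.b] - X[fc.a], Y[fc.b] - Y[fc.a], Z[fc.b] - Z[fc.a]};
    double v[3] = {X[fc.c] - X[fc.a], Y[fc.c] - Y[fc.a], Z[fc.c] - Z[fc.a]};
    double nrm[3];
    cross3(u, v, nrm);
    double a2 = std::sqrt(nrm[0] * nrm[0] + nrm[1] * nrm[1] + nrm[2] * nrm[2]);
    area += 0.5 * a2;
    double w[3] = {X[fc.a] - rx, Y[fc.a] - ry, Z[fc.a] - rz};
    vol += (nrm[0] * w[0] + nrm[1] * w[1] + nrm[2] * w[2]) / 6.0;
    fm(r, 0) = fc.a + 1; fm(r, 1) = fc.b + 1; fm(r, 2) = fc.c + 1;
    ++r;
  }
  return List::create(_["volume"] = std::fabs(vol), _["area"] = area,
                      _["faces"] = fm, _["reason"] = "");
}
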