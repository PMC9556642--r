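// 3D convex hull volume via randomized incremental construction
// (beneath-beyond). Point clouds here are small (~100 points per analysis
// window), so no conflict lists are needed. Degenerate (coplanar or lower
// dimensional) inputs return volume 0.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

struct Facet {
  int a, b, c;        // vertex indices, oriented so normal points outward
  double nx, ny, nz;  // outward normal (not normalized)
  double off;         // plane offset: n . x = off
  bool alive;
};

static inline void facet_plane(Facet &f, const std::vector<double> &X,
                               const std::vector<double> &Y,
                               const std::vector<double> &Z) {
  double ux = X[f.b] - X[f.a], uy = Y[f.b] - Y[f.a], uz = Z[f.b] - Z[f.a];
  double vx = X[f.c] - X[f.a], vy = Y[f.c] - Y[f.a], vz = Z[f.c] - Z[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * X[f.a] + f.ny * Y[f.a] + f.nz * Z[f.a];
}

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) stop("need at least 4 points");
  std::vector<double> X(n), Y(n), Z(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2);
    scale = std::max(scale, std::abs(X[i]));
    scale = std::max(scale, std::abs(Y[i]));
    scale = std::max(scale, std::abs(Z[i]));
  }
  if (scale == 0.0) scale = 1.0;
  const double eps = 1e-10 * scale * scale * scale;

  // initial simplex: first point, farthest point, max-area third,
  // max-volume fourth
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = 0.0;
  for (int i = 1; i < n; ++i) {
    double d = std::abs(X[i] - X[i0]) + std::abs(Y[i] - Y[i0]) +
               std::abs(Z[i] - Z[i0]);
    if (d > best) { best = d; i1 = i; }
  }
  if (i1 < 0 || best <= 1e-12 * scale) return 0.0;
  best = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ux = X[i1] - X[i0], uy = Y[i1] - Y[i0], uz = Z[i1] - Z[i0];
    double vx = X[i] - X[i0], vy = Y[i] - Y[i0], vz = Z[i] - Z[i0];
    double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
           cz = ux * vy - uy * vx;
    double a2 = cx * cx + cy * cy + cz * cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (i2 < 0 || best <= 1e-20 * scale * scale * scale * scale) return 0.0;
  Facet base{i0, i1, i2, 0, 0, 0, 0, true};
  facet_plane(base, X, Y, Z);
  best = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = std::abs(base.nx * X[i] + base.ny * Y[i] + base.nz * Z[i] -
                        base.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0 || best <= eps) return 0.0;  // all points coplanar

  // interior reference point
  double cx = (X[i0] + X[i1] + X[i2] + X[i3]) / 4.0;
  double cy = (Y[i0] + Y[i1] + Y[i2] + Y[i3]) / 4.0;
  double cz = (Z[i0] + Z[i1] + Z[i2] + Z[i3]) / 4.0;

  std::vector<Facet> facets;
  int tet[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (auto &t : tet) {
    Facet f{t[0], t[1], t[2], 0, 0, 0, 0, true};
    facet_plane(f, X, Y, Z);
    if (f.nx * cx + f.ny * cy + f.nz * cz - f.off > 0) {  // flip outward
      std::swap(f.b, f.c);
      facet_plane(f, X, Y, Z);
    }
    facets.push_back(f);
  }

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<int> visible;
    for (size_t k = 0; k < facets.size(); ++k) {
      if (!facets[k].alive) continue;
      double d = facets[k].nx * X[p] + facets[k].ny * Y[p] +
                 facets[k].nz * Z[p] - facets[k].off;
      if (d > eps) visible.push_back((int)k);
    }
    if (visible.empty()) continue;  // inside (or on) the current hull
    // horizon = edges of visible facets not shared with another visible one
    std::vector<std::array<int, 2>> horizon;
    for (int k : visible) {
      int vs[3][2] = {{facets[k].a, facets[k].b},
                      {facets[k].b, facets[k].c},
                      {facets[k].c, facets[k].a}};
      for (auto &e : vs) {
        bool shared = false;
        for (int k2 : visible) {
          if (k2 == k) continue;
          const Facet &g = facets[k2];
          int gv[3][2] = {{g.a, g.b}, {g.b, g.c}, {g.c, g.a}};
          for (auto &e2 : gv)
            if (e2[0] == e[1] && e2[1] == e[0]) { shared = true; break; }
          if (shared) break;
        }
        if (!shared) horizon.push_back({e[0], e[1]});
      }
    }
    for (int k : visible) facets[k].alive = false;
    for (auto &e : horizon) {
      Facet f{e[0], e[1], p, 0, 0, 0, 0, true};
      facet_plane(f, X, Y, Z);
      if (f.nx * cx + f.ny * cy + f.nz * cz - f.off > 0) {
        std::swap(f.b, f.c);
        facet_plane(f, X, Y, Z);
      }
      facets.push_back(f);
    }
  }

  // volume: sum of signed tetrahedra (facet, interior point)
  double vol6 = 0.0;
  for (const Facet &f : facets) {
    if (!f.alive) continue;
    double ax = X[f.a] - cx, ay = Y[f.a] - cy, az = Z[f.a] - cz;
    double bx = X[f.b] - cx, by = Y[f.b] - cy, bz = Z[f.b] - cz;
    double qx = X[f.c] - cx, qy = Y[f.c] - cy, qz = Z[f.c] - cz;
    vol6 += ax * (by * qz - bz * qy) - ay * (bx * qz - bz * qx) +
            az * (bx * qy - by * qx);
  }
  return vol6 / 6.0;
}
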