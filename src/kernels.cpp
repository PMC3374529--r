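// Compiled geometry kernels: point-triangle queries, silhouette
// rasterization, parity voxelization, distance transforms, marching
// tetrahedra and the relaxed-constraint tissue solver.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3 &o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3 &o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision Detection.
Vec3 closest_on_triangle(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

struct TriSoup {
  std::vector<Vec3> v;
  std::vector<int> f; // 3 per face, 0-based

  void load(const NumericMatrix &V, const IntegerMatrix &F) {
    int nv = V.nrow(), nf = F.nrow();
    v.resize(nv);
    for (int i = 0; i < nv; ++i) v[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
    f.resize(3 * nf);
    for (int i = 0; i < nf; ++i) {
      f[3 * i] = F(i, 0);
      f[3 * i + 1] = F(i, 1);
      f[3 * i + 2] = F(i, 2);
    }
  }
  int nfaces() const { return (int)f.size() / 3; }
};

// Uniform grid over triangle bounding boxes for closest-point queries.
struct TriGrid {
  const TriSoup &mesh;
  double lo[3], hi[3], cell;
  int dims[3];
  std::vector<std::vector<int> > bins;

  TriGrid(const TriSoup &m) : mesh(m) {
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::numeric_limits<double>::infinity();
      hi[d] = -std::numeric_limits<double>::infinity();
    }
    double mean_ext = 0.0;
    int nf = mesh.nfaces();
    for (size_t i = 0; i < mesh.v.size(); ++i) {
      const Vec3 &p = mesh.v[i];
      double c[3] = {p.x, p.y, p.z};
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], c[d]);
        hi[d] = std::max(hi[d], c[d]);
      }
    }
    for (int i = 0; i < nf; ++i) {
      const Vec3 &a = mesh.v[mesh.f[3 * i]];
      const Vec3 &b = mesh.v[mesh.f[3 * i + 1]];
      const Vec3 &c = mesh.v[mesh.f[3 * i + 2]];
      double ext = std::max(norm(b - a), std::max(norm(c - b), norm(a - c)));
      mean_ext += ext;
    }
    mean_ext = nf > 0 ? mean_ext / nf : 1.0;
    cell = std::max(mean_ext, 1e-6);
    for (int d = 0; d < 3; ++d) {
      double span = hi[d] - lo[d];
      dims[d] = std::max(1, std::min(128, (int)std::ceil(span / cell)));
    }
    // recompute cell so grid covers the bbox exactly per axis (use max)
    double cmax = cell;
    for (int d = 0; d < 3; ++d) {
      double span = std::max(hi[d] - lo[d], 1e-9);
      cmax = std::max(cmax, span / dims[d]);
    }
    cell = cmax * 1.0000001;
    bins.assign((size_t)dims[0] * dims[1] * dims[2], std::vector<int>());
    for (int i = 0; i < nf; ++i) {
      const Vec3 *tv[3] = {&mesh.v[mesh.f[3 * i]], &mesh.v[mesh.f[3 * i + 1]], &mesh.v[mesh.f[3 * i + 2]]};
      double tlo[3], thi[3];
      for (int d = 0; d < 3; ++d) {
        double c0[3] = {tv[0]->x, tv[0]->y, tv[0]->z};
        double c1[3] = {tv[1]->x, tv[1]->y, tv[1]->z};
        double c2[3] = {tv[2]->x, tv[2]->y, tv[2]->z};
        tlo[d] = std::min(c0[d], std::min(c1[d], c2[d]));
        thi[d] = std::max(c0[d], std::max(c1[d], c2[d]));
      }
      int i0[3], i1[3];
      for (int d = 0; d < 3; ++d) {
        i0[d] = clampi((int)std::floor((tlo[d] - lo[d]) / cell), dims[d]);
        i1[d] = clampi((int)std::floor((thi[d] - lo[d]) / cell), dims[d]);
      }
      for (int x = i0[0]; x <= i1[0]; ++x)
        for (int y = i0[1]; y <= i1[1]; ++y)
          for (int z = i0[2]; z <= i1[2]; ++z)
            bins[idx(x, y, z)].push_back(i);
    }
  }

  static int clampi(int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); }
  size_t idx(int x, int y, int z) const {
    return (size_t)x + (size_t)dims[0] * ((size_t)y + (size_t)dims[1] * z);
  }
  double cell_dist(const Vec3 &p, int x, int y, int z) const {
    double d2 = 0.0;
    double pc[3] = {p.x, p.y, p.z};
    int ic[3] = {x, y, z};
    for (int d = 0; d < 3; ++d) {
      double c0 = lo[d] + ic[d] * cell, c1 = c0 + cell;
      if (pc[d] < c0) d2 += (c0 - pc[d]) * (c0 - pc[d]);
      else if (pc[d] > c1) d2 += (pc[d] - c1) * (pc[d] - c1);
    }
    return std::sqrt(d2);
  }

  void query(const Vec3 &p, double &best_d, Vec3 &best_q, int &best_f) const {
    best_d = std::numeric_limits<double>::infinity();
    best_f = -1;
    int cx = clampi((int)std::floor((p.x - lo[0]) / cell), dims[0]);
    int cy = clampi((int)std::floor((p.y - lo[1]) / cell), dims[1]);
    int cz = clampi((int)std::floor((p.z - lo[2]) / cell), dims[2]);
    int max_ring = std::max(dims[0], std::max(dims[1], dims[2]));
    for (int r = 0; r <= max_ring; ++r) {
      double ring_min = std::numeric_limits<double>::infinity();
      bool any = false;
      for (int x = cx - r; x <= cx + r; ++x) {
        if (x < 0 || x >= dims[0]) continue;
        for (int y = cy - r; y <= cy + r; ++y) {
          if (y < 0 || y >= dims[1]) continue;
          for (int z = cz - r; z <= cz + r; ++z) {
            if (z < 0 || z >= dims[2]) continue;
            int cheb = std::max(std::abs(x - cx), std::max(std::abs(y - cy), std::abs(z - cz)));
            if (cheb != r) continue;
            any = true;
            double cd = cell_dist(p, x, y, z);
            ring_min = std::min(ring_min, cd);
            if (cd >= best_d) continue;
            const std::vector<int> &tris = bins[idx(x, y, z)];
            for (size_t t = 0; t < tris.size(); ++t) {
              int fi = tris[t];
              Vec3 q = closest_on_triangle(p, mesh.v[mesh.f[3 * fi]],
                                           mesh.v[mesh.f[3 * fi + 1]],
                                           mesh.v[mesh.f[3 * fi + 2]]);
              double d = norm(p - q);
              if (d < best_d) { best_d = d; best_q = q; best_f = fi; }
            }
          }
        }
      }
      if (best_f >= 0 && any && ring_min > best_d) break;
      // if the ring is entirely outside the grid and we have an answer, stop
      if (!any && best_f >= 0) break;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_closest_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriSoup soup;
  soup.load(V, F);
  TriGrid grid(soup);
  int n = P.nrow();
  NumericVector dist(n);
  NumericMatrix closest(n, 3);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2)), q;
    double d;
    int fi;
    grid.query(p, d, q, fi);
    dist[i] = d;
    closest(i, 0) = q.x;
    closest(i, 1) = q.y;
    closest(i, 2) = q.z;
    face[i] = fi + 1; // 1-based for R
  }
  return List::create(_["distance"] = dist, _["closest"] = closest, _["face"] = face);
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist_brute(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  TriSoup soup;
  soup.load(V, F);
  int n = P.nrow(), nf = soup.nfaces();
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2));
    double best = std::numeric_limits<double>::infinity();
    for (int t = 0; t < nf; ++t) {
      Vec3 q = closest_on_triangle(p, soup.v[soup.f[3 * t]], soup.v[soup.f[3 * t + 1]],
                                   soup.v[soup.f[3 * t + 2]]);
      best = std::min(best, norm(p - q));
    }
    dist[i] = best;
  }
  return dist;
}

// Fill pixels whose centers fall inside any projected triangle.
// U: nvert x 2 continuous pixel coords (u = column axis, v = row axis),
// pixel (r, c) 1-based has center (c - 0.5, r - 0.5).
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize(NumericMatrix U, IntegerMatrix F, int nrow, int ncol) {
  LogicalMatrix img(nrow, ncol);
  int nf = F.nrow();
  for (int t = 0; t < nf; ++t) {
    double ax = U(F(t, 0), 0), ay = U(F(t, 0), 1);
    double bx = U(F(t, 1), 0), by = U(F(t, 1), 1);
    double cx = U(F(t, 2), 0), cy = U(F(t, 2), 1);
    double lox = std::min(ax, std::min(bx, cx)), hix = std::max(ax, std::max(bx, cx));
    double loy = std::min(ay, std::min(by, cy)), hiy = std::max(ay, std::max(by, cy));
    int c0 = std::max(1, (int)std::floor(lox + 0.5)), c1 = std::min(ncol, (int)std::ceil(hix + 0.5));
    int r0 = std::max(1, (int)std::floor(loy + 0.5)), r1 = std::min(nrow, (int)std::ceil(hiy + 0.5));
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-14) continue;
    for (int r = r0; r <= r1; ++r) {
      double py = r - 0.5;
      for (int c = c0; c <= c1; ++c) {
        if (img(r - 1, c - 1)) continue;
        double px = c - 0.5;
        double w0 = ((bx - px) * (cy - py) - (by - py) * (cx - px)) / det;
        double w1 = ((cx - px) * (ay - py) - (cy - py) * (ax - px)) / det;
        double w2 = 1.0 - w0 - w1;
        const double eps = -1e-9;
        if (w0 >= eps && w1 >= eps && w2 >= eps)
          img(r - 1, c - 1) = true;
      }
    }
  }
  return img;
}

// Inside/outside by ray parity along +z for every voxel column.
// Returns list(inside = logical, ambiguous = count of odd-parity columns).
// [[Rcpp::export]]
List cpp_voxel_inside(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                      double spacing, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::vector<double> > cross_z((size_t)nx * ny);
  int nf = F.nrow();
  // deterministic sub-voxel shift keeps rays off shared edges/vertices;
  // its sign follows the side of the grid centre so a mirror-symmetric
  // mesh classifies mirror-symmetrically
  const double ex0 = 0.371229 * spacing * 1e-3, ey0 = 0.614159 * spacing * 1e-3;
  const double cxg = origin[0] + 0.5 * nx * spacing;
  const double cyg = origin[1] + 0.5 * ny * spacing;
  for (int t = 0; t < nf; ++t) {
    double ax = V(F(t, 0), 0), ay = V(F(t, 0), 1), az = V(F(t, 0), 2);
    double bx = V(F(t, 1), 0), by = V(F(t, 1), 1), bz = V(F(t, 1), 2);
    double cx = V(F(t, 2), 0), cy = V(F(t, 2), 1), cz = V(F(t, 2), 2);
    double lox = std::min(ax, std::min(bx, cx)), hix = std::max(ax, std::max(bx, cx));
    double loy = std::min(ay, std::min(by, cy)), hiy = std::max(ay, std::max(by, cy));
    int i0 = std::max(0, (int)std::floor((lox - origin[0]) / spacing - 0.5) - 1);
    int i1 = std::min(nx - 1, (int)std::ceil((hix - origin[0]) / spacing - 0.5) + 1);
    int j0 = std::max(0, (int)std::floor((loy - origin[1]) / spacing - 0.5) - 1);
    int j1 = std::min(ny - 1, (int)std::ceil((hiy - origin[1]) / spacing - 0.5) + 1);
    double det = (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
    if (std::fabs(det) < 1e-14) continue;
    for (int j = j0; j <= j1; ++j) {
      double py0 = origin[1] + (j + 0.5) * spacing;
      double py = py0 + (py0 >= cyg ? ey0 : -ey0);
      for (int i = i0; i <= i1; ++i) {
        double px0 = origin[0] + (i + 0.5) * spacing;
        double px = px0 + (px0 >= cxg ? ex0 : -ex0);
        double w0 = ((bx - px) * (cy - py) - (by - py) * (cx - px)) / det;
        double w1 = ((cx - px) * (ay - py) - (cy - py) * (ax - px)) / det;
        double w2 = 1.0 - w0 - w1;
        if (w0 >= 0 && w1 >= 0 && w2 >= 0) {
          // w0, w1, w2 weight vertices a, b, c; clamp to the triangle's
          // z-range so near-z-parallel slivers cannot amplify roundoff
          double z = w0 * az + w1 * bz + w2 * cz;
          double zlo = std::min(az, std::min(bz, cz));
          double zhi = std::max(az, std::max(bz, cz));
          if (z < zlo) z = zlo;
          if (z > zhi) z = zhi;
          cross_z[(size_t)i + (size_t)nx * j].push_back(z);
        }
      }
    }
  }
  LogicalVector inside((size_t)nx * ny * nz);
  int ambiguous = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      std::vector<double> &zs = cross_z[(size_t)i + (size_t)nx * j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      size_t m = zs.size();
      if (m % 2 == 1) { ++ambiguous; m -= 1; }
      for (size_t p = 0; p + 1 < m; p += 2) {
        double z0 = zs[p], z1 = zs[p + 1];
        int k0 = std::max(0, (int)std::ceil((z0 - origin[2]) / spacing - 0.5));
        int k1 = std::min(nz - 1, (int)std::floor((z1 - origin[2]) / spacing - 0.5));
        for (int k = k0; k <= k1; ++k)
          inside[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = true;
      }
    }
  }
  return List::create(_["inside"] = inside, _["ambiguous"] = ambiguous);
}

namespace {
// Felzenszwalb & Huttenlocher 1D squared distance transform.
void dt1d(std::vector<double> &f, std::vector<double> &d, std::vector<int> &v,
          std::vector<double> &zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}
} // namespace

// Squared euclidean distance (in voxel units) from every voxel to the
// nearest voxel where feature == TRUE.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  const double INF = 1e20;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : INF;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)nx * ((size_t)j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, zb, nx);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
      dt1d(f, d, v, zb, ny);
      for (int j = 0; j < ny; ++j) g[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
      dt1d(f, d, v, zb, nz);
      for (int k = 0; k < nz; ++k) g[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = d[k];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}

namespace {
struct MTVert {
  long long key;
  double f;
  Vec3 p;
};

struct MTOut {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::map<long long, int> edge_vert;
};

int edge_vertex(MTOut &out, const MTVert &a, const MTVert &b, long long M,
                double iso) {
  long long ka = a.key, kb = b.key;
  long long key = ka < kb ? ka * M + kb : kb * M + ka;
  std::map<long long, int>::iterator it = out.edge_vert.find(key);
  if (it != out.edge_vert.end()) return it->second;
  double t = (iso - a.f) / (b.f - a.f);
  // keep vertices strictly inside edges so no emitted triangle degenerates
  if (t < 1e-3) t = 1e-3;
  if (t > 1 - 1e-3) t = 1 - 1e-3;
  Vec3 p = a.p + (b.p - a.p) * t;
  int id = (int)out.vx.size();
  out.vx.push_back(p.x);
  out.vy.push_back(p.y);
  out.vz.push_back(p.z);
  out.edge_vert[key] = id;
  return id;
}

void emit_tri(MTOut &out, int a, int b, int c, const Vec3 &grad) {
  Vec3 pa(out.vx[a], out.vy[a], out.vz[a]);
  Vec3 pb(out.vx[b], out.vy[b], out.vz[b]);
  Vec3 pc(out.vx[c], out.vy[c], out.vz[c]);
  Vec3 n = cross(pb - pa, pc - pa);
  if (dot(n, grad) < 0) std::swap(b, c);
  out.tri.push_back(a);
  out.tri.push_back(b);
  out.tri.push_back(c);
}

// order-independent sum so mirrored cubes average to identical values
double stable_avg(const double *v, int n) {
  std::vector<double> s(v, v + n);
  std::sort(s.begin(), s.end());
  double acc = 0;
  for (int i = 0; i < n; ++i) acc += s[i];
  return acc / n;
}

void march_one_tet(MTOut &out, const MTVert v[4], long long M, double iso) {
  bool in[4];
  int nin = 0;
  for (int q = 0; q < 4; ++q) {
    in[q] = v[q].f < iso;
    if (in[q]) ++nin;
  }
  if (nin == 0 || nin == 4) return;
  // affine gradient inside the tet (rows of m are edge vectors)
  double m[3][3] = {
    {v[1].p.x - v[0].p.x, v[1].p.y - v[0].p.y, v[1].p.z - v[0].p.z},
    {v[2].p.x - v[0].p.x, v[2].p.y - v[0].p.y, v[2].p.z - v[0].p.z},
    {v[3].p.x - v[0].p.x, v[3].p.y - v[0].p.y, v[3].p.z - v[0].p.z}
  };
  double rhs[3] = {v[1].f - v[0].f, v[2].f - v[0].f, v[3].f - v[0].f};
  double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1])
             - m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0])
             + m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  Vec3 grad(0, 0, 1);
  if (std::fabs(det) > 1e-20) {
    double inv[3][3];
    inv[0][0] = (m[1][1] * m[2][2] - m[1][2] * m[2][1]) / det;
    inv[0][1] = (m[0][2] * m[2][1] - m[0][1] * m[2][2]) / det;
    inv[0][2] = (m[0][1] * m[1][2] - m[0][2] * m[1][1]) / det;
    inv[1][0] = (m[1][2] * m[2][0] - m[1][0] * m[2][2]) / det;
    inv[1][1] = (m[0][0] * m[2][2] - m[0][2] * m[2][0]) / det;
    inv[1][2] = (m[0][2] * m[1][0] - m[0][0] * m[1][2]) / det;
    inv[2][0] = (m[1][0] * m[2][1] - m[1][1] * m[2][0]) / det;
    inv[2][1] = (m[0][1] * m[2][0] - m[0][0] * m[2][1]) / det;
    inv[2][2] = (m[0][0] * m[1][1] - m[0][1] * m[1][0]) / det;
    grad = Vec3(inv[0][0] * rhs[0] + inv[0][1] * rhs[1] + inv[0][2] * rhs[2],
                inv[1][0] * rhs[0] + inv[1][1] * rhs[1] + inv[1][2] * rhs[2],
                inv[2][0] * rhs[0] + inv[2][1] * rhs[1] + inv[2][2] * rhs[2]);
  }
  int vin[4], vout[4], ni = 0, no = 0;
  for (int q = 0; q < 4; ++q) {
    if (in[q]) vin[ni++] = q; else vout[no++] = q;
  }
  if (nin == 1) {
    int s = vin[0];
    int e0 = edge_vertex(out, v[s], v[vout[0]], M, iso);
    int e1 = edge_vertex(out, v[s], v[vout[1]], M, iso);
    int e2 = edge_vertex(out, v[s], v[vout[2]], M, iso);
    emit_tri(out, e0, e1, e2, grad);
  } else if (nin == 3) {
    int s = vout[0];
    int e0 = edge_vertex(out, v[s], v[vin[0]], M, iso);
    int e1 = edge_vertex(out, v[s], v[vin[1]], M, iso);
    int e2 = edge_vertex(out, v[s], v[vin[2]], M, iso);
    emit_tri(out, e0, e1, e2, grad);
  } else { // nin == 2
    int a0 = vin[0], a1 = vin[1], b0 = vout[0], b1 = vout[1];
    int e00 = edge_vertex(out, v[a0], v[b0], M, iso);
    int e01 = edge_vertex(out, v[a0], v[b1], M, iso);
    int e10 = edge_vertex(out, v[a1], v[b0], M, iso);
    int e11 = edge_vertex(out, v[a1], v[b1], M, iso);
    emit_tri(out, e00, e01, e11, grad);
    emit_tri(out, e00, e11, e10, grad);
  }
}
} // namespace

// Marching tetrahedra over a node-centred scalar field using the
// body-centred 24-tet cube decomposition (face centres + body centre),
// which is invariant under axis reflections: a mirror-symmetric field
// yields an exactly mirror-symmetric surface. Inside = field < iso;
// triangle normals follow the field gradient (toward "outside").
// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, NumericVector origin,
                    double spacing, double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long long N = (long long)nx * ny * nz;
  long long M = 5LL * N;
  MTOut out;
  // face corner cycles (corner bit order dx + 2 dy + 4 dz), with the axis
  // each face is perpendicular to
  static const int faces[6][5] = {
    {0, 2, 6, 4, 0}, {1, 3, 7, 5, 0},  // x- and x+ faces
    {0, 1, 5, 4, 1}, {2, 3, 7, 6, 1},  // y- and y+ faces
    {0, 1, 3, 2, 2}, {4, 5, 7, 6, 2}   // z- and z+ faces
  };
  std::vector<double> fv(field.begin(), field.end());
  for (size_t i = 0; i < fv.size(); ++i)
    if (std::fabs(fv[i] - iso) < 1e-12) fv[i] = iso + 1e-9;
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        long long gid[8];
        double f[8];
        Vec3 p[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          long long g = (long long)(i + dx) + (long long)nx * ((long long)(j + dy) + (long long)ny * (k + dz));
          gid[c] = g;
          f[c] = fv[(size_t)g];
          p[c] = Vec3(origin[0] + (i + dx) * spacing, origin[1] + (j + dy) * spacing,
                      origin[2] + (k + dz) * spacing);
          if (f[c] < iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        MTVert body;
        body.key = 4LL * N + gid[0];
        body.f = stable_avg(f, 8);
        if (std::fabs(body.f - iso) < 1e-12) body.f = iso + 1e-9;
        body.p = Vec3(origin[0] + (i + 0.5) * spacing, origin[1] + (j + 0.5) * spacing,
                      origin[2] + (k + 0.5) * spacing);
        for (int fc = 0; fc < 6; ++fc) {
          const int *cyc = faces[fc];
          int axis = faces[fc][4];
          double fcv[4] = {f[cyc[0]], f[cyc[1]], f[cyc[2]], f[cyc[3]]};
          MTVert face;
          long long gmin = gid[cyc[0]];
          for (int q = 1; q < 4; ++q) gmin = std::min(gmin, gid[cyc[q]]);
          face.key = (long long)(1 + axis) * N + gmin;
          face.f = stable_avg(fcv, 4);
          if (std::fabs(face.f - iso) < 1e-12) face.f = iso + 1e-9;
          face.p = (p[cyc[0]] + p[cyc[1]] + p[cyc[2]] + p[cyc[3]]) * 0.25;
          for (int e = 0; e < 4; ++e) {
            int c0 = cyc[e], c1 = cyc[(e + 1) % 4];
            MTVert v[4];
            v[0].key = gid[c0]; v[0].f = f[c0]; v[0].p = p[c0];
            v[1].key = gid[c1]; v[1].f = f[c1]; v[1].p = p[c1];
            v[2] = face;
            v[3] = body;
            march_one_tet(out, v, M, iso);
          }
        }
      }
    }
  }
  int nv = (int)out.vx.size(), nf = (int)out.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = out.vx[i];
    V(i, 1) = out.vy[i];
    V(i, 2) = out.vz[i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = out.tri[3 * i];
    F(i, 1) = out.tri[3 * i + 1];
    F(i, 2) = out.tri[3 * i + 2];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// For each row of A (n x 2), squared-min distance to rows of B (m x 2).
// [[Rcpp::export]]
NumericVector cpp_nn2d(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ax = A(i, 0), ay = A(i, 1);
    double best = std::numeric_limits<double>::infinity();
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1);
      double d = dx * dx + dy * dy;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

namespace {
double cell_volume(const std::vector<double> &px, const std::vector<double> &py,
                   const std::vector<double> &pz, const int *c) {
  // average edge vectors of the hexahedral cell (corner bit order x+2y+4z)
  double ex[3] = {0, 0, 0}, ey[3] = {0, 0, 0}, ez[3] = {0, 0, 0};
  static const int xp[4][2] = {{0, 1}, {2, 3}, {4, 5}, {6, 7}};
  static const int yp[4][2] = {{0, 2}, {1, 3}, {4, 6}, {5, 7}};
  static const int zp[4][2] = {{0, 4}, {1, 5}, {2, 6}, {3, 7}};
  for (int q = 0; q < 4; ++q) {
    ex[0] += px[c[xp[q][1]]] - px[c[xp[q][0]]];
    ex[1] += py[c[xp[q][1]]] - py[c[xp[q][0]]];
    ex[2] += pz[c[xp[q][1]]] - pz[c[xp[q][0]]];
    ey[0] += px[c[yp[q][1]]] - px[c[yp[q][0]]];
    ey[1] += py[c[yp[q][1]]] - py[c[yp[q][0]]];
    ey[2] += pz[c[yp[q][1]]] - pz[c[yp[q][0]]];
    ez[0] += px[c[zp[q][1]]] - px[c[zp[q][0]]];
    ez[1] += py[c[zp[q][1]]] - py[c[zp[q][0]]];
    ez[2] += pz[c[zp[q][1]]] - pz[c[zp[q][0]]];
  }
  for (int d = 0; d < 3; ++d) { ex[d] *= 0.25; ey[d] *= 0.25; ez[d] *= 0.25; }
  return ex[0] * (ey[1] * ez[2] - ey[2] * ez[1])
       - ex[1] * (ey[0] * ez[2] - ey[2] * ez[0])
       + ex[2] * (ey[0] * ez[1] - ey[1] * ez[0]);
}
} // namespace

// [[Rcpp::export]]
NumericVector cpp_cell_volumes(NumericMatrix pos, IntegerMatrix cells) {
  int nc = cells.nrow();
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2); }
  NumericVector out(nc);
  for (int c = 0; c < nc; ++c) {
    int idx[8];
    for (int q = 0; q < 8; ++q) idx[q] = cells(c, q);
    out[c] = cell_volume(px, py, pz, idx);
  }
  return out;
}

// Relaxed-constraint (position-based) tissue solver. Jacobi accumulation so
// the sweep is order-independent: deterministic and mirror-symmetric.
// [[Rcpp::export]]
List cpp_tem_solve(NumericMatrix pos0, NumericMatrix rest, NumericVector invmass,
                   IntegerMatrix edges, NumericVector edge_len0, NumericVector edge_k,
                   IntegerMatrix cells, NumericVector cell_v0, double cell_k,
                   IntegerMatrix bend, NumericMatrix bend_off, NumericVector bend_k,
                   NumericVector anchor_k,
                   NumericMatrix ellipsoids, double collide_k, LogicalVector collidable,
                   NumericVector gravity, int max_iter, double tol, double omega,
                   int divergence_window) {
  int n = pos0.nrow();
  std::vector<double> px(n), py(n), pz(n), rx(n), ry(n), rz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1); pz[i] = pos0(i, 2);
    rx[i] = rest(i, 0); ry[i] = rest(i, 1); rz[i] = rest(i, 2);
  }
  int ne = edges.nrow(), ncl = cells.nrow(), nb = bend.nrow(), nell = ellipsoids.nrow();
  std::vector<int> e1(ne), e2(ne);
  for (int e = 0; e < ne; ++e) { e1[e] = edges(e, 0); e2[e] = edges(e, 1); }
  std::vector<double> dx(n), dy(n), dz(n), w(n);
  bool grav_on = (std::fabs(gravity[0]) + std::fabs(gravity[1]) + std::fabs(gravity[2])) > 0;
  double maxdisp = 0.0, prev_maxdisp = std::numeric_limits<double>::infinity();
  int grow_run = 0, iter = 0;
  bool converged = false, diverged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    std::fill(dx.begin(), dx.end(), 0.0);
    std::fill(dy.begin(), dy.end(), 0.0);
    std::fill(dz.begin(), dz.end(), 0.0);
    std::fill(w.begin(), w.end(), 0.0);
    // stretch
    for (int e = 0; e < ne; ++e) {
      int a = e1[e], b = e2[e];
      double vx = px[b] - px[a], vy = py[b] - py[a], vz = pz[b] - pz[a];
      double L = std::sqrt(vx * vx + vy * vy + vz * vz);
      if (L < 1e-12) continue;
      double wa = invmass[a], wb = invmass[b];
      double ws = wa + wb;
      if (ws <= 0) continue;
      double C = L - edge_len0[e];
      double k = edge_k[e];
      double s = C / L;
      dx[a] += k * (wa / ws) * s * vx; dy[a] += k * (wa / ws) * s * vy; dz[a] += k * (wa / ws) * s * vz;
      dx[b] -= k * (wb / ws) * s * vx; dy[b] -= k * (wb / ws) * s * vy; dz[b] -= k * (wb / ws) * s * vz;
      w[a] += k; w[b] += k;
    }
    // relaxed volume restoration per hexahedral cell
    if (cell_k > 0) {
      for (int c = 0; c < ncl; ++c) {
        int idx[8];
        double cx = 0, cy = 0, cz = 0;
        for (int q = 0; q < 8; ++q) {
          idx[q] = cells(c, q);
          cx += px[idx[q]]; cy += py[idx[q]]; cz += pz[idx[q]];
        }
        cx /= 8.0; cy /= 8.0; cz /= 8.0;
        double V = cell_volume(px, py, pz, idx);
        if (V < 1e-9) V = 1e-9;
        double s = std::cbrt(cell_v0[c] / V);
        if (s < 0.5) s = 0.5;
        if (s > 2.0) s = 2.0;
        double g = s - 1.0;
        for (int q = 0; q < 8; ++q) {
          int i = idx[q];
          if (invmass[i] <= 0) continue;
          dx[i] += cell_k * g * (px[i] - cx);
          dy[i] += cell_k * g * (py[i] - cy);
          dz[i] += cell_k * g * (pz[i] - cz);
          w[i] += cell_k;
        }
      }
    }
    // skin shape-memory bending
    for (int b = 0; b < nb; ++b) {
      int ip = bend(b, 0), im = bend(b, 1), in_ = bend(b, 2);
      if (invmass[im] <= 0) continue;
      double k = bend_k[b];
      double tx = 0.5 * (px[ip] + px[in_]) + bend_off(b, 0);
      double ty = 0.5 * (py[ip] + py[in_]) + bend_off(b, 1);
      double tz = 0.5 * (pz[ip] + pz[in_]) + bend_off(b, 2);
      dx[im] += k * (tx - px[im]);
      dy[im] += k * (ty - py[im]);
      dz[im] += k * (tz - pz[im]);
      w[im] += k;
    }
    // anchors (near-rigid implant particles)
    for (int i = 0; i < n; ++i) {
      double k = anchor_k[i];
      if (k <= 0 || invmass[i] <= 0) continue;
      dx[i] += k * (rx[i] - px[i]);
      dy[i] += k * (ry[i] - py[i]);
      dz[i] += k * (rz[i] - pz[i]);
      w[i] += k;
    }
    // implant exclusion: push collidable tissue out of implant ellipsoids
    if (nell > 0 && collide_k > 0) {
      for (int i = 0; i < n; ++i) {
        if (!collidable[i] || invmass[i] <= 0) continue;
        for (int m = 0; m < nell; ++m) {
          double ox = px[i] - ellipsoids(m, 0);
          double oy = py[i] - ellipsoids(m, 1);
          double oz = pz[i] - ellipsoids(m, 2);
          // rotate into implant frame (rows of R stored row-major, cols 6..14)
          double lx = ellipsoids(m, 6) * ox + ellipsoids(m, 7) * oy + ellipsoids(m, 8) * oz;
          double ly = ellipsoids(m, 9) * ox + ellipsoids(m, 10) * oy + ellipsoids(m, 11) * oz;
          double lz = ellipsoids(m, 12) * ox + ellipsoids(m, 13) * oy + ellipsoids(m, 14) * oz;
          double qx = lx / ellipsoids(m, 3), qy = ly / ellipsoids(m, 4), qz = lz / ellipsoids(m, 5);
          double r = std::sqrt(qx * qx + qy * qy + qz * qz);
          if (r >= 1.0 || r < 1e-9) continue;
          double s = 1.0 / r;
          double nlx = qx * s * ellipsoids(m, 3), nly = qy * s * ellipsoids(m, 4), nlz = qz * s * ellipsoids(m, 5);
          // back to world frame (R^T since rows were applied)
          double wx = ellipsoids(m, 6) * nlx + ellipsoids(m, 9) * nly + ellipsoids(m, 12) * nlz;
          double wy = ellipsoids(m, 7) * nlx + ellipsoids(m, 10) * nly + ellipsoids(m, 13) * nlz;
          double wz = ellipsoids(m, 8) * nlx + ellipsoids(m, 11) * nly + ellipsoids(m, 14) * nlz;
          double txp = ellipsoids(m, 0) + wx, typ = ellipsoids(m, 1) + wy, tzp = ellipsoids(m, 2) + wz;
          dx[i] += collide_k * (txp - px[i]);
          dy[i] += collide_k * (typ - py[i]);
          dz[i] += collide_k * (tzp - pz[i]);
          w[i] += collide_k;
        }
      }
    }
    // apply
    maxdisp = 0.0;
    for (int i = 0; i < n; ++i) {
      if (invmass[i] <= 0) continue;
      double gx = grav_on ? gravity[0] : 0.0;
      double gy = grav_on ? gravity[1] : 0.0;
      double gz = grav_on ? gravity[2] : 0.0;
      double ddx = gx, ddy = gy, ddz = gz;
      if (w[i] > 0) {
        ddx += omega * dx[i] / w[i];
        ddy += omega * dy[i] / w[i];
        ddz += omega * dz[i] / w[i];
      }
      px[i] += ddx; py[i] += ddy; pz[i] += ddz;
      double d = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
      if (d > maxdisp) maxdisp = d;
    }
    if (maxdisp < tol) { converged = true; ++iter; break; }
    if (maxdisp > prev_maxdisp * (1.0 + 1e-12)) {
      ++grow_run;
      if (grow_run >= divergence_window) { diverged = true; ++iter; break; }
    } else {
      grow_run = 0;
    }
    prev_maxdisp = maxdisp;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i]; }
  return List::create(_["pos"] = out, _["iterations"] = iter,
                      _["converged"] = converged, _["diverged"] = diverged,
                      _["residual"] = maxdisp);
}
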