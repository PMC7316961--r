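// Geometric kernels: KD-tree nearest neighbour, triangle-mesh BVH
// (closest point / ray cast), z-column parity voxelization and a
// marching-tetrahedra isosurface. All coordinates are world millimetres.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------- KD-tree

struct KDTree {
  std::vector<double> pts;   // original coordinates, 3*i + d
  std::vector<double> tpts;  // coordinates in tree order (cache-friendly)
  std::vector<int> order;    // permutation defining the implicit tree
  int n = 0;

  double coord(int i, int d) const { return tpts[3 * (size_t)i + d]; }

  void buildRange(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    int mid = lo + (hi - lo) / 2;
    int d = depth % 3;
    const std::vector<double>& P = pts;
    std::nth_element(order.begin() + lo, order.begin() + mid,
                     order.begin() + hi,
                     [&](int a, int b) { return P[3 * a + d] < P[3 * b + d]; });
    buildRange(lo, mid, depth + 1);
    buildRange(mid + 1, hi, depth + 1);
  }

  void build(const NumericMatrix& P) {
    n = P.nrow();
    pts.resize(3 * (size_t)n);
    order.resize(n);
    for (int i = 0; i < n; ++i) {
      order[i] = i;
      pts[3 * (size_t)i]     = P(i, 0);
      pts[3 * (size_t)i + 1] = P(i, 1);
      pts[3 * (size_t)i + 2] = P(i, 2);
    }
    buildRange(0, n, 0);
    tpts.resize(3 * (size_t)n);
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        tpts[3 * (size_t)i + d] = pts[3 * (size_t)order[i] + d];
  }

  void nn(const double* q, int lo, int hi, int depth,
          double& bestD2, int& bestIdx) const {
    if (hi <= lo) return;
    int mid = lo + (hi - lo) / 2;
    int d = depth % 3;
    double dx = q[0] - coord(mid, 0), dy = q[1] - coord(mid, 1),
           dz = q[2] - coord(mid, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestD2) { bestD2 = d2; bestIdx = order[mid]; }
    double diff = q[d] - coord(mid, d);
    int nearLo = diff <= 0 ? lo : mid + 1, nearHi = diff <= 0 ? mid : hi;
    int farLo  = diff <= 0 ? mid + 1 : lo, farHi = diff <= 0 ? hi : mid;
    nn(q, nearLo, nearHi, depth + 1, bestD2, bestIdx);
    if (diff * diff < bestD2) nn(q, farLo, farHi, depth + 1, bestD2, bestIdx);
  }
};

// [[Rcpp::export]]
SEXP cpp_kdtree_build(NumericMatrix pts) {
  KDTree* t = new KDTree();
  t->build(pts);
  XPtr<KDTree> p(t, true);
  return p;
}

// [[Rcpp::export]]
List cpp_kdtree_query(SEXP tree, NumericMatrix query) {
  XPtr<KDTree> t(tree);
  int m = query.nrow();
  NumericVector dist(m);
  IntegerVector idx(m);
  double q[3];
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    double bestD2 = std::numeric_limits<double>::infinity();
    int bestIdx = -1;
    t->nn(q, 0, t->n, 0, bestD2, bestIdx);
    dist[i] = std::sqrt(bestD2);
    idx[i] = bestIdx + 1;  // 1-based for R
  }
  return List::create(_["distance"] = dist, _["index"] = idx);
}

// [[Rcpp::export]]
double cpp_kdtree_meansq(SEXP tree, NumericMatrix query) {
  XPtr<KDTree> t(tree);
  int m = query.nrow();
  double acc = 0.0, q[3];
  for (int i = 0; i < m; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    double bestD2 = std::numeric_limits<double>::infinity();
    int bestIdx = -1;
    t->nn(q, 0, t->n, 0, bestD2, bestIdx);
    acc += bestD2;
  }
  return acc / m;
}

// All (query, indexed-point) pairs within `radius`, with distances.
// Used to assemble sparse compact-support kernel matrices.
// [[Rcpp::export]]
List cpp_kdtree_pairs(SEXP tree, NumericMatrix query, double radius) {
  XPtr<KDTree> t(tree);
  std::vector<int> qi, pj;
  std::vector<double> dist;
  double r2 = radius * radius;
  // iterative stack over implicit tree segments
  struct Seg { int lo, hi, depth; };
  std::vector<Seg> stack;
  for (int i = 0; i < query.nrow(); ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    stack.clear();
    stack.push_back({0, t->n, 0});
    while (!stack.empty()) {
      Seg s = stack.back();
      stack.pop_back();
      if (s.hi <= s.lo) continue;
      int mid = s.lo + (s.hi - s.lo) / 2;
      int d = s.depth % 3;
      double dx = q[0] - t->coord(mid, 0), dy = q[1] - t->coord(mid, 1),
             dz = q[2] - t->coord(mid, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= r2) {
        qi.push_back(i + 1);
        pj.push_back(t->order[mid] + 1);
        dist.push_back(std::sqrt(d2));
      }
      double diff = q[d] - t->coord(mid, d);
      if (diff <= 0) {
        stack.push_back({s.lo, mid, s.depth + 1});
        if (diff * diff <= r2) stack.push_back({mid + 1, s.hi, s.depth + 1});
      } else {
        stack.push_back({mid + 1, s.hi, s.depth + 1});
        if (diff * diff <= r2) stack.push_back({s.lo, mid, s.depth + 1});
      }
    }
  }
  return List::create(_["i"] = IntegerVector(qi.begin(), qi.end()),
                      _["j"] = IntegerVector(pj.begin(), pj.end()),
                      _["d"] = NumericVector(dist.begin(), dist.end()));
}

// [[Rcpp::export]]
int cpp_kdtree_size(SEXP tree) {
  XPtr<KDTree> t(tree);
  return t->n;
}

// ---------------------------------------------------------------- triangle BVH

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}

// Closest point on triangle abc to p (Voronoi-region walk), with barycentrics.
static Vec3 closestPtTriangle(const Vec3& p, const Vec3& a, const Vec3& b,
                              const Vec3& c, double* bary) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { bary[0] = 1; bary[1] = 0; bary[2] = 0; return a; }
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { bary[0] = 0; bary[1] = 1; bary[2] = 0; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    bary[0] = 1 - v; bary[1] = v; bary[2] = 0;
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { bary[0] = 0; bary[1] = 0; bary[2] = 1; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    bary[0] = 1 - w; bary[1] = 0; bary[2] = w;
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    bary[0] = 0; bary[1] = 1 - w; bary[2] = w;
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  bary[0] = 1 - v - w; bary[1] = v; bary[2] = w;
  return a + ab * v + ac * w;
}

struct BVHNode {
  double bmin[3], bmax[3];
  int left = -1, right = -1;  // children; leaf iff left < 0
  int start = 0, count = 0;   // triangle range for leaves
};

struct MeshBVH {
  std::vector<Vec3> V;
  std::vector<int> F;        // 3*t + k, 0-based vertex ids
  std::vector<int> tri;      // triangle permutation
  std::vector<BVHNode> nodes;
  int ntri = 0;

  Vec3 vert(int t, int k) const { return V[F[3 * tri[t] + k]]; }

  int buildNode(int start, int count, std::vector<Vec3>& cent) {
    BVHNode nd;
    nd.bmin[0] = nd.bmin[1] = nd.bmin[2] = std::numeric_limits<double>::infinity();
    nd.bmax[0] = nd.bmax[1] = nd.bmax[2] = -std::numeric_limits<double>::infinity();
    for (int i = start; i < start + count; ++i) {
      for (int k = 0; k < 3; ++k) {
        Vec3 v = vert(i, k);
        double co[3] = {v.x, v.y, v.z};
        for (int d = 0; d < 3; ++d) {
          nd.bmin[d] = std::min(nd.bmin[d], co[d]);
          nd.bmax[d] = std::max(nd.bmax[d], co[d]);
        }
      }
    }
    int self = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) {
      nodes[self].start = start; nodes[self].count = count;
      return self;
    }
    // split on longest axis at median centroid
    double ext[3] = {nd.bmax[0] - nd.bmin[0], nd.bmax[1] - nd.bmin[1],
                     nd.bmax[2] - nd.bmin[2]};
    int axis = 0;
    if (ext[1] > ext[axis]) axis = 1;
    if (ext[2] > ext[axis]) axis = 2;
    int mid = start + count / 2;
    std::nth_element(tri.begin() + start, tri.begin() + mid,
                     tri.begin() + start + count, [&](int a, int b) {
                       double ca = axis == 0 ? cent[a].x : (axis == 1 ? cent[a].y : cent[a].z);
                       double cb = axis == 0 ? cent[b].x : (axis == 1 ? cent[b].y : cent[b].z);
                       return ca < cb;
                     });
    int l = buildNode(start, mid - start, cent);
    int r = buildNode(mid, start + count - mid, cent);
    nodes[self].left = l; nodes[self].right = r;
    return self;
  }

  void build(const NumericMatrix& Vm, const IntegerMatrix& Fm) {
    int nv = Vm.nrow();
    ntri = Fm.nrow();
    V.resize(nv);
    for (int i = 0; i < nv; ++i) V[i] = Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2));
    F.resize(3 * (size_t)ntri);
    tri.resize(ntri);
    std::vector<Vec3> cent(ntri);
    for (int t = 0; t < ntri; ++t) {
      tri[t] = t;
      for (int k = 0; k < 3; ++k) F[3 * (size_t)t + k] = Fm(t, k) - 1;
      cent[t] = (V[F[3 * t]] + V[F[3 * t + 1]] + V[F[3 * t + 2]]) * (1.0 / 3.0);
    }
    nodes.reserve(2 * ntri);
    buildNode(0, ntri, cent);
  }

  double boxDist2(const BVHNode& nd, const Vec3& p) const {
    double d2 = 0, co[3] = {p.x, p.y, p.z};
    for (int d = 0; d < 3; ++d) {
      double e = 0;
      if (co[d] < nd.bmin[d]) e = nd.bmin[d] - co[d];
      else if (co[d] > nd.bmax[d]) e = co[d] - nd.bmax[d];
      d2 += e * e;
    }
    return d2;
  }

  void closest(const Vec3& p, int node, double& bestD2, Vec3& bestPt,
               int& bestTri, double* bestBary) const {
    const BVHNode& nd = nodes[node];
    if (boxDist2(nd, p) >= bestD2) return;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        double bary[3];
        Vec3 q = closestPtTriangle(p, vert(i, 0), vert(i, 1), vert(i, 2), bary);
        Vec3 dvec = p - q;
        double d2 = dot(dvec, dvec);
        if (d2 < bestD2) {
          bestD2 = d2; bestPt = q; bestTri = tri[i];
          bestBary[0] = bary[0]; bestBary[1] = bary[1]; bestBary[2] = bary[2];
        }
      }
      return;
    }
    double dl = boxDist2(nodes[nd.left], p), dr = boxDist2(nodes[nd.right], p);
    if (dl < dr) {
      closest(p, nd.left, bestD2, bestPt, bestTri, bestBary);
      closest(p, nd.right, bestD2, bestPt, bestTri, bestBary);
    } else {
      closest(p, nd.right, bestD2, bestPt, bestTri, bestBary);
      closest(p, nd.left, bestD2, bestPt, bestTri, bestBary);
    }
  }

  // all parametric hits of line o + t*dir with the mesh
  void raycastAll(const Vec3& o, const Vec3& dir, int node,
                  std::vector<double>& ts, std::vector<int>& tris) const {
    const BVHNode& nd = nodes[node];
    // slab test for infinite line
    double t0 = -std::numeric_limits<double>::infinity();
    double t1 = std::numeric_limits<double>::infinity();
    double oc[3] = {o.x, o.y, o.z}, dc[3] = {dir.x, dir.y, dir.z};
    for (int d = 0; d < 3; ++d) {
      if (std::fabs(dc[d]) < 1e-300) {
        if (oc[d] < nd.bmin[d] || oc[d] > nd.bmax[d]) return;
      } else {
        double a = (nd.bmin[d] - oc[d]) / dc[d];
        double b = (nd.bmax[d] - oc[d]) / dc[d];
        if (a > b) std::swap(a, b);
        t0 = std::max(t0, a); t1 = std::min(t1, b);
        if (t0 > t1) return;
      }
    }
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        // Moller-Trumbore, full line (t unrestricted)
        Vec3 a = vert(i, 0), b = vert(i, 1), c = vert(i, 2);
        Vec3 e1 = b - a, e2 = c - a;
        Vec3 pv = cross(dir, e2);
        double det = dot(e1, pv);
        if (std::fabs(det) < 1e-14) continue;
        double inv = 1.0 / det;
        Vec3 tv = o - a;
        double u = dot(tv, pv) * inv;
        if (u < -1e-10 || u > 1 + 1e-10) continue;
        Vec3 qv = cross(tv, e1);
        double v = dot(dir, qv) * inv;
        if (v < -1e-10 || u + v > 1 + 1e-10) continue;
        double t = dot(e2, qv) * inv;
        ts.push_back(t);
        tris.push_back(tri[i]);
      }
      return;
    }
    raycastAll(o, dir, nd.left, ts, tris);
    raycastAll(o, dir, nd.right, ts, tris);
  }
};

// [[Rcpp::export]]
SEXP cpp_bvh_build(NumericMatrix V, IntegerMatrix F) {
  MeshBVH* m = new MeshBVH();
  m->build(V, F);
  XPtr<MeshBVH> p(m, true);
  return p;
}

// [[Rcpp::export]]
List cpp_bvh_closest(SEXP bvh, NumericMatrix query) {
  XPtr<MeshBVH> m(bvh);
  int n = query.nrow();
  NumericVector dist(n);
  NumericMatrix pts(n, 3), bary(n, 3);
  IntegerVector triIdx(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(query(i, 0), query(i, 1), query(i, 2));
    double bestD2 = std::numeric_limits<double>::infinity();
    Vec3 bestPt; int bestTri = -1; double bb[3] = {0, 0, 0};
    m->closest(p, 0, bestD2, bestPt, bestTri, bb);
    dist[i] = std::sqrt(bestD2);
    pts(i, 0) = bestPt.x; pts(i, 1) = bestPt.y; pts(i, 2) = bestPt.z;
    triIdx[i] = bestTri + 1;
    bary(i, 0) = bb[0]; bary(i, 1) = bb[1]; bary(i, 2) = bb[2];
  }
  return List::create(_["distance"] = dist, _["point"] = pts,
                      _["triangle"] = triIdx, _["bary"] = bary);
}

// Nearest |t| intersection of the line origin + t*direction per query.
// Returns t = NA when the line misses the mesh.
// [[Rcpp::export]]
List cpp_bvh_linecast(SEXP bvh, NumericMatrix origins, NumericMatrix dirs) {
  XPtr<MeshBVH> m(bvh);
  int n = origins.nrow();
  NumericVector tout(n);
  IntegerVector triIdx(n);
  std::vector<double> ts;
  std::vector<int> tris;
  for (int i = 0; i < n; ++i) {
    ts.clear(); tris.clear();
    Vec3 o(origins(i, 0), origins(i, 1), origins(i, 2));
    Vec3 d(dirs(i, 0), dirs(i, 1), dirs(i, 2));
    m->raycastAll(o, d, 0, ts, tris);
    if (ts.empty()) {
      tout[i] = NA_REAL; triIdx[i] = NA_INTEGER;
    } else {
      int best = 0;
      for (size_t k = 1; k < ts.size(); ++k)
        if (std::fabs(ts[k]) < std::fabs(ts[best])) best = (int)k;
      tout[i] = ts[best];
      triIdx[i] = tris[best] + 1;
    }
  }
  return List::create(_["t"] = tout, _["triangle"] = triIdx);
}

// Parity-count point-in-mesh test (closed meshes).
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(SEXP bvh, NumericMatrix query) {
  XPtr<MeshBVH> m(bvh);
  int n = query.nrow();
  LogicalVector inside(n);
  std::vector<double> ts;
  std::vector<int> tris;
  // fixed irrational-ish direction to dodge edge-on degeneracies
  Vec3 d(0.577350269189626, 0.211324865405187, 0.788675134594813);
  for (int i = 0; i < n; ++i) {
    ts.clear(); tris.clear();
    Vec3 o(query(i, 0), query(i, 1), query(i, 2));
    m->raycastAll(o, d, 0, ts, tris);
    int cnt = 0;
    for (double t : ts) if (t > 0) ++cnt;
    inside[i] = (cnt % 2) == 1;
  }
  return inside;
}

// Voxelize one closed mesh onto the grid: voxel (i,j,k) [0-based] has world
// center origin + (i,j,k)*spacing; true iff center inside the mesh.
// Returns an integer vector of length nx*ny*nz (column-major x fastest).
// [[Rcpp::export]]
IntegerVector cpp_voxelize_mesh(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, NumericVector spacing,
                                IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((size_t)nx * ny * nz);
  // 2D bins over (x,y) triangle bounding boxes
  int ntri = F.nrow();
  double minx = origin[0], miny = origin[1];
  std::vector<std::vector<int>> bins((size_t)nx * ny);
  for (int t = 0; t < ntri; ++t) {
    double bx0 = std::numeric_limits<double>::infinity(), bx1 = -bx0;
    double by0 = bx0, by1 = -bx0;
    for (int k = 0; k < 3; ++k) {
      int v = F(t, k) - 1;
      bx0 = std::min(bx0, V(v, 0)); bx1 = std::max(bx1, V(v, 0));
      by0 = std::min(by0, V(v, 1)); by1 = std::max(by1, V(v, 1));
    }
    int i0 = std::max(0, (int)std::ceil((bx0 - minx) / spacing[0] - 1e-9));
    int i1 = std::min(nx - 1, (int)std::floor((bx1 - minx) / spacing[0] + 1e-9));
    int j0 = std::max(0, (int)std::ceil((by0 - miny) / spacing[1] - 1e-9));
    int j1 = std::min(ny - 1, (int)std::floor((by1 - miny) / spacing[1] + 1e-9));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) bins[(size_t)j * nx + i].push_back(t);
  }
  const double eps = 1e-6;  // column jitter avoids edge-exact hits
  std::vector<double> zs;
  for (int j = 0; j < ny; ++j) {
    double y = origin[1] + j * spacing[1] + eps * spacing[1];
    for (int i = 0; i < nx; ++i) {
      const std::vector<int>& cand = bins[(size_t)j * nx + i];
      if (cand.empty()) continue;
      double x = origin[0] + i * spacing[0] + eps * spacing[0];
      zs.clear();
      for (int t : cand) {
        // z-crossing of vertical line with triangle t
        int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
        double x1 = V(a, 0), y1 = V(a, 1), x2 = V(b, 0), y2 = V(b, 1),
               x3 = V(c, 0), y3 = V(c, 1);
        double det = (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3);
        if (std::fabs(det) < 1e-14) continue;
        double l1 = ((y2 - y3) * (x - x3) + (x3 - x2) * (y - y3)) / det;
        double l2 = ((y3 - y1) * (x - x3) + (x1 - x3) * (y - y3)) / det;
        double l3 = 1 - l1 - l2;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        zs.push_back(l1 * V(a, 2) + l2 * V(b, 2) + l3 * V(c, 2));
      }
      if (zs.size() < 2) continue;
      std::sort(zs.begin(), zs.end());
      // fill voxels between consecutive crossing pairs
      for (size_t p = 0; p + 1 < zs.size(); p += 2) {
        int k0 = std::max(0, (int)std::ceil((zs[p] - origin[2]) / spacing[2] - 1e-9));
        int k1 = std::min(nz - 1,
                          (int)std::floor((zs[p + 1] - origin[2]) / spacing[2] + 1e-9));
        for (int k = k0; k <= k1; ++k)
          out[(size_t)k * nx * ny + (size_t)j * nx + i] = 1;
      }
    }
  }
  return out;
}

// ------------------------------------------------- marching tetrahedra

struct MTState {
  std::unordered_map<uint64_t, int> edgeVert;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
};

static int mtEdgeVertex(MTState& st, uint64_t ia, uint64_t ib,
                        const Vec3& pa, const Vec3& pb, double va, double vb,
                        double iso) {
  uint64_t key = ia < ib ? (ia << 32) | ib : (ib << 32) | ia;
  auto it = st.edgeVert.find(key);
  if (it != st.edgeVert.end()) return it->second;
  double t = (iso - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  Vec3 p = pa + (pb - pa) * t;
  int id = (int)st.vx.size();
  st.vx.push_back(p.x); st.vy.push_back(p.y); st.vz.push_back(p.z);
  st.edgeVert[key] = id;
  return id;
}

static void mtEmit(MTState& st, int v0, int v1, int v2,
                   const Vec3& insideRef) {
  // orient so the normal points away from the interior reference point
  Vec3 a(st.vx[v0], st.vy[v0], st.vz[v0]);
  Vec3 b(st.vx[v1], st.vy[v1], st.vz[v1]);
  Vec3 c(st.vx[v2], st.vy[v2], st.vz[v2]);
  Vec3 n = cross(b - a, c - a);
  Vec3 ctr = (a + b + c) * (1.0 / 3.0);
  if (dot(n, ctr - insideRef) < 0) std::swap(v1, v2);
  st.fa.push_back(v0 + 1); st.fb.push_back(v1 + 1); st.fc.push_back(v2 + 1);
}

static void mtTet(MTState& st, const uint64_t gid[4], const Vec3 p[4],
                  const double v[4], double iso) {
  bool in[4];
  int nin = 0;
  for (int k = 0; k < 4; ++k) { in[k] = v[k] >= iso; if (in[k]) ++nin; }
  if (nin == 0 || nin == 4) return;
  int ins[4], outs[4], ni = 0, no = 0;
  for (int k = 0; k < 4; ++k) (in[k] ? ins[ni++] : outs[no++]) = k;
  if (nin == 1) {
    int a = ins[0];
    int e0 = mtEdgeVertex(st, gid[a], gid[outs[0]], p[a], p[outs[0]], v[a], v[outs[0]], iso);
    int e1 = mtEdgeVertex(st, gid[a], gid[outs[1]], p[a], p[outs[1]], v[a], v[outs[1]], iso);
    int e2 = mtEdgeVertex(st, gid[a], gid[outs[2]], p[a], p[outs[2]], v[a], v[outs[2]], iso);
    mtEmit(st, e0, e1, e2, p[a]);
  } else if (nin == 3) {
    int a = outs[0];
    int e0 = mtEdgeVertex(st, gid[a], gid[ins[0]], p[a], p[ins[0]], v[a], v[ins[0]], iso);
    int e1 = mtEdgeVertex(st, gid[a], gid[ins[1]], p[a], p[ins[1]], v[a], v[ins[1]], iso);
    int e2 = mtEdgeVertex(st, gid[a], gid[ins[2]], p[a], p[ins[2]], v[a], v[ins[2]], iso);
    Vec3 insideCtr = (p[ins[0]] + p[ins[1]] + p[ins[2]]) * (1.0 / 3.0);
    mtEmit(st, e0, e1, e2, insideCtr);
  } else {  // 2 in, 2 out -> quad
    int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
    int eac = mtEdgeVertex(st, gid[a], gid[c], p[a], p[c], v[a], v[c], iso);
    int ead = mtEdgeVertex(st, gid[a], gid[d], p[a], p[d], v[a], v[d], iso);
    int ebc = mtEdgeVertex(st, gid[b], gid[c], p[b], p[c], v[b], v[c], iso);
    int ebd = mtEdgeVertex(st, gid[b], gid[d], p[b], p[d], v[b], v[d], iso);
    Vec3 insideCtr = (p[a] + p[b]) * 0.5;
    mtEmit(st, eac, ead, ebd, insideCtr);
    mtEmit(st, eac, ebd, ebc, insideCtr);
  }
}

// Marching tetrahedra over a scalar grid (column-major, x fastest).
// Voxel (i,j,k) 0-based has world position origin + (i,j,k)*spacing.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, IntegerVector dims,
                       NumericVector origin, NumericVector spacing,
                       double iso) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  MTState st;
  // 6-tetrahedra decomposition around the cube main diagonal c0-c7
  static const int tets[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                                 {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  auto lin = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)k * nx * ny + (uint64_t)j * nx + i;
  };
  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        uint64_t gid[8];
        Vec3 pc[8];
        double vv[8];
        bool any = false, all = true;
        for (int b = 0; b < 8; ++b) {
          int di = b & 1, dj = (b >> 1) & 1, dk = (b >> 2) & 1;
          gid[b] = lin(i + di, j + dj, k + dk);
          vv[b] = vals[gid[b]];
          pc[b] = Vec3(origin[0] + (i + di) * spacing[0],
                       origin[1] + (j + dj) * spacing[1],
                       origin[2] + (k + dk) * spacing[2]);
          if (vv[b] >= iso) any = true; else all = false;
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          uint64_t g[4];
          Vec3 p[4];
          double v[4];
          for (int q = 0; q < 4; ++q) {
            g[q] = gid[tets[t][q]]; p[q] = pc[tets[t][q]]; v[q] = vv[tets[t][q]];
          }
          mtTet(st, g, p, v, iso);
        }
      }
    }
  }
  int nv = (int)st.vx.size(), nf = (int)st.fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  for (int t = 0; t < nf; ++t) {
    F(t, 0) = st.fa[t]; F(t, 1) = st.fb[t]; F(t, 2) = st.fc[t];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Surface voxels: true voxels with at least one false 6-neighbour
// (grid boundary counts as false).
// [[Rcpp::export]]
LogicalVector cpp_surface_voxels(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((size_t)nx * ny * nz);
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[(size_t)k * nx * ny + (size_t)j * nx + i];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!at(i, j, k)) continue;
        bool surf = !at(i - 1, j, k) || !at(i + 1, j, k) || !at(i, j - 1, k) ||
                    !at(i, j + 1, k) || !at(i, j, k - 1) || !at(i, j, k + 1);
        if (surf) out[(size_t)k * nx * ny + (size_t)j * nx + i] = true;
      }
  return out;
}

// One 6-neighbourhood binary dilation pass.
// [[Rcpp::export]]
LogicalVector cpp_dilate6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((size_t)nx * ny * nz);
  auto at = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return mask[(size_t)k * nx * ny + (size_t)j * nx + i];
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool v = at(i, j, k) || at(i - 1, j, k) || at(i + 1, j, k) ||
                 at(i, j - 1, k) || at(i, j + 1, k) || at(i, j, k - 1) ||
                 at(i, j, k + 1);
        if (v) out[(size_t)k * nx * ny + (size_t)j * nx + i] = true;
      }
  return out;
}
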