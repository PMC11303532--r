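// Mesh distance queries: point-triangle / segment-segment primitives,
// AABB-tree accelerated mesh-mesh minimum distance, signed point-to-mesh
// distance with angle-weighted pseudonormals, and vertical ray casting.
// Correctness contract is the brute-force feature-pair minimum; the tree
// only prunes.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
#include <algorithm>
#include <map>
using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3& a, const Vec3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm2(const Vec3& a) { return dot(a, a); }
static inline double norm(const Vec3& a) { return std::sqrt(norm2(a)); }

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
static Vec3 closest_point_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                   const Vec3& c, int* feature = nullptr) {
  // feature codes: 0 face, 1/2/3 vertex a/b/c, 4 edge ab, 5 edge bc, 6 edge ca
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { if (feature) *feature = 1; return a; }
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { if (feature) *feature = 2; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    if (feature) *feature = 4;
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { if (feature) *feature = 3; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    if (feature) *feature = 6;
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    if (feature) *feature = 5;
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  if (feature) *feature = 0;
  return a + ab * v + ac * w;
}

// Closest points between segments p1q1 and p2q2 (Ericson 5.1.9).
static double closest_segment_segment(const Vec3& p1, const Vec3& q1,
                                      const Vec3& p2, const Vec3& q2,
                                      Vec3& c1, Vec3& c2) {
  const double EPS = 1e-14;
  Vec3 d1 = q1 - p1, d2 = q2 - p2, r = p1 - p2;
  double a = norm2(d1), e = norm2(d2), f = dot(d2, r);
  double s, t;
  if (a <= EPS && e <= EPS) { c1 = p1; c2 = p2; return norm(c1 - c2); }
  if (a <= EPS) {
    s = 0.0; t = std::min(std::max(f / e, 0.0), 1.0);
  } else {
    double c = dot(d1, r);
    if (e <= EPS) {
      t = 0.0; s = std::min(std::max(-c / a, 0.0), 1.0);
    } else {
      double b = dot(d1, d2);
      double denom = a * e - b * b;
      s = (denom > EPS) ? std::min(std::max((b * f - c * e) / denom, 0.0), 1.0) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(std::max(-c / a, 0.0), 1.0); }
      else if (t > 1.0) { t = 1.0; s = std::min(std::max((b - c) / a, 0.0), 1.0); }
    }
  }
  c1 = p1 + d1 * s;
  c2 = p2 + d2 * t;
  return norm(c1 - c2);
}

// Moller-Trumbore segment-triangle intersection (inclusive of boundary).
static bool segment_intersects_triangle(const Vec3& p, const Vec3& q,
                                        const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 dir = q - p;
  Vec3 e1 = b - a, e2 = c - a;
  Vec3 h = cross(dir, e2);
  double det = dot(e1, h);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  Vec3 s = p - a;
  double u = dot(s, h) * inv;
  if (u < -1e-12 || u > 1.0 + 1e-12) return false;
  Vec3 qv = cross(s, e1);
  double v = dot(dir, qv) * inv;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return false;
  double t = dot(e2, qv) * inv;
  return t >= -1e-12 && t <= 1.0 + 1e-12;
}

// Minimum distance between two triangles with witness points.
static double triangle_triangle_distance(const Vec3 A[3], const Vec3 B[3],
                                         Vec3& pa, Vec3& pb) {
  double best = DBL_MAX;
  Vec3 c1, c2;
  // vertex-to-face, both directions
  for (int i = 0; i < 3; ++i) {
    Vec3 q = closest_point_triangle(A[i], B[0], B[1], B[2]);
    double d = norm(A[i] - q);
    if (d < best) { best = d; pa = A[i]; pb = q; }
    q = closest_point_triangle(B[i], A[0], A[1], A[2]);
    d = norm(B[i] - q);
    if (d < best) { best = d; pa = q; pb = B[i]; }
  }
  // edge-to-edge
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      double d = closest_segment_segment(A[i], A[(i + 1) % 3], B[j], B[(j + 1) % 3], c1, c2);
      if (d < best) { best = d; pa = c1; pb = c2; }
    }
  }
  if (best > 0.0) {
    // piercing intersection: an edge of one passes through the other
    for (int i = 0; i < 3; ++i) {
      if (segment_intersects_triangle(A[i], A[(i + 1) % 3], B[0], B[1], B[2]) ||
          segment_intersects_triangle(B[i], B[(i + 1) % 3], A[0], A[1], A[2])) {
        best = 0.0;
        pa = pb = A[i];
        break;
      }
    }
  }
  return best;
}

// ---------------- AABB tree ----------------
struct AABB {
  Vec3 lo, hi;
  AABB() : lo(DBL_MAX, DBL_MAX, DBL_MAX), hi(-DBL_MAX, -DBL_MAX, -DBL_MAX) {}
  void expand(const Vec3& p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
  }
  void expand(const AABB& b) { expand(b.lo); expand(b.hi); }
};
static inline double aabb_dist2(const AABB& a, const AABB& b) {
  double d = 0, t;
  t = std::max({a.lo.x - b.hi.x, b.lo.x - a.hi.x, 0.0}); d += t * t;
  t = std::max({a.lo.y - b.hi.y, b.lo.y - a.hi.y, 0.0}); d += t * t;
  t = std::max({a.lo.z - b.hi.z, b.lo.z - a.hi.z, 0.0}); d += t * t;
  return d;
}
static inline double aabb_point_dist2(const AABB& a, const Vec3& p) {
  double d = 0, t;
  t = std::max({a.lo.x - p.x, p.x - a.hi.x, 0.0}); d += t * t;
  t = std::max({a.lo.y - p.y, p.y - a.hi.y, 0.0}); d += t * t;
  t = std::max({a.lo.z - p.z, p.z - a.hi.z, 0.0}); d += t * t;
  return d;
}

struct Tree {
  struct Node { AABB box; int left, right, start, count; };
  std::vector<Node> nodes;
  std::vector<int> tri;           // triangle ids, leaf ranges index into this
  std::vector<AABB> tri_box;
  const std::vector<Vec3>* V;
  const int* F; int nF;

  void build(const std::vector<Vec3>& verts, const IntegerMatrix& faces) {
    V = &verts;
    nF = faces.nrow();
    tri.resize(nF);
    tri_box.resize(nF);
    std::vector<Vec3> cent(nF);
    for (int i = 0; i < nF; ++i) {
      tri[i] = i;
      AABB b;
      Vec3 c(0, 0, 0);
      for (int k = 0; k < 3; ++k) {
        const Vec3& p = verts[faces(i, k) - 1];
        b.expand(p);
        c = c + p * (1.0 / 3.0);
      }
      tri_box[i] = b;
      cent[i] = c;
    }
    centroids = cent;
    nodes.clear();
    nodes.reserve(2 * nF / 4 + 8);
    build_node(0, nF);
  }
  std::vector<Vec3> centroids;
  int build_node(int start, int count) {
    Node nd;
    nd.start = start; nd.count = count; nd.left = nd.right = -1;
    for (int i = start; i < start + count; ++i) nd.box.expand(tri_box[tri[i]]);
    int idx = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) return idx;
    Vec3 ext = nd.box.hi - nd.box.lo;
    int axis = (ext.x >= ext.y && ext.x >= ext.z) ? 0 : (ext.y >= ext.z ? 1 : 2);
    int mid = start + count / 2;
    std::nth_element(tri.begin() + start, tri.begin() + mid, tri.begin() + start + count,
                     [&](int a, int b) {
                       const Vec3 &ca = centroids[a], &cb = centroids[b];
                       double va = axis == 0 ? ca.x : (axis == 1 ? ca.y : ca.z);
                       double vb = axis == 0 ? cb.x : (axis == 1 ? cb.y : cb.z);
                       return va < vb;
                     });
    int l = build_node(start, mid - start);
    int r = build_node(mid, start + count - mid);
    nodes[idx].left = l;
    nodes[idx].right = r;
    nodes[idx].count = 0;
    return idx;
  }
};

static std::vector<Vec3> as_vec3(const NumericMatrix& V) {
  std::vector<Vec3> out(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) out[i] = Vec3(V(i, 0), V(i, 1), V(i, 2));
  return out;
}

// Recursive traversal: triangle ta of mesh A against tree of B.
static void query_tri(const Vec3 A[3], const AABB& boxA, const Tree& tb,
                      const IntegerMatrix& Fb, const std::vector<Vec3>& Vb,
                      int node, double& best, Vec3& pa, Vec3& pb) {
  const Tree::Node& nd = tb.nodes[node];
  if (aabb_dist2(nd.box, boxA) >= best * best) return;
  if (nd.left < 0) {
    for (int i = nd.start; i < nd.start + nd.count; ++i) {
      int f = tb.tri[i];
      if (aabb_dist2(tb.tri_box[f], boxA) >= best * best) continue;
      Vec3 B[3] = { Vb[Fb(f, 0) - 1], Vb[Fb(f, 1) - 1], Vb[Fb(f, 2) - 1] };
      Vec3 qa, qb;
      double d = triangle_triangle_distance(A, B, qa, qb);
      if (d < best) { best = d; pa = qa; pb = qb; }
    }
    return;
  }
  double dl = aabb_dist2(tb.nodes[nd.left].box, boxA);
  double dr = aabb_dist2(tb.nodes[nd.right].box, boxA);
  if (dl < dr) {
    query_tri(A, boxA, tb, Fb, Vb, nd.left, best, pa, pb);
    query_tri(A, boxA, tb, Fb, Vb, nd.right, best, pa, pb);
  } else {
    query_tri(A, boxA, tb, Fb, Vb, nd.right, best, pa, pb);
    query_tri(A, boxA, tb, Fb, Vb, nd.left, best, pa, pb);
  }
}

// [[Rcpp::export]]
List cpp_mesh_min_distance(NumericMatrix Va, IntegerMatrix Fa,
                           NumericMatrix Vb, IntegerMatrix Fb) {
  std::vector<Vec3> va = as_vec3(Va), vb = as_vec3(Vb);
  Tree tb;
  tb.build(vb, Fb);
  double best = norm(va[0] - vb[0]) + 1e-9; // upper bound seed
  Vec3 pa = va[0], pb = vb[0];
  // order A's triangles by centroid distance to B's root box for tighter early bounds
  int nA = Fa.nrow();
  std::vector<int> order(nA);
  std::vector<double> key(nA);
  std::vector<AABB> boxA(nA);
  for (int i = 0; i < nA; ++i) {
    AABB b;
    Vec3 c(0, 0, 0);
    for (int k = 0; k < 3; ++k) { const Vec3& p = va[Fa(i, k) - 1]; b.expand(p); c = c + p * (1.0 / 3.0); }
    boxA[i] = b;
    order[i] = i;
    key[i] = aabb_point_dist2(tb.nodes[0].box, c);
  }
  std::sort(order.begin(), order.end(), [&](int a, int b) { return key[a] < key[b]; });
  for (int oi = 0; oi < nA; ++oi) {
    int i = order[oi];
    if (aabb_dist2(boxA[i], tb.nodes[0].box) >= best * best) continue;
    Vec3 A[3] = { va[Fa(i, 0) - 1], va[Fa(i, 1) - 1], va[Fa(i, 2) - 1] };
    query_tri(A, boxA[i], tb, Fb, vb, 0, best, pa, pb);
    if (best == 0.0) break;
  }
  return List::create(_["distance"] = best,
                      _["point_a"] = NumericVector::create(pa.x, pa.y, pa.z),
                      _["point_b"] = NumericVector::create(pb.x, pb.y, pb.z));
}

// Closest point on mesh for each query point; returns distance, closest point,
// and signed distance using angle-weighted pseudonormals.
// [[Rcpp::export]]
List cpp_signed_point_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  std::vector<Vec3> v = as_vec3(V);
  int nF = F.nrow(), nV = V.nrow(), nP = P.nrow();
  Tree tr;
  tr.build(v, F);
  // face normals
  std::vector<Vec3> fn(nF);
  for (int i = 0; i < nF; ++i) {
    Vec3 a = v[F(i, 0) - 1], b = v[F(i, 1) - 1], c = v[F(i, 2) - 1];
    Vec3 n = cross(b - a, c - a);
    double l = norm(n);
    fn[i] = l > 0 ? n * (1.0 / l) : Vec3(0, 0, 0);
  }
  // angle-weighted vertex normals
  std::vector<Vec3> vn(nV, Vec3(0, 0, 0));
  for (int i = 0; i < nF; ++i) {
    for (int k = 0; k < 3; ++k) {
      int iv = F(i, k) - 1;
      Vec3 p = v[iv], q = v[F(i, (k + 1) % 3) - 1], r = v[F(i, (k + 2) % 3) - 1];
      Vec3 e1 = q - p, e2 = r - p;
      double cosang = dot(e1, e2) / (norm(e1) * norm(e2) + 1e-300);
      cosang = std::min(1.0, std::max(-1.0, cosang));
      double ang = std::acos(cosang);
      vn[iv] = vn[iv] + fn[i] * ang;
    }
  }
  // edge normals: sum of adjacent face normals
  std::map<std::pair<int, int>, Vec3> en;
  for (int i = 0; i < nF; ++i) {
    for (int k = 0; k < 3; ++k) {
      int a = F(i, k) - 1, b = F(i, (k + 1) % 3) - 1;
      if (a > b) std::swap(a, b);
      auto key = std::make_pair(a, b);
      auto it = en.find(key);
      if (it == en.end()) en[key] = fn[i];
      else it->second = it->second + fn[i];
    }
  }
  NumericVector dist(nP), sdist(nP);
  NumericMatrix closest(nP, 3);
  const double EPS = 1e-9;
  for (int ip = 0; ip < nP; ++ip) {
    Vec3 p(P(ip, 0), P(ip, 1), P(ip, 2));
    double best2 = DBL_MAX;
    Vec3 cp;
    int bestf = -1;
    // traverse
    std::vector<int> stack = {0};
    while (!stack.empty()) {
      int node = stack.back();
      stack.pop_back();
      const Tree::Node& nd = tr.nodes[node];
      if (aabb_point_dist2(nd.box, p) >= best2) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int f = tr.tri[i];
          Vec3 q = closest_point_triangle(p, v[F(f, 0) - 1], v[F(f, 1) - 1], v[F(f, 2) - 1]);
          double d2 = norm2(p - q);
          if (d2 < best2) { best2 = d2; cp = q; bestf = f; }
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    double d = std::sqrt(best2);
    dist[ip] = d;
    closest(ip, 0) = cp.x; closest(ip, 1) = cp.y; closest(ip, 2) = cp.z;
    // pick pseudonormal by feature of the closest point on the best face
    Vec3 a = v[F(bestf, 0) - 1], b = v[F(bestf, 1) - 1], c = v[F(bestf, 2) - 1];
    Vec3 nrm = fn[bestf];
    int vid[3] = { F(bestf, 0) - 1, F(bestf, 1) - 1, F(bestf, 2) - 1 };
    Vec3 vs[3] = { a, b, c };
    int at_vertex = -1;
    for (int k = 0; k < 3; ++k) if (norm(cp - vs[k]) < EPS) at_vertex = k;
    if (at_vertex >= 0) {
      nrm = vn[vid[at_vertex]];
    } else {
      for (int k = 0; k < 3; ++k) {
        Vec3 e0 = vs[k], e1 = vs[(k + 1) % 3];
        Vec3 dseg = e1 - e0;
        double t = dot(cp - e0, dseg) / (norm2(dseg) + 1e-300);
        if (t > -EPS && t < 1 + EPS) {
          Vec3 proj = e0 + dseg * t;
          if (norm(cp - proj) < EPS) {
            int u = vid[k], w = vid[(k + 1) % 3];
            if (u > w) std::swap(u, w);
            auto it = en.find(std::make_pair(u, w));
            if (it != en.end()) nrm = it->second;
            break;
          }
        }
      }
    }
    double s = dot(p - cp, nrm);
    sdist[ip] = (s >= 0 ? 1.0 : -1.0) * d;
  }
  return List::create(_["distance"] = dist, _["signed_distance"] = sdist,
                      _["closest"] = closest);
}

// First-hit parameter t along direction dir from each origin (NA when no hit).
// [[Rcpp::export]]
NumericVector cpp_raycast(NumericMatrix O, NumericVector dir,
                          NumericMatrix V, IntegerMatrix F) {
  std::vector<Vec3> v = as_vec3(V);
  int nF = F.nrow(), nO = O.nrow();
  Vec3 d(dir[0], dir[1], dir[2]);
  // precompute triangle data
  std::vector<Vec3> e1(nF), e2(nF), va(nF);
  std::vector<double> lox(nF), hix(nF), loz(nF), hiz(nF);
  bool prune_xz = std::fabs(d.x) < 1e-12 && std::fabs(d.z) < 1e-12; // vertical ray fast path
  for (int i = 0; i < nF; ++i) {
    Vec3 a = v[F(i, 0) - 1], b = v[F(i, 1) - 1], c = v[F(i, 2) - 1];
    va[i] = a; e1[i] = b - a; e2[i] = c - a;
    lox[i] = std::min({a.x, b.x, c.x}); hix[i] = std::max({a.x, b.x, c.x});
    loz[i] = std::min({a.z, b.z, c.z}); hiz[i] = std::max({a.z, b.z, c.z});
  }
  NumericVector out(nO, NA_REAL);
  for (int ip = 0; ip < nO; ++ip) {
    Vec3 o(O(ip, 0), O(ip, 1), O(ip, 2));
    double tbest = DBL_MAX;
    for (int i = 0; i < nF; ++i) {
      if (prune_xz && (o.x < lox[i] - 1e-12 || o.x > hix[i] + 1e-12 ||
                       o.z < loz[i] - 1e-12 || o.z > hiz[i] + 1e-12)) continue;
      Vec3 h = cross(d, e2[i]);
      double det = dot(e1[i], h);
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      Vec3 s = o - va[i];
      double u = dot(s, h) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      Vec3 q = cross(s, e1[i]);
      double w = dot(d, q) * inv;
      if (w < -1e-9 || u + w > 1 + 1e-9) continue;
      double t = dot(e2[i], q) * inv;
      if (t > 1e-12 && t < tbest) tbest = t;
    }
    if (tbest < DBL_MAX) out[ip] = tbest;
  }
  return out;
}
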