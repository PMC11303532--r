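// Quadric error metric edge-collapse decimation (Garland & Heckbert style),
// with link-condition and normal-flip guards; boundary edges are pinned by
// heavy constraint quadrics so open meshes keep their rims.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <map>
#include <set>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Quadric {
  // symmetric 4x4: a11 a12 a13 a14 a22 a23 a24 a33 a34 a44
  double q[10];
  Quadric() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d, double w = 1.0) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d;
    q[9] += w * d * d;
  }
  Quadric operator+(const Quadric& o) const {
    Quadric r;
    for (int i = 0; i < 10; ++i) r.q[i] = q[i] + o.q[i];
    return r;
  }
  double eval(double x, double y, double z) const {
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x +
           q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y +
           q[7]*z*z + 2*q[8]*z + q[9];
  }
  // minimize: solve [a11 a12 a13; a12 a22 a23; a13 a23 a33] v = -[a14;a24;a34]
  bool optimum(double& x, double& y, double& z) const {
    double A[3][3] = {{q[0], q[1], q[2]}, {q[1], q[4], q[5]}, {q[2], q[5], q[7]}};
    double b[3] = {-q[3], -q[6], -q[8]};
    // Cramer
    double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
               - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
               + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
    if (std::fabs(det) < 1e-10) return false;
    auto det3 = [](double M[3][3]) {
      return M[0][0]*(M[1][1]*M[2][2]-M[1][2]*M[2][1])
           - M[0][1]*(M[1][0]*M[2][2]-M[1][2]*M[2][0])
           + M[0][2]*(M[1][0]*M[2][1]-M[1][1]*M[2][0]);
    };
    double Mx[3][3], My[3][3], Mz[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) { Mx[i][j] = A[i][j]; My[i][j] = A[i][j]; Mz[i][j] = A[i][j]; }
    for (int i = 0; i < 3; ++i) { Mx[i][0] = b[i]; My[i][1] = b[i]; Mz[i][2] = b[i]; }
    x = det3(Mx) / det; y = det3(My) / det; z = det3(Mz) / det;
    return true;
  }
};

// Edges referenced by more than two faces (1-based vertex ids, rows = edges).
// [[Rcpp::export]]
IntegerMatrix cpp_nonmanifold_edges(IntegerMatrix F) {
  std::map<std::pair<int, int>, int> cnt;
  for (int i = 0; i < F.nrow(); ++i) {
    for (int k = 0; k < 3; ++k) {
      int a = F(i, k), b = F(i, (k + 1) % 3);
      if (a > b) std::swap(a, b);
      cnt[{a, b}]++;
    }
  }
  std::vector<std::pair<int, int> > bad;
  for (auto& kv : cnt) if (kv.second > 2) bad.push_back(kv.first);
  IntegerMatrix out((int)bad.size(), 2);
  for (int i = 0; i < (int)bad.size(); ++i) { out(i, 0) = bad[i].first; out(i, 1) = bad[i].second; }
  return out;
}

struct HeapItem {
  double cost;
  int u, v;
  long stamp;
  bool operator<(const HeapItem& o) const { return cost > o.cost; } // min-heap
};

// [[Rcpp::export]]
List cpp_decimate(NumericMatrix Vin, IntegerMatrix Fin, int target_faces) {
  int nV = Vin.nrow(), nF = Fin.nrow();
  std::vector<double> X(nV), Y(nV), Z(nV);
  for (int i = 0; i < nV; ++i) { X[i] = Vin(i, 0); Y[i] = Vin(i, 1); Z[i] = Vin(i, 2); }
  std::vector<std::array<int, 3> > faces(nF);
  std::vector<char> face_alive(nF, 1);
  for (int i = 0; i < nF; ++i) faces[i] = { Fin(i, 0) - 1, Fin(i, 1) - 1, Fin(i, 2) - 1 };
  std::vector<std::set<int> > vfaces(nV);
  for (int i = 0; i < nF; ++i)
    for (int k = 0; k < 3; ++k) vfaces[faces[i][k]].insert(i);

  auto face_normal = [&](int f, double* n) -> double {
    int a = faces[f][0], b = faces[f][1], c = faces[f][2];
    double e1x = X[b]-X[a], e1y = Y[b]-Y[a], e1z = Z[b]-Z[a];
    double e2x = X[c]-X[a], e2y = Y[c]-Y[a], e2z = Z[c]-Z[a];
    n[0] = e1y*e2z - e1z*e2y; n[1] = e1z*e2x - e1x*e2z; n[2] = e1x*e2y - e1y*e2x;
    double l = std::sqrt(n[0]*n[0] + n[1]*n[1] + n[2]*n[2]);
    if (l > 0) { n[0]/=l; n[1]/=l; n[2]/=l; }
    return l / 2.0; // area
  };

  // vertex quadrics
  std::vector<Quadric> Q(nV);
  std::map<std::pair<int, int>, std::vector<int> > edge_faces;
  for (int f = 0; f < nF; ++f) {
    double n[3];
    double area = face_normal(f, n);
    if (area <= 0) continue;
    int a = faces[f][0];
    double d = -(n[0]*X[a] + n[1]*Y[a] + n[2]*Z[a]);
    for (int k = 0; k < 3; ++k) Q[faces[f][k]].add_plane(n[0], n[1], n[2], d, area);
    for (int k = 0; k < 3; ++k) {
      int u = faces[f][k], v = faces[f][(k + 1) % 3];
      if (u > v) std::swap(u, v);
      edge_faces[{u, v}].push_back(f);
    }
  }
  // boundary constraints: plane through edge, perpendicular to the face
  for (auto& kv : edge_faces) {
    if (kv.second.size() != 1) continue;
    int f = kv.second[0];
    int u = kv.first.first, v = kv.first.second;
    double n[3];
    face_normal(f, n);
    double ex = X[v]-X[u], ey = Y[v]-Y[u], ez = Z[v]-Z[u];
    double cx = ey*n[2]-ez*n[1], cy = ez*n[0]-ex*n[2], cz = ex*n[1]-ey*n[0];
    double l = std::sqrt(cx*cx + cy*cy + cz*cz);
    if (l <= 0) continue;
    cx/=l; cy/=l; cz/=l;
    double d = -(cx*X[u] + cy*Y[u] + cz*Z[u]);
    double w = 1000.0;
    Q[u].add_plane(cx, cy, cz, d, w);
    Q[v].add_plane(cx, cy, cz, d, w);
  }

  std::vector<long> stamp(nV, 0);
  std::priority_queue<HeapItem> heap;
  auto edge_cost = [&](int u, int v, double& ox, double& oy, double& oz) -> double {
    Quadric q = Q[u] + Q[v];
    double x, y, z;
    if (!q.optimum(x, y, z)) {
      double mx = (X[u]+X[v])/2, my = (Y[u]+Y[v])/2, mz = (Z[u]+Z[v])/2;
      double cm = q.eval(mx, my, mz), cu = q.eval(X[u], Y[u], Z[u]), cv = q.eval(X[v], Y[v], Z[v]);
      if (cm <= cu && cm <= cv) { x = mx; y = my; z = mz; }
      else if (cu <= cv) { x = X[u]; y = Y[u]; z = Z[u]; }
      else { x = X[v]; y = Y[v]; z = Z[v]; }
    }
    ox = x; oy = y; oz = z;
    return q.eval(x, y, z);
  };
  auto push_edge = [&](int u, int v) {
    if (u == v) return;
    if (u > v) std::swap(u, v);
    double x, y, z;
    double c = edge_cost(u, v, x, y, z);
    heap.push({c, u, v, stamp[u] + stamp[v]});
  };
  for (auto& kv : edge_faces) push_edge(kv.first.first, kv.first.second);

  int alive = nF;
  std::vector<int> tmp_neigh;
  while (alive > target_faces && !heap.empty()) {
    HeapItem it = heap.top();
    heap.pop();
    int u = it.u, v = it.v;
    if (it.stamp != stamp[u] + stamp[v]) continue; // stale
    // both must still be referenced
    if (vfaces[u].empty() || vfaces[v].empty()) continue;
    // must still share >=1 face (still an edge)
    std::vector<int> shared;
    for (int f : vfaces[u]) if (vfaces[v].count(f)) shared.push_back(f);
    if (shared.empty()) continue;
    // link condition: common neighbor vertices must be exactly the opposite
    // vertices of the shared faces
    std::set<int> nu, nv;
    for (int f : vfaces[u]) for (int k = 0; k < 3; ++k) if (faces[f][k] != u) nu.insert(faces[f][k]);
    for (int f : vfaces[v]) for (int k = 0; k < 3; ++k) if (faces[f][k] != v) nv.insert(faces[f][k]);
    std::set<int> common;
    std::set_intersection(nu.begin(), nu.end(), nv.begin(), nv.end(),
                          std::inserter(common, common.begin()));
    common.erase(u); common.erase(v);
    std::set<int> opposite;
    for (int f : shared) for (int k = 0; k < 3; ++k)
      if (faces[f][k] != u && faces[f][k] != v) opposite.insert(faces[f][k]);
    if (common != opposite) continue;
    // optimal position
    double x, y, z;
    edge_cost(u, v, x, y, z);
    // normal-flip / degeneracy guard on surviving faces of u and v
    bool ok = true;
    double ox = X[u], oy = Y[u], oz = Z[u];
    double ovx = X[v], ovy = Y[v], ovz = Z[v];
    auto check = [&](int w) {
      for (int f : vfaces[w]) {
        bool is_shared = false;
        for (int g : shared) if (g == f) is_shared = true;
        if (is_shared) continue;
        double n0[3];
        double area0 = face_normal(f, n0);
        double sx = X[w], sy = Y[w], sz = Z[w];
        X[w] = x; Y[w] = y; Z[w] = z;
        double n1[3];
        double area1 = face_normal(f, n1);
        X[w] = sx; Y[w] = sy; Z[w] = sz;
        if (area1 < 1e-12 ||
            (area0 > 1e-12 && n0[0]*n1[0] + n0[1]*n1[1] + n0[2]*n1[2] < 0.1)) {
          ok = false;
          return;
        }
      }
    };
    check(u);
    if (ok) check(v);
    if (!ok) { (void)ox; (void)oy; (void)oz; (void)ovx; (void)ovy; (void)ovz; continue; }
    // perform collapse: v -> u, u moves to optimum
    X[u] = x; Y[u] = y; Z[u] = z;
    Q[u] = Q[u] + Q[v];
    for (int f : shared) {
      if (!face_alive[f]) continue;
      face_alive[f] = 0;
      alive--;
      for (int k = 0; k < 3; ++k) vfaces[faces[f][k]].erase(f);
    }
    std::vector<int> vf(vfaces[v].begin(), vfaces[v].end());
    for (int f : vf) {
      for (int k = 0; k < 3; ++k) if (faces[f][k] == v) faces[f][k] = u;
      vfaces[v].erase(f);
      vfaces[u].insert(f);
    }
    stamp[u]++; stamp[v]++;
    // requeue edges around u
    std::set<int> around;
    for (int f : vfaces[u]) for (int k = 0; k < 3; ++k) if (faces[f][k] != u) around.insert(faces[f][k]);
    for (int w : around) push_edge(u, w);
  }

  // compact
  std::vector<int> vmap(nV, -1);
  std::vector<int> keepF;
  for (int f = 0; f < nF; ++f) if (face_alive[f]) keepF.push_back(f);
  int nv2 = 0;
  for (int f : keepF) for (int k = 0; k < 3; ++k) {
    int w = faces[f][k];
    if (vmap[w] < 0) vmap[w] = nv2++;
  }
  NumericMatrix Vout(nv2, 3);
  for (int i = 0; i < nV; ++i) {
    if (vmap[i] >= 0) { Vout(vmap[i], 0) = X[i]; Vout(vmap[i], 1) = Y[i]; Vout(vmap[i], 2) = Z[i]; }
  }
  IntegerMatrix Fout((int)keepF.size(), 3);
  for (int i = 0; i < (int)keepF.size(); ++i)
    for (int k = 0; k < 3; ++k) Fout(i, k) = vmap[faces[keepF[i]][k]] + 1;
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
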