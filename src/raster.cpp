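// Silhouette rasterization and contour machinery.
// Conventions: the detector grid stores pixel [row, col] with the center of
// pixel [1,1] at (u_left, v_top) detector mm; u grows with the column index,
// v DECREASES with the row index (image convention, v axis points up).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Rasterize projected triangles onto a fine grid (subsample^2 samples per
// output pixel), then box-average to fractional coverage in [0,1].
// P: n x 2 projected vertices (u, v) in detector mm, F: m x 3 1-based faces.
// [[Rcpp::export]]
NumericMatrix cpp_render_coverage(NumericMatrix P, IntegerMatrix F,
                                  double u_left, double v_top, double pitch,
                                  int nrow, int ncol, int subsample) {
  const int s = subsample < 1 ? 1 : subsample;
  const long fr = (long)nrow * s, fc = (long)ncol * s;
  const double fstep = pitch / s;
  // fine cell (1,1) center so that the s x s block averages to the pixel center
  const double fu0 = u_left - pitch / 2.0 + fstep / 2.0;
  const double fv0 = v_top + pitch / 2.0 - fstep / 2.0;
  std::vector<uint8_t> grid((size_t)fr * fc, 0);

  const int nF = F.nrow();
  for (int t = 0; t < nF; ++t) {
    double ux[3], vy[3];
    for (int k = 0; k < 3; ++k) {
      int iv = F(t, k) - 1;
      ux[k] = P(iv, 0);
      vy[k] = P(iv, 1);
    }
    // convert to fine-grid fractional coordinates: col x = (u - fu0)/fstep,
    // row y = (fv0 - v)/fstep
    double X[3], Y[3];
    for (int k = 0; k < 3; ++k) {
      X[k] = (ux[k] - fu0) / fstep;
      Y[k] = (fv0 - vy[k]) / fstep;
    }
    double ymin = std::min({Y[0], Y[1], Y[2]}), ymax = std::max({Y[0], Y[1], Y[2]});
    long r0 = (long)std::ceil(ymin - 1e-12), r1 = (long)std::floor(ymax + 1e-12);
    if (r0 < 0) r0 = 0;
    if (r1 > fr - 1) r1 = fr - 1;
    for (long r = r0; r <= r1; ++r) {
      double yr = (double)r;
      // x-span of the triangle at scanline yr
      double xlo = 1e300, xhi = -1e300;
      for (int k = 0; k < 3; ++k) {
        double y1 = Y[k], y2 = Y[(k + 1) % 3];
        double x1 = X[k], x2 = X[(k + 1) % 3];
        if ((y1 <= yr && y2 >= yr) || (y2 <= yr && y1 >= yr)) {
          double dy = y2 - y1;
          double x = (std::fabs(dy) < 1e-30) ? std::min(x1, x2)
                                             : x1 + (yr - y1) / dy * (x2 - x1);
          if (std::fabs(dy) < 1e-30) { // horizontal edge on the scanline
            xlo = std::min({xlo, x1, x2});
            xhi = std::max({xhi, x1, x2});
          } else {
            xlo = std::min(xlo, x);
            xhi = std::max(xhi, x);
          }
        }
      }
      if (xhi < xlo) continue;
      long c0 = (long)std::ceil(xlo - 1e-12), c1 = (long)std::floor(xhi + 1e-12);
      if (c0 < 0) c0 = 0;
      if (c1 > fc - 1) c1 = fc - 1;
      if (c1 < c0) continue;
      uint8_t* rowp = grid.data() + (size_t)r * fc;
      std::fill(rowp + c0, rowp + c1 + 1, (uint8_t)1);
    }
  }
  NumericMatrix out(nrow, ncol);
  const double inv = 1.0 / (double)(s * s);
  for (int i = 0; i < nrow; ++i) {
    for (int j = 0; j < ncol; ++j) {
      int acc = 0;
      for (int a = 0; a < s; ++a) {
        const uint8_t* rowp = grid.data() + (size_t)((long)i * s + a) * fc + (long)j * s;
        for (int b = 0; b < s; ++b) acc += rowp[b];
      }
      out(i, j) = acc * inv;
    }
  }
  return out;
}

// ---------------- marching squares ----------------
// Iso-contours of a scalar grid at `level`, linear interpolation between
// pixel centers. The grid is padded with zeros so all contours close.
// Returns a list of k x 2 (u, v) loops in detector mm, each implicitly closed
// (first point not repeated). Orientation is not normalized.

struct MSPoint { double x, y; }; // padded-grid coordinates (x=col, y=row, 0-based)

// [[Rcpp::export]]
List cpp_marching_squares(NumericMatrix M, double level,
                          double u_left, double v_top, double pitch) {
  const int nr = M.nrow(), nc = M.ncol();
  const int R = nr + 2, C = nc + 2; // padded
  // contiguous zero-padded copy: the cell scan reads R*C*4 values
  std::vector<double> buf((size_t)R * C, 0.0);
  for (int j = 0; j < nc; ++j) {
    const double* col = &M(0, j);
    double* dst = buf.data() + (size_t)1 * C + (j + 1);
    for (int i = 0; i < nr; ++i) dst[(size_t)i * C] = col[i];
  }
  auto val = [&](int i, int j) -> double { return buf[(size_t)i * C + j]; };
  // Edge key: horizontal edge between (i,j)-(i,j+1) id = 2*(i*C+j),
  // vertical edge between (i,j)-(i+1,j) id = 2*(i*C+j)+1.
  auto interp = [&](int i1, int j1, int i2, int j2) -> MSPoint {
    double v1 = val(i1, j1), v2 = val(i2, j2);
    double t = (level - v1) / (v2 - v1);
    MSPoint p;
    p.x = j1 + t * (j2 - j1);
    p.y = i1 + t * (i2 - i1);
    return p;
  };
  std::unordered_map<int64_t, MSPoint> pts;
  std::vector<std::pair<int64_t, int64_t> > segs;
  segs.reserve(1024);
  auto hedge = [&](int i, int j) -> int64_t { return 2 * ((int64_t)i * C + j); };
  auto vedge = [&](int i, int j) -> int64_t { return 2 * ((int64_t)i * C + j) + 1; };
  for (int i = 0; i < R - 1; ++i) {
    const double* row0 = buf.data() + (size_t)i * C;
    const double* row1 = row0 + C;
    for (int j = 0; j < C - 1; ++j) {
      const double vtl = row0[j], vtr = row0[j + 1], vbr = row1[j + 1], vbl = row1[j];
      // fast reject for uniform cells (the overwhelming majority)
      if ((vtl > level) == (vtr > level) && (vtr > level) == (vbr > level) &&
          (vbr > level) == (vbl > level)) continue;
      int code = 0;
      if (vtl > level) code |= 1;
      if (vtr > level) code |= 2;
      if (vbr > level) code |= 4;
      if (vbl > level) code |= 8;
      if (code == 0 || code == 15) continue;
      int64_t top = hedge(i, j), bottom = hedge(i + 1, j);
      int64_t left = vedge(i, j), right = vedge(i, j + 1);
      auto put = [&](int64_t e) {
        if (pts.count(e)) return;
        if (e & 1) { // vertical
          int64_t cell = e >> 1;
          int ii = (int)(cell / C), jj = (int)(cell % C);
          pts[e] = interp(ii, jj, ii + 1, jj);
        } else {
          int64_t cell = e >> 1;
          int ii = (int)(cell / C), jj = (int)(cell % C);
          pts[e] = interp(ii, jj, ii, jj + 1);
        }
      };
      auto add = [&](int64_t a, int64_t b) { put(a); put(b); segs.push_back({a, b}); };
      switch (code) {
        case 1:  add(left, top); break;
        case 2:  add(top, right); break;
        case 3:  add(left, right); break;
        case 4:  add(right, bottom); break;
        case 5: { // saddle: decide by center average
          double cen = (vtl + vtr + vbr + vbl) / 4.0;
          if (cen > level) { add(left, bottom); add(top, right); }
          else { add(left, top); add(right, bottom); }
          break;
        }
        case 6:  add(top, bottom); break;
        case 7:  add(left, bottom); break;
        case 8:  add(bottom, left); break;
        case 9:  add(top, bottom); break;
        case 10: {
          double cen = (vtl + vtr + vbr + vbl) / 4.0;
          if (cen > level) { add(top, left); add(bottom, right); }
          else { add(top, right); add(bottom, left); }
          break;
        }
        case 11: add(bottom, right); break;
        case 12: add(right, left); break;
        case 13: add(top, right); break;
        case 14: add(left, top); break;
      }
    }
  }
  // link segments into loops
  std::unordered_map<int64_t, std::vector<int> > by_end;
  by_end.reserve(segs.size() * 2);
  for (int k = 0; k < (int)segs.size(); ++k) {
    by_end[segs[k].first].push_back(k);
    by_end[segs[k].second].push_back(k);
  }
  std::vector<char> used(segs.size(), 0);
  List loops;
  for (int k0 = 0; k0 < (int)segs.size(); ++k0) {
    if (used[k0]) continue;
    std::vector<int64_t> chain;
    used[k0] = 1;
    chain.push_back(segs[k0].first);
    chain.push_back(segs[k0].second);
    bool closed = false;
    while (true) {
      int64_t tail = chain.back();
      if (tail == chain.front()) { closed = true; chain.pop_back(); break; }
      int next = -1;
      auto it = by_end.find(tail);
      if (it != by_end.end()) {
        for (int cand : it->second) {
          if (!used[cand]) { next = cand; break; }
        }
      }
      if (next < 0) break;
      used[next] = 1;
      chain.push_back(segs[next].first == tail ? segs[next].second : segs[next].first);
    }
    if ((int)chain.size() < 3) continue;
    NumericMatrix loop((int)chain.size(), 2);
    for (int k = 0; k < (int)chain.size(); ++k) {
      const MSPoint& p = pts[chain[k]];
      // padded grid (x=col index, y=row index, pad offset 1) -> detector mm
      loop(k, 0) = u_left + (p.x - 1.0) * pitch;
      loop(k, 1) = v_top - (p.y - 1.0) * pitch;
    }
    loop.attr("closed") = closed;
    loops.push_back(loop);
  }
  return loops;
}

// Minimum distance from each point to a set of segments (k x 4: x1 y1 x2 y2).
// [[Rcpp::export]]
NumericVector cpp_points_to_segments(NumericMatrix P, NumericMatrix S) {
  const int n = P.nrow(), m = S.nrow();
  NumericVector out(n);
  // contiguous copies: the inner loop runs n*m times
  std::vector<double> x1(m), y1(m), dx(m), dy(m), il2(m);
  for (int j = 0; j < m; ++j) {
    x1[j] = S(j, 0); y1[j] = S(j, 1);
    dx[j] = S(j, 2) - x1[j]; dy[j] = S(j, 3) - y1[j];
    double l2 = dx[j] * dx[j] + dy[j] * dy[j];
    il2[j] = l2 > 0 ? 1.0 / l2 : 0.0;
  }
  for (int i = 0; i < n; ++i) {
    const double px = P(i, 0), py = P(i, 1);
    double best = 1e300;
    for (int j = 0; j < m; ++j) {
      double t = ((px - x1[j]) * dx[j] + (py - y1[j]) * dy[j]) * il2[j];
      t = t < 0 ? 0 : (t > 1 ? 1 : t);
      const double qx = x1[j] + t * dx[j] - px, qy = y1[j] + t * dy[j] - py;
      const double d2 = qx * qx + qy * qy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
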