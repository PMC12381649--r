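#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection. Returns t (>0) or -1.
static inline double rayTri(const double* orig, const double* dir,
                            const double* v0, const double* v1, const double* v2) {
  const double EPS = 1e-12;
  double e1[3], e2[3], p[3], s[3], q[3];
  for (int i = 0; i < 3; ++i) { e1[i] = v1[i] - v0[i]; e2[i] = v2[i] - v0[i]; }
  p[0] = dir[1]*e2[2] - dir[2]*e2[1];
  p[1] = dir[2]*e2[0] - dir[0]*e2[2];
  p[2] = dir[0]*e2[1] - dir[1]*e2[0];
  double det = e1[0]*p[0] + e1[1]*p[1] + e1[2]*p[2];
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) s[i] = orig[i] - v0[i];
  double u = (s[0]*p[0] + s[1]*p[1] + s[2]*p[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  q[0] = s[1]*e1[2] - s[2]*e1[1];
  q[1] = s[2]*e1[0] - s[0]*e1[2];
  q[2] = s[0]*e1[1] - s[1]*e1[0];
  double v = (dir[0]*q[0] + dir[1]*q[1] + dir[2]*q[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = (e2[0]*q[0] + e2[1]*q[1] + e2[2]*q[2]) * inv;
  return (t > EPS) ? t : -1.0;
}

// Radial distance from `center` to a closed mesh along each direction in `dirs`
// (rows, unit vectors). Takes the farthest intersection, so the result is the
// outer surface radius for star-shaped meshes. Returns -1 where no hit.
// [[Rcpp::export]]
NumericVector cpp_radial_project(NumericMatrix verts, IntegerMatrix faces,
                                 NumericVector center, NumericMatrix dirs) {
  int nf = faces.nrow(), nd = dirs.nrow();
  std::vector<double> V(verts.nrow() * 3);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3*i + j] = verts(i, j);
  NumericVector out(nd);
  double c[3] = {center[0], center[1], center[2]};
  for (int d = 0; d < nd; ++d) {
    double dir[3] = {dirs(d, 0), dirs(d, 1), dirs(d, 2)};
    double best = -1.0;
    for (int f = 0; f < nf; ++f) {
      const double* v0 = &V[3*(faces(f,0)-1)];
      const double* v1 = &V[3*(faces(f,1)-1)];
      const double* v2 = &V[3*(faces(f,2)-1)];
      double t = rayTri(c, dir, v0, v1, v2);
      if (t > best) best = t;
    }
    out[d] = best;
  }
  return out;
}

struct QNode {
  double d; int v;
  bool operator<(const QNode& o) const { return d > o.d; } // min-heap
};

// Fast marching on a triangle mesh with the planar virtual-source update:
// for a wavefront crossing edge AB of a triangle, the update of C places a
// virtual source consistent with d(A), d(B) and takes the straight-line
// distance, falling back to the Dijkstra edge update when the geodesic does
// not pass through the triangle interior.
// [[Rcpp::export]]
NumericVector cpp_geodesic_fmm(NumericMatrix verts, IntegerMatrix faces,
                               IntegerVector sources) {
  int nv = verts.nrow(), nf = faces.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(nv, INF);
  std::vector<char> frozen(nv, 0);
  // vertex -> incident faces
  std::vector<std::vector<int>> vfaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int j = 0; j < 3; ++j) vfaces[faces(f, j) - 1].push_back(f);

  std::priority_queue<QNode> pq;
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i] - 1;
    dist[s] = 0.0;
    pq.push({0.0, s});
  }

  auto vx = [&](int i, int k) { return verts(i, k); };
  auto elen = [&](int a, int b) {
    double s = 0;
    for (int k = 0; k < 3; ++k) { double d = vx(a,k) - vx(b,k); s += d*d; }
    return std::sqrt(s);
  };

  // try to update vertex c from triangle (a, b, c); a and b must be finite
  auto triUpdate = [&](int a, int b, int c) -> double {
    double dA = dist[a], dB = dist[b];
    if (!std::isfinite(dA) || !std::isfinite(dB)) return INF;
    if (dA > dB) { std::swap(a, b); std::swap(dA, dB); }
    double lab = elen(a, b), lac = elen(a, c), lbc = elen(b, c);
    double fallback = std::min(dA + lac, dB + lbc);
    if (lab < 1e-14) return fallback;
    // local 2D frame: A at origin, B at (lab, 0), C above the axis
    double cxn = 0, cyn = 0;
    {
      double abv[3], acv[3];
      for (int k = 0; k < 3; ++k) { abv[k] = vx(b,k) - vx(a,k); acv[k] = vx(c,k) - vx(a,k); }
      double dotp = (abv[0]*acv[0] + abv[1]*acv[1] + abv[2]*acv[2]) / lab;
      cxn = dotp;
      double h2 = lac*lac - dotp*dotp;
      cyn = (h2 > 0) ? std::sqrt(h2) : 0.0;
    }
    // virtual source below the AB axis
    double sx = (lab*lab + dA*dA - dB*dB) / (2.0 * lab);
    double sy2 = dA*dA - sx*sx;
    if (sy2 < 0) return fallback;
    double sy = -std::sqrt(sy2);
    if (cyn - sy < 1e-14) return fallback;
    // ray S->C must cross segment AB
    double xint = sx + (cxn - sx) * (0.0 - sy) / (cyn - sy);
    if (xint < -1e-9 || xint > lab + 1e-9) return fallback;
    double dx = cxn - sx, dy = cyn - sy;
    return std::sqrt(dx*dx + dy*dy);
  };

  while (!pq.empty()) {
    QNode top = pq.top(); pq.pop();
    int v = top.v;
    if (frozen[v]) continue;
    if (top.d > dist[v] + 1e-12) continue;
    frozen[v] = 1;
    for (size_t fi = 0; fi < vfaces[v].size(); ++fi) {
      int f = vfaces[v][fi];
      int tri[3] = {faces(f,0)-1, faces(f,1)-1, faces(f,2)-1};
      for (int j = 0; j < 3; ++j) {
        int c = tri[j];
        if (frozen[c]) continue;
        int a = tri[(j+1)%3], b = tri[(j+2)%3];
        double cand = INF;
        if (std::isfinite(dist[a]) && std::isfinite(dist[b]))
          cand = triUpdate(a, b, c);
        else if (std::isfinite(dist[a]))
          cand = dist[a] + elen(a, c);
        else if (std::isfinite(dist[b]))
          cand = dist[b] + elen(b, c);
        if (cand < dist[c] - 1e-14) {
          dist[c] = cand;
          pq.push({cand, c});
        }
      }
    }
  }
  return NumericVector(dist.begin(), dist.end());
}
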