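#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Geometry kernels for spherical sensor layouts: an incremental 3D convex
// hull (all inputs are in convex position, so every point ends up a vertex)
// and a distmesh-style edge-spring relaxation constrained to the sphere.

static inline void cross3(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

struct Face {
  int a, b, c;
  double n[3];   // outward normal (not unit)
  double off;    // n . vertex_a
  bool alive;
};

static Face make_face(int a, int b, int c, const NumericMatrix &P) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  double u[3], v[3], pa[3];
  for (int k = 0; k < 3; ++k) {
    pa[k] = P(a, k);
    u[k] = P(b, k) - P(a, k);
    v[k] = P(c, k) - P(a, k);
  }
  cross3(u, v, f.n);
  f.off = dot3(f.n, pa);
  f.alive = true;
  return f;
}

// [[Rcpp::export]]
IntegerMatrix convex_hull3_cpp(NumericMatrix P) {
  const int n = P.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  double scale = 0.0;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) scale = std::max(scale, std::fabs(P(i, k)));
  const double eps = 1e-10 * scale * scale;  // tolerance on n.(p-a), units len^2*len

  // initial simplex: spread-out quadruple
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = 0;
    for (int k = 0; k < 3; ++k) d += (P(i, k) - P(i0, k)) * (P(i, k) - P(i0, k));
    if (d > best) { best = d; i1 = i; }
  }
  best = -1.0;
  double e0[3];
  for (int k = 0; k < 3; ++k) e0[k] = P(i1, k) - P(i0, k);
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double w[3], cr[3];
    for (int k = 0; k < 3; ++k) w[k] = P(i, k) - P(i0, k);
    cross3(e0, w, cr);
    double d = dot3(cr, cr);
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= eps * eps) stop("degenerate input: points are collinear");
  Face base = make_face(i0, i1, i2, P);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double pa[3];
    for (int k = 0; k < 3; ++k) pa[k] = P(i, k);
    double d = std::fabs(dot3(base.n, pa) - base.off);
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= eps) stop("degenerate input: points are coplanar");

  std::vector<Face> faces;
  {
    int t[4] = { i0, i1, i2, i3 };
    double ctr[3] = { 0, 0, 0 };
    for (int j = 0; j < 4; ++j)
      for (int k = 0; k < 3; ++k) ctr[k] += 0.25 * P(t[j], k);
    int tri[4][3] = { {0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3} };
    for (int j = 0; j < 4; ++j) {
      Face f = make_face(t[tri[j][0]], t[tri[j][1]], t[tri[j][2]], P);
      if (dot3(f.n, ctr) - f.off > 0) { // flip to outward
        std::swap(f.b, f.c);
        f = make_face(f.a, f.b, f.c, P);
      }
      faces.push_back(f);
    }
  }

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;

  std::vector<int> visible;
  for (int i = 0; i < n; ++i) {
    if (used[i]) continue;
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    visible.clear();
    for (size_t fI = 0; fI < faces.size(); ++fI) {
      if (!faces[fI].alive) continue;
      if (dot3(faces[fI].n, p) - faces[fI].off > eps) visible.push_back((int)fI);
    }
    if (visible.empty()) continue; // inside current hull (numerically)

    // horizon: directed edges of visible faces whose reverse is not visible
    std::unordered_set<long long> vEdges;
    vEdges.reserve(visible.size() * 4);
    auto key = [n](int a, int b) { return (long long)a * n + b; };
    for (int fI : visible) {
      const Face &f = faces[fI];
      vEdges.insert(key(f.a, f.b));
      vEdges.insert(key(f.b, f.c));
      vEdges.insert(key(f.c, f.a));
    }
    std::vector<std::pair<int, int>> horizon;
    for (int fI : visible) {
      const Face &f = faces[fI];
      int ed[3][2] = { {f.a, f.b}, {f.b, f.c}, {f.c, f.a} };
      for (int e = 0; e < 3; ++e)
        if (!vEdges.count(key(ed[e][1], ed[e][0])))
          horizon.push_back({ ed[e][0], ed[e][1] });
      faces[fI].alive = false;
    }
    for (auto &e : horizon) faces.push_back(make_face(e.first, e.second, i, P));
  }

  int nf = 0;
  for (auto &f : faces) if (f.alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1;
    out(r, 1) = f.b + 1;
    out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}

// distmesh-style relaxation on the sphere: truncated repulsive springs on
// the current triangulation edges, uniform target length with scale factor
// fscale, explicit Euler steps of size dt, points reprojected each step.
// [[Rcpp::export]]
List spring_relax_cpp(NumericMatrix P0, IntegerMatrix edges, double radius,
                      int n_steps, double dt, double fscale) {
  const int n = P0.nrow(), ne = edges.nrow();
  NumericMatrix P = clone(P0);
  std::vector<double> F(3 * n);
  double maxdisp = 0.0;
  for (int step = 0; step < n_steps; ++step) {
    double sum_d2 = 0.0;
    std::vector<double> dlen(ne);
    for (int e = 0; e < ne; ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      double dx = P(a, 0) - P(b, 0), dy = P(a, 1) - P(b, 1),
             dz = P(a, 2) - P(b, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      dlen[e] = d;
      sum_d2 += d * d;
    }
    const double L0 = fscale * std::sqrt(sum_d2 / ne);
    std::fill(F.begin(), F.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      double d = dlen[e];
      double f = L0 - d;
      if (f <= 0.0 || d == 0.0) continue;
      double w = f / d;
      for (int k = 0; k < 3; ++k) {
        double comp = w * (P(a, k) - P(b, k));
        F[3 * a + k] += comp;
        F[3 * b + k] -= comp;
      }
    }
    maxdisp = 0.0;
    for (int i = 0; i < n; ++i) {
      double q[3], nq = 0.0, disp2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        q[k] = P(i, k) + dt * F[3 * i + k];
        nq += q[k] * q[k];
      }
      nq = radius / std::sqrt(nq);
      for (int k = 0; k < 3; ++k) {
        q[k] *= nq;
        double dd = q[k] - P(i, k);
        disp2 += dd * dd;
        P(i, k) = q[k];
      }
      maxdisp = std::max(maxdisp, std::sqrt(disp2));
    }
  }
  return List::create(_["points"] = P, _["max_displacement"] = maxdisp);
}
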