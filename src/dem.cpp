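// Soft-sphere DEM core: Hertz-Mindlin (no-slip) normal/tangential contact
// with velocity-proportional damping, Coulomb-capped tangential springs,
// constant-directional rolling-friction torque, optional JKR cohesion, and
// triangle-mesh walls with prescribed rigid-body motion.  Integration is
// semi-implicit (symplectic) Euler.  All quantities SI.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

// Rodrigues rotation of v by angle th about unit axis u.
static inline Vec3 rotate(const Vec3& v, const Vec3& u, double th) {
  double c = std::cos(th), s = std::sin(th);
  return v * c + cross(u, v) * s + u * (dot(u, v) * (1.0 - c));
}

// Closest point on triangle abc to point p (Ericson, Real-Time Collision
// Detection, 5.1.5).
static Vec3 closest_pt_triangle(const Vec3& p, const Vec3& a, const Vec3& b,
                                const Vec3& c) {
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

// --- walls ------------------------------------------------------------------

struct WallMesh {
  std::vector<Vec3> verts;            // body frame
  std::vector<int> tri;               // 3 * ntri indices
  Vec3 axis_point, axis_dir, v_trans;
  double omega;                       // rad/s
  // static uniform grid over body-frame triangle AABBs
  double cell;                        // cell edge
  Vec3 lo;                            // grid origin
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;
  int ntri() const { return (int)tri.size() / 3; }

  void build_grid(double min_cell) {
    int m = ntri();
    Vec3 mn(1e30, 1e30, 1e30), mx(-1e30, -1e30, -1e30);
    double max_edge = 0;
    for (int t = 0; t < m; t++) {
      for (int k = 0; k < 3; k++) {
        const Vec3& v = verts[tri[3 * t + k]];
        mn.x = std::min(mn.x, v.x); mn.y = std::min(mn.y, v.y);
        mn.z = std::min(mn.z, v.z);
        mx.x = std::max(mx.x, v.x); mx.y = std::max(mx.y, v.y);
        mx.z = std::max(mx.z, v.z);
      }
      const Vec3 &a = verts[tri[3 * t]], &b = verts[tri[3 * t + 1]],
                 &c = verts[tri[3 * t + 2]];
      max_edge = std::max(max_edge, norm(b - a));
      max_edge = std::max(max_edge, norm(c - a));
      max_edge = std::max(max_edge, norm(c - b));
    }
    cell = std::max(min_cell, 0.51 * max_edge);
    lo = mn - Vec3(cell, cell, cell);
    nx = (int)((mx.x - lo.x) / cell) + 3;
    ny = (int)((mx.y - lo.y) / cell) + 3;
    nz = (int)((mx.z - lo.z) / cell) + 3;
    cells.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int t = 0; t < m; t++) {
      Vec3 tmn(1e30, 1e30, 1e30), tmx(-1e30, -1e30, -1e30);
      for (int k = 0; k < 3; k++) {
        const Vec3& v = verts[tri[3 * t + k]];
        tmn.x = std::min(tmn.x, v.x); tmn.y = std::min(tmn.y, v.y);
        tmn.z = std::min(tmn.z, v.z);
        tmx.x = std::max(tmx.x, v.x); tmx.y = std::max(tmx.y, v.y);
        tmx.z = std::max(tmx.z, v.z);
      }
      int i0 = (int)((tmn.x - lo.x) / cell), i1 = (int)((tmx.x - lo.x) / cell);
      int j0 = (int)((tmn.y - lo.y) / cell), j1 = (int)((tmx.y - lo.y) / cell);
      int k0 = (int)((tmn.z - lo.z) / cell), k1 = (int)((tmx.z - lo.z) / cell);
      for (int i = i0; i <= i1; i++)
        for (int j = j0; j <= j1; j++)
          for (int k = k0; k <= k1; k++)
            cells[((size_t)i * ny + j) * nz + k].push_back(t);
    }
  }

  // candidate triangles within radius rad of body-frame point q
  void candidates(const Vec3& q, double rad, std::vector<int>& out,
                  std::vector<long long>& stamp, long long tick) const {
    out.clear();
    int i0 = (int)((q.x - rad - lo.x) / cell), i1 = (int)((q.x + rad - lo.x) / cell);
    int j0 = (int)((q.y - rad - lo.y) / cell), j1 = (int)((q.y + rad - lo.y) / cell);
    int k0 = (int)((q.z - rad - lo.z) / cell), k1 = (int)((q.z + rad - lo.z) / cell);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
    i1 = std::min(i1, nx - 1); j1 = std::min(j1, ny - 1); k1 = std::min(k1, nz - 1);
    for (int i = i0; i <= i1; i++)
      for (int j = j0; j <= j1; j++)
        for (int k = k0; k <= k1; k++) {
          const std::vector<int>& cl = cells[((size_t)i * ny + j) * nz + k];
          for (size_t s = 0; s < cl.size(); s++) {
            int t = cl[s];
            if (stamp[t] != tick) { stamp[t] = tick; out.push_back(t); }
          }
        }
  }
};

struct WallContact {
  Vec3 cp, n;
  double overlap;
  int tri;        // source triangle
  int feat[3];    // vertex ids of the closest feature (-1 padded)
  int nfeat;      // 3 = face, 2 = edge, 1 = vertex
};

// barycentric coordinates of p (assumed in the plane region) w.r.t. abc
static void barycentric(const Vec3& p, const Vec3& a, const Vec3& b,
                        const Vec3& c, double* u, double* v, double* w) {
  Vec3 v0 = b - a, v1 = c - a, v2 = p - a;
  double d00 = dot(v0, v0), d01 = dot(v0, v1), d11 = dot(v1, v1);
  double d20 = dot(v2, v0), d21 = dot(v2, v1);
  double denom = d00 * d11 - d01 * d01;
  if (std::fabs(denom) < 1e-30) { *u = 1; *v = 0; *w = 0; return; }
  *v = (d11 * d20 - d01 * d21) / denom;
  *w = (d00 * d21 - d01 * d20) / denom;
  *u = 1.0 - *v - *w;
}

// contacts of sphere (x_lab, r) with a moving wall at time t; results in lab
// frame.  reach extends detection beyond touching (JKR tensile necks).
static void wall_contacts_narrow(const WallMesh& w, const Vec3& x_lab,
                                 double r, double t, double reach,
                                 const std::vector<int>& cand,
                                 std::vector<WallContact>& out) {
  out.clear();
  double th = w.omega * t;
  Vec3 off = w.v_trans * t;
  // body frame: q = R(-th) (x - c - off) + c
  Vec3 q = rotate(x_lab - w.axis_point - off, w.axis_dir, -th) + w.axis_point;
  std::vector<WallContact> raw;
  for (size_t s = 0; s < cand.size(); s++) {
    int tr = cand[s];
    Vec3 cp = closest_pt_triangle(q, w.verts[w.tri[3 * tr]],
                                  w.verts[w.tri[3 * tr + 1]],
                                  w.verts[w.tri[3 * tr + 2]]);
    Vec3 d = q - cp;
    double dist = norm(d);
    if (dist >= r + reach || dist < 1e-14) continue;
    WallContact c;
    c.overlap = r - dist;
    c.n = d * (1.0 / dist);
    c.cp = cp;
    c.tri = tr;
    int ia = w.tri[3 * tr], ib = w.tri[3 * tr + 1], ic = w.tri[3 * tr + 2];
    double bu, bv, bw;
    barycentric(cp, w.verts[ia], w.verts[ib], w.verts[ic], &bu, &bv, &bw);
    c.nfeat = 0;
    const double tol = 1e-9;
    if (bu > tol) c.feat[c.nfeat++] = ia;
    if (bv > tol) c.feat[c.nfeat++] = ib;
    if (bw > tol) c.feat[c.nfeat++] = ic;
    if (c.nfeat == 0) { c.feat[0] = ia; c.nfeat = 1; }
    raw.push_back(c);
  }
  if (raw.empty()) return;
  // face contacts first, then deeper contacts; edge/vertex contacts that
  // duplicate an already-accepted smooth patch are dropped
  std::stable_sort(raw.begin(), raw.end(),
                   [](const WallContact& a, const WallContact& b) {
                     bool fa = a.nfeat == 3, fb = b.nfeat == 3;
                     if (fa != fb) return fa;
                     return a.overlap > b.overlap;
                   });
  const double cos_same = 0.999;       // coplanar duplicate
  const double cos_patch = 0.8192;     // ~35 deg: same smooth patch
  for (size_t i = 0; i < raw.size(); i++) {
    bool dup = false;
    for (size_t j = 0; j < out.size() && !dup; j++) {
      double cn = dot(raw[i].n, out[j].n);
      if (cn > cos_same) { dup = true; break; }
      if (raw[i].nfeat < 3) {
        if (cn > cos_patch) { dup = true; break; }
        // feature entirely shared with an accepted triangle -> adjacent
        bool shared = true;
        for (int f = 0; f < raw[i].nfeat && shared; f++) {
          int vid = raw[i].feat[f];
          shared = vid == w.tri[3 * out[j].tri] ||
                   vid == w.tri[3 * out[j].tri + 1] ||
                   vid == w.tri[3 * out[j].tri + 2];
        }
        if (shared) { dup = true; break; }
      }
    }
    if (!dup) out.push_back(raw[i]);
  }
  // back to lab frame
  for (size_t i = 0; i < out.size(); i++) {
    out[i].n = rotate(out[i].n, w.axis_dir, th);
    out[i].cp = rotate(out[i].cp - w.axis_point, w.axis_dir, th) +
                w.axis_point + off;
  }
}

static void wall_contacts(const WallMesh& w, const Vec3& x_lab, double r,
                          double t, double reach,
                          std::vector<WallContact>& out,
                          std::vector<int>& cand,
                          std::vector<long long>& stamp, long long tick) {
  double th = w.omega * t;
  Vec3 off = w.v_trans * t;
  Vec3 q = rotate(x_lab - w.axis_point - off, w.axis_dir, -th) + w.axis_point;
  w.candidates(q, r + reach, cand, stamp, tick);
  wall_contacts_narrow(w, x_lab, r, t, reach, cand, out);
}

static inline Vec3 wall_velocity(const WallMesh& w, const Vec3& p_lab,
                                 double t) {
  Vec3 c_t = w.axis_point + w.v_trans * t;
  return cross(w.axis_dir * w.omega, p_lab - c_t) + w.v_trans;
}

// --- contact history --------------------------------------------------------

struct Hist {
  Vec3 dt; int last; bool jkr_active;
  Hist() : dt(), last(0), jkr_active(false) {}
};
typedef std::unordered_map<uint64_t, Hist> HistMap;

struct PPair { int i, j; Hist h; };

// --- pair property lookup ---------------------------------------------------

struct PairProps {
  // (nmat+1) x (nmat+1); wall index = nmat
  int n;
  std::vector<double> Estar, Gstar, beta, mus, mur, gamma;
  double at(const std::vector<double>& v, int a, int b) const {
    return v[(size_t)a * n + b];
  }
};

// JKR helpers: contact radius from overlap on the stable outer branch.
static double jkr_radius(double delta, double gamma, double Estar,
                         double Rstar, double* dmin_out) {
  double cc = std::sqrt(4.0 * M_PI * gamma / Estar);
  double ac = std::pow(cc * Rstar / 4.0, 2.0 / 3.0);
  double dmin = ac * ac / Rstar - cc * std::sqrt(ac);
  if (dmin_out) *dmin_out = dmin;
  if (delta < dmin) return -1.0;
  double a = std::max(std::sqrt(Rstar * std::max(delta, 0.0)), 2.0 * ac);
  for (int it = 0; it < 50; it++) {
    double f = a * a / Rstar - cc * std::sqrt(a) - delta;
    double fp = 2.0 * a / Rstar - cc / (2.0 * std::sqrt(a));
    double an = a - f / fp;
    if (an < ac) an = 0.5 * (a + ac);
    if (std::fabs(an - a) < 1e-16 + 1e-12 * a) { a = an; break; }
    a = an;
  }
  return a;
}

// One contact force/torque evaluation shared by pp and pw paths.
// n points from partner toward particle i; returns force on i; tq_i/tq_j get
// torque increments.  fn_cap_out reports |normal force| for wall-load use.
struct ContactOut { Vec3 F; Vec3 tq_i; Vec3 tq_j; bool active; };

static ContactOut contact_force(double delta, const Vec3& n, const Vec3& cp,
                                const Vec3& xi, const Vec3& vi, const Vec3& wi,
                                const Vec3* xj, const Vec3* vj, const Vec3* wj,
                                const Vec3* vwall,
                                double Estar, double Gstar, double beta,
                                double mus, double mur, double gamma,
                                double Rstar, double mstar, double dt_step,
                                Hist& h) {
  ContactOut out;
  out.active = false;
  bool cohesive = gamma > 0.0;
  if (!cohesive && delta <= 0.0) return out;
  double dmin = 0.0, fn = 0.0;
  if (cohesive) {
    bool was = h.jkr_active;
    if (!was && delta <= 0.0) return out;          // approach: touch first
    double a = jkr_radius(delta, gamma, Estar, Rstar, &dmin);
    if (a < 0.0) { h.jkr_active = false; return out; }   // snapped off
    h.jkr_active = true;
    fn = -4.0 * std::sqrt(M_PI * gamma * Estar) * a * std::sqrt(a) +
         (4.0 * Estar / (3.0 * Rstar)) * a * a * a;
  } else {
    fn = (4.0 / 3.0) * Estar * std::sqrt(Rstar) * delta * std::sqrt(delta);
  }
  // relative velocity of i w.r.t. partner at the contact point
  Vec3 vrel = vi + cross(wi, cp - xi);
  if (xj) vrel -= (*vj + cross(*wj, cp - *xj));
  else if (vwall) vrel -= *vwall;
  double vn = dot(vrel, n);
  Vec3 vt = vrel - n * vn;
  double fn_total = fn;
  if (delta > 0.0) {
    double Sn = 2.0 * Estar * std::sqrt(Rstar * delta);
    fn_total += -2.0 * std::sqrt(5.0 / 6.0) * beta *
                std::sqrt(Sn * mstar) * vn;
  }
  Vec3 F = n * fn_total;
  Vec3 Ft(0, 0, 0);
  if (delta > 0.0) {
    double St = 8.0 * Gstar * std::sqrt(Rstar * delta);
    Vec3 dtv = h.dt + vt * dt_step;
    dtv -= n * dot(dtv, n);                        // keep in tangent plane
    Ft = dtv * (-St) + vt * (-2.0 * std::sqrt(5.0 / 6.0) * beta *
                             std::sqrt(St * mstar));
    double cap = mus * std::fabs(fn_total);
    double mag = norm(Ft);
    if (mag > cap && mag > 0.0) {
      Ft = Ft * (cap / mag);
      if (St > 0.0) dtv = Ft * (-1.0 / St);
    }
    h.dt = dtv;
    F += Ft;
  } else {
    h.dt = Vec3(0, 0, 0);
  }
  out.F = F;
  // torques: tangential force lever arm + rolling resistance
  Vec3 ri = cp - xi;
  out.tq_i = cross(ri, Ft);
  double wmag = norm(wi);
  double Rp_i = norm(ri);
  if (wmag > 1e-12 && mur > 0.0)
    out.tq_i += wi * (-mur * std::fabs(fn_total) * Rp_i / wmag);
  if (xj) {
    Vec3 rj = cp - *xj;
    out.tq_j = cross(rj, Ft * (-1.0));
    const Vec3& wjv = *wj;
    double wjm = norm(wjv);
    if (wjm > 1e-12 && mur > 0.0)
      out.tq_j += wjv * (-mur * std::fabs(fn_total) * norm(rj) / wjm);
  }
  out.active = true;
  return out;
}

// --- particle neighbour grid ------------------------------------------------

struct PGrid {
  double cell;
  std::unordered_map<int64_t, std::vector<int> > map;
  static int64_t key(int i, int j, int k) {
    return ((int64_t)(i + 1048576) << 42) | ((int64_t)(j + 1048576) << 21) |
           (int64_t)(k + 1048576);
  }
  void build(const std::vector<Vec3>& X, double cell_) {
    cell = cell_;
    map.clear();
    for (size_t i = 0; i < X.size(); i++) {
      int a = (int)std::floor(X[i].x / cell), b = (int)std::floor(X[i].y / cell),
          c = (int)std::floor(X[i].z / cell);
      map[key(a, b, c)].push_back((int)i);
    }
  }
  template <class F>
  void for_pairs(const std::vector<Vec3>& X, F fn) const {
    for (std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
             map.begin(); it != map.end(); ++it) {
      int64_t k = it->first;
      int ci = (int)((k >> 42) & 0x1FFFFF) - 1048576;
      int cj = (int)((k >> 21) & 0x1FFFFF) - 1048576;
      int ck = (int)(k & 0x1FFFFF) - 1048576;
      const std::vector<int>& A = it->second;
      for (int di = -1; di <= 1; di++)
        for (int dj = -1; dj <= 1; dj++)
          for (int dk = -1; dk <= 1; dk++) {
            int64_t nk = key(ci + di, cj + dj, ck + dk);
            if (nk < k) continue;   // visit each unordered cell pair once
            std::unordered_map<int64_t, std::vector<int> >::const_iterator jt =
                map.find(nk);
            if (jt == map.end()) continue;
            const std::vector<int>& B = jt->second;
            if (nk == k) {
              for (size_t a = 0; a < A.size(); a++)
                for (size_t b = a + 1; b < A.size(); b++) fn(A[a], A[b]);
            } else {
              for (size_t a = 0; a < A.size(); a++)
                for (size_t b = 0; b < B.size(); b++) fn(A[a], B[b]);
            }
          }
    }
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix X, NumericVector radius,
                                 double cutoff) {
  int n = X.nrow();
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; i++) P[i] = Vec3(X(i, 0), X(i, 1), X(i, 2));
  PGrid g;
  g.build(P, cutoff);
  std::vector<std::pair<int, int> > pairs;
  g.for_pairs(P, [&](int i, int j) {
    if (norm(P[i] - P[j]) <= cutoff) {
      pairs.push_back(std::make_pair(std::min(i, j), std::max(i, j)));
    }
  });
  std::sort(pairs.begin(), pairs.end());
  pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t p = 0; p < pairs.size(); p++) {
    out(p, 0) = pairs[p].first + 1;
    out(p, 1) = pairs[p].second + 1;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_wall_contact(NumericVector x, double r, List wall, double t,
                      double reach) {
  WallMesh w;
  NumericMatrix V = wall["vertices"];
  IntegerMatrix T = wall["triangles"];
  for (int i = 0; i < V.nrow(); i++)
    w.verts.push_back(Vec3(V(i, 0), V(i, 1), V(i, 2)));
  for (int i = 0; i < T.nrow(); i++) {
    w.tri.push_back(T(i, 0) - 1);
    w.tri.push_back(T(i, 1) - 1);
    w.tri.push_back(T(i, 2) - 1);
  }
  NumericVector ap = wall["axis_point"], ad = wall["axis_dir"],
                vt = wall["v_trans"];
  w.axis_point = Vec3(ap[0], ap[1], ap[2]);
  w.axis_dir = Vec3(ad[0], ad[1], ad[2]);
  w.v_trans = Vec3(vt[0], vt[1], vt[2]);
  w.omega = as<double>(wall["omega"]);
  w.build_grid(2.0 * r);
  std::vector<int> cand;
  std::vector<long long> stamp(w.ntri(), -1);
  std::vector<WallContact> cs;
  wall_contacts(w, Vec3(x[0], x[1], x[2]), r, t, reach, cs, cand, stamp, 0);
  int m = (int)cs.size();
  NumericMatrix cp(m, 3), nn(m, 3), wv(m, 3);
  NumericVector ov(m);
  for (int i = 0; i < m; i++) {
    cp(i, 0) = cs[i].cp.x; cp(i, 1) = cs[i].cp.y; cp(i, 2) = cs[i].cp.z;
    nn(i, 0) = cs[i].n.x;  nn(i, 1) = cs[i].n.y;  nn(i, 2) = cs[i].n.z;
    ov[i] = cs[i].overlap;
    Vec3 v = wall_velocity(w, cs[i].cp, t);
    wv(i, 0) = v.x; wv(i, 1) = v.y; wv(i, 2) = v.z;
  }
  return List::create(_["point"] = cp, _["normal"] = nn, _["overlap"] = ov,
                      _["wall_velocity"] = wv);
}

// [[Rcpp::export]]
List cpp_dem_run(NumericMatrix X0, NumericMatrix V0, NumericMatrix W0,
                 NumericVector radius, IntegerVector mat0,
                 NumericVector mass,
                 NumericMatrix PEstar, NumericMatrix PGstar,
                 NumericMatrix PBeta, NumericMatrix PMuS,
                 NumericMatrix PMuR, NumericMatrix PGamma,
                 List walls_in, NumericVector gravity,
                 double dt, int nsteps, int save_every, double t0,
                 double domain_radius, int integrator) {
  const int n = X0.nrow();
  const int nmat = PEstar.nrow() - 1;   // last index is the wall material
  std::vector<Vec3> X(n), V(n), W(n), F(n), TQ(n);
  std::vector<double> R(n), M(n), I(n);
  std::vector<int> mat(n);
  double rmax = 0.0;
  for (int i = 0; i < n; i++) {
    X[i] = Vec3(X0(i, 0), X0(i, 1), X0(i, 2));
    V[i] = Vec3(V0(i, 0), V0(i, 1), V0(i, 2));
    W[i] = Vec3(W0(i, 0), W0(i, 1), W0(i, 2));
    R[i] = radius[i];
    M[i] = mass[i];
    I[i] = 0.4 * mass[i] * radius[i] * radius[i];
    mat[i] = mat0[i] - 1;
    rmax = std::max(rmax, R[i]);
  }
  PairProps pp;
  pp.n = nmat + 1;
  int np2 = pp.n * pp.n;
  pp.Estar.resize(np2); pp.Gstar.resize(np2); pp.beta.resize(np2);
  pp.mus.resize(np2); pp.mur.resize(np2); pp.gamma.resize(np2);
  for (int a = 0; a < pp.n; a++)
    for (int b = 0; b < pp.n; b++) {
      pp.Estar[(size_t)a * pp.n + b] = PEstar(a, b);
      pp.Gstar[(size_t)a * pp.n + b] = PGstar(a, b);
      pp.beta[(size_t)a * pp.n + b] = PBeta(a, b);
      pp.mus[(size_t)a * pp.n + b] = PMuS(a, b);
      pp.mur[(size_t)a * pp.n + b] = PMuR(a, b);
      pp.gamma[(size_t)a * pp.n + b] = PGamma(a, b);
    }
  // walls
  std::vector<WallMesh> walls;
  for (int wi = 0; wi < walls_in.size(); wi++) {
    List wl = walls_in[wi];
    WallMesh w;
    NumericMatrix Vm = wl["vertices"];
    IntegerMatrix Tm = wl["triangles"];
    for (int i = 0; i < Vm.nrow(); i++)
      w.verts.push_back(Vec3(Vm(i, 0), Vm(i, 1), Vm(i, 2)));
    for (int i = 0; i < Tm.nrow(); i++) {
      w.tri.push_back(Tm(i, 0) - 1);
      w.tri.push_back(Tm(i, 1) - 1);
      w.tri.push_back(Tm(i, 2) - 1);
    }
    NumericVector ap = wl["axis_point"], ad = wl["axis_dir"],
                  vt = wl["v_trans"];
    w.axis_point = Vec3(ap[0], ap[1], ap[2]);
    w.axis_dir = Vec3(ad[0], ad[1], ad[2]);
    w.v_trans = Vec3(vt[0], vt[1], vt[2]);
    w.omega = as<double>(wl["omega"]);
    w.build_grid(2.5 * rmax);
    walls.push_back(w);
  }
  Vec3 g(gravity[0], gravity[1], gravity[2]);
  const double reach = 0.01 * rmax;     // JKR tensile detection margin
  PGrid grid;
  // Verlet (skin) lists: particle pairs and per-particle wall-triangle
  // candidates are rebuilt only after relative motion can have covered
  // half the skin
  const double skin = 0.9 * rmax;
  std::vector<PPair> vpairs;
  double wall_speed = 0.0;
  for (size_t wi = 0; wi < walls.size(); wi++) {
    double rad = 0.0;
    for (size_t v = 0; v < walls[wi].verts.size(); v++) {
      Vec3 d = walls[wi].verts[v] - walls[wi].axis_point;
      d -= walls[wi].axis_dir * dot(d, walls[wi].axis_dir);
      rad = std::max(rad, norm(d));
    }
    wall_speed = std::max(wall_speed,
                          std::fabs(walls[wi].omega) * rad +
                              norm(walls[wi].v_trans));
  }
  std::vector<std::vector<std::vector<int> > > wcand(walls.size());
  for (size_t wi = 0; wi < walls.size(); wi++) wcand[wi].resize(n);
  // up to 4 concurrent contacts per particle per wall, slot-indexed
  std::vector<std::vector<Hist> > whist(walls.size());
  for (size_t wi = 0; wi < walls.size(); wi++) whist[wi].resize(4 * n);
  double travel = 1e30;                 // force initial rebuild
  int nsave = nsteps / save_every;
  NumericVector times(nsave), ke(nsave);
  List snapX(nsave), snapV(nsave), snapW(nsave);
  int nw = (int)walls.size();
  NumericMatrix wall_torque(nsave, nw), wall_fax(nsave, nw);
  std::vector<double> acc_tq(nw, 0.0), acc_fa(nw, 0.0);
  std::vector<int> cand;
  std::vector<std::vector<long long> > stamps(nw);
  for (int wi = 0; wi < nw; wi++) stamps[wi].assign(walls[wi].ntri(), -1);
  long long tick = 0;
  std::vector<WallContact> wcs;
  int isave = 0;
  double cellsz = 2.05 * rmax + reach;
  int stamp_step = 0;
  // evaluates all contact forces/torques at time tnow into F/TQ;
  // hist_dt scales tangential-history advancement, load_w weights the
  // wall-load accumulators (velocity Verlet evaluates forces twice per dt)
  auto rebuild_lists = [&](double t) {
    // carry active tangential springs / JKR state across the rebuild
    HistMap carry;
    for (size_t p = 0; p < vpairs.size(); p++) {
      const PPair& vp = vpairs[p];
      if (vp.h.jkr_active || dot(vp.h.dt, vp.h.dt) > 0.0)
        carry[((uint64_t)vp.i << 32) | (uint64_t)vp.j] = vp.h;
    }
    grid.build(X, cellsz + skin);
    vpairs.clear();
    grid.for_pairs(X, [&](int i, int j) {
      if (norm(X[i] - X[j]) < R[i] + R[j] + skin + reach) {
        PPair vp;
        vp.i = std::min(i, j); vp.j = std::max(i, j);
        HistMap::iterator it =
            carry.find(((uint64_t)vp.i << 32) | (uint64_t)vp.j);
        if (it != carry.end()) vp.h = it->second;
        vpairs.push_back(vp);
      }
    });
    for (size_t wi = 0; wi < walls.size(); wi++) {
      const WallMesh& w = walls[wi];
      double th = w.omega * t;
      Vec3 off = w.v_trans * t;
      for (int i = 0; i < n; i++) {
        Vec3 q = rotate(X[i] - w.axis_point - off, w.axis_dir, -th) +
                 w.axis_point;
        tick++;
        w.candidates(q, R[i] + skin + reach, wcand[wi][i], stamps[wi], tick);
      }
    }
    travel = 0.0;
  };
  auto compute_forces = [&](double t, double hist_dt, double load_w) {
    for (int i = 0; i < n; i++) { F[i] = Vec3(0, 0, 0); TQ[i] = Vec3(0, 0, 0); }
    if (travel > 0.5 * skin) rebuild_lists(t);
    // particle-particle
    for (size_t pidx = 0; pidx < vpairs.size(); pidx++) {
      PPair& vp = vpairs[pidx];
      int i = vp.i, j = vp.j;
      Vec3 d = X[i] - X[j];
      double d2 = dot(d, d);
      double touch = R[i] + R[j];
      int a = mat[i], b = mat[j];
      double gam = pp.at(pp.gamma, a, b);
      double lim = touch + (gam > 0 ? reach : 0.0);
      if (d2 >= lim * lim || d2 < 1e-28) {
        if (vp.h.jkr_active || vp.h.dt.x != 0.0 || vp.h.dt.y != 0.0 ||
            vp.h.dt.z != 0.0)
          vp.h = Hist();
        continue;
      }
      double dist = std::sqrt(d2);
      double delta = touch - dist;
      Vec3 nrm = d * (1.0 / dist);
      Vec3 cp = X[j] + nrm * (R[j] - 0.5 * delta);
      double Rstar = 1.0 / (1.0 / R[i] + 1.0 / R[j]);
      double mstar = 1.0 / (1.0 / M[i] + 1.0 / M[j]);
      ContactOut c = contact_force(
          delta, nrm, cp, X[i], V[i], W[i], &X[j], &V[j], &W[j], NULL,
          pp.at(pp.Estar, a, b), pp.at(pp.Gstar, a, b), pp.at(pp.beta, a, b),
          pp.at(pp.mus, a, b), pp.at(pp.mur, a, b), gam, Rstar, mstar,
          hist_dt, vp.h);
      if (c.active) {
        F[i] += c.F; F[j] -= c.F;
        TQ[i] += c.tq_i; TQ[j] += c.tq_j;
      } else {
        vp.h = Hist();
      }
    }
    // particle-wall
    for (int wi = 0; wi < nw; wi++) {
      WallMesh& w = walls[wi];
      for (int i = 0; i < n; i++) {
        int a = mat[i];
        if (wcand[wi][i].empty()) continue;
        double gam = pp.at(pp.gamma, a, nmat);
        wall_contacts_narrow(w, X[i], R[i], t, gam > 0 ? reach : 0.0,
                             wcand[wi][i], wcs);
        for (size_t ci = 0; ci < wcs.size() && ci < 4; ci++) {
          const WallContact& wc = wcs[ci];
          Hist& h = whist[wi][4 * i + ci];
          Vec3 vw = wall_velocity(w, wc.cp, t);
          ContactOut c = contact_force(
              wc.overlap, wc.n, wc.cp, X[i], V[i], W[i], NULL, NULL, NULL,
              &vw, pp.at(pp.Estar, a, nmat), pp.at(pp.Gstar, a, nmat),
              pp.at(pp.beta, a, nmat), pp.at(pp.mus, a, nmat),
              pp.at(pp.mur, a, nmat), gam, R[i], M[i], hist_dt, h);
          if (c.active) {
            F[i] += c.F;
            TQ[i] += c.tq_i;
            // reaction on the wall: torque about its axis + axial force
            Vec3 Fw = c.F * (-1.0);
            Vec3 c_t = w.axis_point + w.v_trans * t;
            acc_tq[wi] += load_w * dot(cross(wc.cp - c_t, Fw), w.axis_dir);
            acc_fa[wi] += load_w * dot(Fw, w.axis_dir);
          } else {
            h = Hist();
          }
        }
      }
    }
  };
  for (int step = 0; step < nsteps; step++) {
    double t = t0 + step * dt;
    stamp_step = step + 1;
    if (integrator == 1) {
      // velocity Verlet (kick-drift-kick); second order also through the
      // velocity-dependent damping to good approximation
      compute_forces(t, 0.5 * dt, 0.5);
      for (int i = 0; i < n; i++) {
        V[i] += (F[i] * (1.0 / M[i]) + g) * (0.5 * dt);
        W[i] += TQ[i] * (1.0 / I[i]) * (0.5 * dt);
        X[i] += V[i] * dt;
      }
      compute_forces(t + dt, 0.5 * dt, 0.5);
      for (int i = 0; i < n; i++) {
        V[i] += (F[i] * (1.0 / M[i]) + g) * (0.5 * dt);
        W[i] += TQ[i] * (1.0 / I[i]) * (0.5 * dt);
      }
    } else {
      // semi-implicit (symplectic) Euler
      compute_forces(t, dt, 1.0);
      for (int i = 0; i < n; i++) {
        V[i] += (F[i] * (1.0 / M[i]) + g) * dt;
        X[i] += V[i] * dt;
        W[i] += TQ[i] * (1.0 / I[i]) * dt;
      }
    }
    double vmax2 = 0.0;
    for (int i = 0; i < n; i++) vmax2 = std::max(vmax2, dot(V[i], V[i]));
    travel += dt * (std::sqrt(vmax2) + wall_speed);
    if ((step + 1) % 500 == 0) Rcpp::checkUserInterrupt();
    if ((step + 1) % save_every == 0) {
      double K = 0.0;
      NumericMatrix SX(n, 3), SV(n, 3), SW(n, 3);
      bool bad = false;
      for (int i = 0; i < n; i++) {
        SX(i, 0) = X[i].x; SX(i, 1) = X[i].y; SX(i, 2) = X[i].z;
        SV(i, 0) = V[i].x; SV(i, 1) = V[i].y; SV(i, 2) = V[i].z;
        SW(i, 0) = W[i].x; SW(i, 1) = W[i].y; SW(i, 2) = W[i].z;
        K += 0.5 * M[i] * dot(V[i], V[i]);
        if (!R_FINITE(X[i].x) || !R_FINITE(V[i].x)) bad = true;
        if (norm(X[i]) > domain_radius) bad = true;
      }
      if (bad)
        stop("integration failure at step %d (t = %g): non-finite state or "
             "particle escaped the domain; reduce dt", step + 1,
             t0 + (step + 1) * dt);
      times[isave] = t0 + (step + 1) * dt;
      ke[isave] = K;
      snapX[isave] = SX; snapV[isave] = SV; snapW[isave] = SW;
      for (int wi = 0; wi < nw; wi++) {
        wall_torque(isave, wi) = acc_tq[wi] / save_every;
        wall_fax(isave, wi) = acc_fa[wi] / save_every;
        acc_tq[wi] = 0.0; acc_fa[wi] = 0.0;
      }
      isave++;
    }
  }
  return List::create(_["times"] = times, _["X"] = snapX, _["V"] = snapV,
                      _["W"] = snapW, _["kinetic_energy"] = ke,
                      _["wall_torque"] = wall_torque,
                      _["wall_axial_force"] = wall_fax);
}
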