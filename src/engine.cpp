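// Explicit DEM engine: velocity-Verlet integration of free spheres, bonded
// multi-sphere (BMS) sub-spheres and rigid (CMS) clusters, with Hertz-Mindlin
// or adhesive elastic-plastic multi-contact normal laws, Coulomb-capped
// tangential springs, constant-directional-torque rolling friction, permanent
// bonds, plane walls (possibly moving) and periodic boundaries.
//
// The R layer owns all model configuration; this file owns the hot loop.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Hist {
  double sx = 0, sy = 0, sz = 0;  // tangential spring (m)
  double d0 = 0;                  // plastic overlap (m)
  bool touched = false;
};

struct WallDef {
  double n[3];   // unit normal pointing toward the particles
  double p[3];   // a point on the plane
  double v[3];   // plane velocity
  int mat;       // 0-based material index
};

struct RigidBody {
  std::vector<int> members;            // 0-based sphere indices
  std::vector<double> off;             // 3*n body-frame (principal) offsets
  double mass = 0;
  double I[3] = {0, 0, 0};             // principal moments
  double q[4] = {1, 0, 0, 0};          // orientation quaternion (w,x,y,z)
  double com[3] = {0, 0, 0};
  double vcom[3] = {0, 0, 0};
  double wb[3] = {0, 0, 0};            // angular velocity, body frame
  double F[3] = {0, 0, 0};
  double T[3] = {0, 0, 0};
  bool fix_rotation = false;   // compression-rig guide: no tumbling
  bool fix_lateral = false;    // compression-rig guide: z translation only
};

inline void quat_to_mat(const double *q, double *R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

inline void quat_mult(const double *a, const double *b, double *out) {
  out[0] = a[0] * b[0] - a[1] * b[1] - a[2] * b[2] - a[3] * b[3];
  out[1] = a[0] * b[1] + a[1] * b[0] + a[2] * b[3] - a[3] * b[2];
  out[2] = a[0] * b[2] - a[1] * b[3] + a[2] * b[0] + a[3] * b[1];
  out[3] = a[0] * b[3] + a[1] * b[2] - a[2] * b[1] + a[3] * b[0];
}

inline void quat_normalize(double *q) {
  double s = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  for (int k = 0; k < 4; ++k) q[k] /= s;
}

inline void cross(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

struct Engine {
  // spheres
  int N = 0;
  std::vector<double> x, v, w;        // 3N
  std::vector<double> r, m, inert, vol;
  std::vector<int> mat;               // 0-based
  std::vector<int> body;              // -1 free, else body index
  std::vector<char> is_cms;           // member of a rigid body
  std::vector<int> kind;              // per body: 1 BMS, 2 CMS
  std::vector<RigidBody> rigids;      // indexed by body where kind == 2
  std::vector<int> rigid_of_body;

  // forces and per-step accumulators
  std::vector<double> F, T, a_lin, a_ang;
  std::vector<double> sig;            // 6N: xx,yy,zz,xy,xz,yz (compression +)
  std::vector<double> P, Pnew;        // lagged mean pressure

  // bonds
  int NB = 0;
  std::vector<int> bi, bj;
  std::vector<double> bL0, bA, box_, boy_, boz_;
  double knb = 0, ktb = 0, bond_zeta = 0;
  std::unordered_set<int64_t> bondkey;

  // walls and domain
  std::vector<WallDef> walls;
  double lo[3], hi[3];
  bool periodic[3] = {false, false, false};
  double grav[3] = {0, 0, 0};

  // material pair tables (M x M)
  int M = 0;
  std::vector<double> Estar, Gstar, numean, dampA, mu, mur;

  // model
  int normal_model = 0;    // 0 hertz, 1 elastoplastic
  int tang_law = 0;        // 0 mindlin, 1 as_printed
  double ep_f0 = 0, ep_k1s = 1, ep_k2r = 5, ep_kcr = 0, ep_beta = 0;

  // contact history
  int64_t stride = 0;
  std::unordered_map<int64_t, Hist> hist;

  // neighbor list
  std::vector<std::pair<int, int>> pairs;
  std::vector<double> x_at_build;
  double skin = 0, rmax = 0, rmin = 0;
  bool use_cells = true;

  // wall reactions (3 per wall), energy
  std::vector<double> wallF;
  double ke = 0;

  double time = 0;

  inline int64_t key(int i, int j) const {
    return static_cast<int64_t>(i) * stride + j;
  }

  inline void minimg(double *d) const {
    for (int k = 0; k < 3; ++k) {
      if (periodic[k]) {
        double L = hi[k] - lo[k];
        d[k] -= L * std::round(d[k] / L);
      }
    }
  }

  void build_pairs() {
    pairs.clear();
    const double skin2cut = skin;
    bool cells_ok = use_cells;
    double cell = 2 * rmax + skin2cut;
    int nc[3];
    double span[3];
    double mn[3] = {1e300, 1e300, 1e300}, mx[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) {
        mn[k] = std::min(mn[k], x[3 * i + k]);
        mx[k] = std::max(mx[k], x[3 * i + k]);
      }
    for (int k = 0; k < 3; ++k) {
      if (periodic[k]) {
        span[k] = hi[k] - lo[k];
        mn[k] = lo[k];
      } else {
        span[k] = mx[k] - mn[k] + cell;
      }
      nc[k] = std::max(1, static_cast<int>(std::floor(span[k] / cell)));
      if (periodic[k] && nc[k] < 3) cells_ok = false;
    }
    if (N <= 64) cells_ok = false;
    if (cells_ok) {
      std::unordered_map<int64_t, std::vector<int>> cells;
      cells.reserve(N * 2);
      auto cellid = [&](int cx, int cy, int cz) {
        return (static_cast<int64_t>(cx) * nc[1] + cy) * nc[2] + cz;
      };
      std::vector<int> ci(3 * N);
      for (int i = 0; i < N; ++i) {
        for (int k = 0; k < 3; ++k) {
          int c = static_cast<int>(std::floor((x[3 * i + k] - mn[k]) / cell));
          if (periodic[k]) {
            c %= nc[k];
            if (c < 0) c += nc[k];
          } else {
            c = std::max(0, std::min(nc[k] - 1, c));
          }
          ci[3 * i + k] = c;
        }
        cells[cellid(ci[3 * i], ci[3 * i + 1], ci[3 * i + 2])].push_back(i);
      }
      std::vector<int> cand;
      for (int i = 0; i < N; ++i) {
        cand.clear();
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              int cx = ci[3 * i] + ox, cy = ci[3 * i + 1] + oy,
                  cz = ci[3 * i + 2] + oz;
              if (periodic[0]) { cx = (cx % nc[0] + nc[0]) % nc[0]; }
              else if (cx < 0 || cx >= nc[0]) continue;
              if (periodic[1]) { cy = (cy % nc[1] + nc[1]) % nc[1]; }
              else if (cy < 0 || cy >= nc[1]) continue;
              if (periodic[2]) { cz = (cz % nc[2] + nc[2]) % nc[2]; }
              else if (cz < 0 || cz >= nc[2]) continue;
              auto it = cells.find(cellid(cx, cy, cz));
              if (it == cells.end()) continue;
              for (int j : it->second)
                if (j > i) cand.push_back(j);
            }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        for (int j : cand) {
          double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                         x[3 * i + 2] - x[3 * j + 2]};
          minimg(d);
          double cut = r[i] + r[j] + skin2cut;
          if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < cut * cut)
            pairs.emplace_back(i, j);
        }
      }
    } else {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                         x[3 * i + 2] - x[3 * j + 2]};
          minimg(d);
          double cut = r[i] + r[j] + skin2cut;
          if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < cut * cut)
            pairs.emplace_back(i, j);
        }
    }
    std::sort(pairs.begin(), pairs.end());
    x_at_build = x;
  }

  bool need_rebuild() const {
    if (x_at_build.empty()) return true;
    double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < N; ++i) {
      double dx = x[3 * i] - x_at_build[3 * i];
      double dy = x[3 * i + 1] - x_at_build[3 * i + 1];
      double dz = x[3 * i + 2] - x_at_build[3 * i + 2];
      if (dx * dx + dy * dy + dz * dz > lim2) return true;
    }
    return false;
  }

  // accumulate the compression-positive Love-Weber stress on sphere i
  inline void add_stress(int i, const double *rel, const double *f) {
    double *s = &sig[6 * i];
    double invv = 1.0 / vol[i];
    s[0] -= rel[0] * f[0] * invv;
    s[1] -= rel[1] * f[1] * invv;
    s[2] -= rel[2] * f[2] * invv;
    s[3] -= 0.5 * (rel[0] * f[1] + rel[1] * f[0]) * invv;
    s[4] -= 0.5 * (rel[0] * f[2] + rel[2] * f[0]) * invv;
    s[5] -= 0.5 * (rel[1] * f[2] + rel[2] * f[1]) * invv;
  }

  // resolve one contact; j >= 0 for a sphere partner, j == -1-widx for walls.
  // nrm points from j to i; delta > 0; cp is the contact point.
  // When `bonded` the rolling torque is skipped.
  void resolve_contact(int i, int j, const double *nrm, double delta,
                       const double *cp, double dt_hist, bool bonded,
                       int widx) {
    bool is_wall = (j < 0);
    int mi = mat[i];
    int mj = is_wall ? walls[widx].mat : mat[j];
    int mp = mi * M + mj;
    double Rstar, mstar;
    const double *vj, *wj;
    double wall_w[3] = {0, 0, 0};
    if (is_wall) {
      Rstar = r[i];
      mstar = m[i];
      vj = walls[widx].v;
      wj = wall_w;
    } else {
      Rstar = r[i] * r[j] / (r[i] + r[j]);
      mstar = m[i] * m[j] / (m[i] + m[j]);
      vj = &v[3 * j];
      wj = &w[3 * j];
    }
    const double *xi = &x[3 * i];
    const double *vi = &v[3 * i];
    const double *wi = &w[3 * i];

    // branch vectors from each center to the contact point; j's is built
    // from the geometry so it stays valid across periodic images. Deep
    // overlaps (delta > 2r, possible for small CMS members swallowed by a
    // plate) clamp the arm at zero: the contact never acts beyond a center.
    double arm_i = is_wall ? (r[i] - delta) : (r[i] - delta / 2);
    if (arm_i < 0) arm_i = 0;
    double ri_c[3] = {-arm_i * nrm[0], -arm_i * nrm[1], -arm_i * nrm[2]};
    double rj_c[3] = {0, 0, 0};
    double wxri[3], wxrj[3] = {0, 0, 0};
    cross(wi, ri_c, wxri);
    if (!is_wall) {
      double arm = r[j] - delta / 2;
      if (arm < 0) arm = 0;
      rj_c[0] = arm * nrm[0];
      rj_c[1] = arm * nrm[1];
      rj_c[2] = arm * nrm[2];
      cross(wj, rj_c, wxrj);
    }
    double vrel[3];
    for (int k = 0; k < 3; ++k)
      vrel[k] = (vi[k] + wxri[k]) - (vj[k] + wxrj[k]);
    double vn_c = (vi[0] - vj[0]) * nrm[0] + (vi[1] - vj[1]) * nrm[1] +
                  (vi[2] - vj[2]) * nrm[2];
    double ddot = -vn_c;  // positive while approaching
    double vrel_n = vrel[0] * nrm[0] + vrel[1] * nrm[1] + vrel[2] * nrm[2];
    double vt[3] = {vrel[0] - vrel_n * nrm[0], vrel[1] - vrel_n * nrm[1],
                    vrel[2] - vrel_n * nrm[2]};

    int64_t k = key(i, is_wall ? static_cast<int>(N + widx) : j);
    Hist &h = hist[k];
    h.touched = true;

    // ---- normal force ----
    double es = Estar[mp], gs = Gstar[mp];
    double sqRd = std::sqrt(Rstar * delta);
    double kn_hertz = 4.0 / 3.0 * es * std::sqrt(Rstar);
    double fn;
    double k1s = 1.0;
    if (normal_model == 1) {
      k1s = ep_k1s;
      double k1 = k1s * kn_hertz;
      double k2 = ep_k2r * k1;
      double kc = ep_kcr * k1;
      double d32 = delta * std::sqrt(delta);
      double d032 = h.d0 * std::sqrt(h.d0);
      double f_unl = k2 * (d32 - d032);
      double f_load = k1 * d32;
      double f_adh = -kc * d32;
      double fb;
      if (f_unl >= f_load) {
        fb = f_load;
        h.d0 = std::cbrt(d32 * (1.0 - k1 / k2));
        h.d0 = h.d0 * h.d0;  // (d32*(1-k1/k2))^(2/3)
      } else if (f_unl <= f_adh) {
        fb = f_adh;
        double t = std::cbrt(d32 * (1.0 + kc / k2));
        h.d0 = t * t;
      } else {
        fb = f_unl;
      }
      // Hertz circle, capped at the smaller sphere's cross-section
      double rmin_c = is_wall ? r[i] : std::min(r[i], r[j]);
      double area = M_PI * std::min(Rstar * delta, rmin_c * rmin_c);
      double pij = is_wall ? P[i] : 0.5 * (P[i] + P[j]);
      fn = ep_f0 + fb + ep_beta * numean[mp] * area * pij;
    } else {
      fn = kn_hertz * delta * std::sqrt(delta);  // kn * delta^{3/2}
    }
    // viscous normal damping (restitution-calibrated)
    double Sn = 2.0 * es * sqRd * k1s;
    double gn = dampA[mp] * std::sqrt(Sn * mstar);
    fn += gn * ddot;
    if (normal_model == 0 && fn < 0) fn = 0;  // Hertz carries no tension

    // ---- tangential force ----
    double s[3] = {h.sx, h.sy, h.sz};
    double sn = s[0] * nrm[0] + s[1] * nrm[1] + s[2] * nrm[2];
    for (int kk = 0; kk < 3; ++kk)
      s[kk] = s[kk] - sn * nrm[kk] + vt[kk] * dt_hist;
    double ft[3] = {0, 0, 0};
    double fn_cap = fn > 0 ? fn : 0;
    double kt_lin = 8.0 * gs * sqRd * k1s;
    double St = kt_lin;
    double gt = dampA[mp] * std::sqrt(St * mstar);
    double smag = std::sqrt(s[0] * s[0] + s[1] * s[1] + s[2] * s[2]);
    if (tang_law == 0) {
      for (int kk = 0; kk < 3; ++kk) ft[kk] = -kt_lin * s[kk] - gt * vt[kk];
    } else {
      double kt0 = 8.0 * gs * std::sqrt(Rstar) * k1s;
      if (smag > 0) {
        double fmagel = kt0 * smag * std::sqrt(smag);
        for (int kk = 0; kk < 3; ++kk)
          ft[kk] = -fmagel * s[kk] / smag - gt * vt[kk];
      } else {
        for (int kk = 0; kk < 3; ++kk) ft[kk] = -gt * vt[kk];
      }
    }
    double ftmag = std::sqrt(ft[0] * ft[0] + ft[1] * ft[1] + ft[2] * ft[2]);
    double cap = mu[mp] * fn_cap;
    if (ftmag > cap) {
      double scale = cap > 0 ? cap / ftmag : 0.0;
      for (int kk = 0; kk < 3; ++kk) ft[kk] *= scale;
      // store the spring consistent with the capped force after removing the
      // damping contribution (folding damping into the spring pumps energy)
      if (tang_law == 0) {
        if (kt_lin > 0)
          for (int kk = 0; kk < 3; ++kk)
            s[kk] = -(ft[kk] + gt * vt[kk]) / kt_lin;
      } else {
        double kt0 = 8.0 * gs * std::sqrt(Rstar) * k1s;
        double fel[3];
        double felmag = 0;
        for (int kk = 0; kk < 3; ++kk) {
          fel[kk] = ft[kk] + gt * vt[kk];
          felmag += fel[kk] * fel[kk];
        }
        felmag = std::sqrt(felmag);
        if (felmag > 0 && kt0 > 0) {
          double smag_new = std::cbrt(felmag / kt0);
          smag_new = smag_new * smag_new;
          for (int kk = 0; kk < 3; ++kk) s[kk] = -smag_new * fel[kk] / felmag;
        } else {
          s[0] = s[1] = s[2] = 0;
        }
      }
    }
    h.sx = s[0]; h.sy = s[1]; h.sz = s[2];

    // ---- apply ----
    double fi[3];
    for (int kk = 0; kk < 3; ++kk) fi[kk] = fn * nrm[kk] + ft[kk];
    for (int kk = 0; kk < 3; ++kk) F[3 * i + kk] += fi[kk];
    double tq[3];
    cross(ri_c, fi, tq);
    for (int kk = 0; kk < 3; ++kk) T[3 * i + kk] += tq[kk];
    add_stress(i, ri_c, fi);

    // rolling friction (skipped for bonded pairs)
    double troll[3] = {0, 0, 0};
    if (!bonded && mur[mp] > 0 && fn_cap > 0) {
      double wrel[3] = {wi[0] - wj[0], wi[1] - wj[1], wi[2] - wj[2]};
      double wmag = std::sqrt(wrel[0] * wrel[0] + wrel[1] * wrel[1] +
                              wrel[2] * wrel[2]);
      if (wmag > 1e-12) {
        double c = -mur[mp] * Rstar * fn_cap / wmag;
        for (int kk = 0; kk < 3; ++kk) troll[kk] = c * wrel[kk];
        for (int kk = 0; kk < 3; ++kk) T[3 * i + kk] += troll[kk];
      }
    }

    if (is_wall) {
      for (int kk = 0; kk < 3; ++kk) wallF[3 * widx + kk] -= fi[kk];
    } else {
      double fj[3] = {-fi[0], -fi[1], -fi[2]};
      // rj_c is the branch vector from j's center to the contact point
      for (int kk = 0; kk < 3; ++kk) F[3 * j + kk] += fj[kk];
      double tqj[3];
      cross(rj_c, fj, tqj);
      for (int kk = 0; kk < 3; ++kk)
        T[3 * j + kk] += tqj[kk] - troll[kk];
      add_stress(j, rj_c, fj);
    }
  }

  void eval_forces(double dt_hist) {
    std::fill(F.begin(), F.end(), 0.0);
    std::fill(T.begin(), T.end(), 0.0);
    std::fill(sig.begin(), sig.end(), 0.0);
    std::fill(wallF.begin(), wallF.end(), 0.0);
    for (auto &kv : hist) kv.second.touched = false;

    for (int i = 0; i < N; ++i) {
      if (!is_cms[i]) {
        F[3 * i] += m[i] * grav[0];
        F[3 * i + 1] += m[i] * grav[1];
        F[3 * i + 2] += m[i] * grav[2];
      }
    }

    // sphere-sphere contacts
    for (auto &pr : pairs) {
      int i = pr.first, j = pr.second;
      if (body[i] >= 0 && body[i] == body[j] && kind[body[i]] == 2)
        continue;                                // intra-CMS: constitutive
      if (NB > 0 && bondkey.count(key(i, j))) continue;  // bond loop's job
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      minimg(d);
      double dist2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double rsum = r[i] + r[j];
      if (dist2 >= rsum * rsum) continue;
      double dist = std::sqrt(dist2);
      if (dist == 0) stop("coincident sphere centers (%d, %d)", i + 1, j + 1);
      double nrm[3] = {d[0] / dist, d[1] / dist, d[2] / dist};
      double delta = rsum - dist;
      double cp[3];
      for (int k = 0; k < 3; ++k)
        cp[k] = x[3 * i + k] - (r[i] - delta / 2) * nrm[k];
      resolve_contact(i, j, nrm, delta, cp, dt_hist, false, -1);
    }

    // sphere-wall contacts
    for (size_t widx = 0; widx < walls.size(); ++widx) {
      const WallDef &wd = walls[widx];
      for (int i = 0; i < N; ++i) {
        double dd = (x[3 * i] - wd.p[0]) * wd.n[0] +
                    (x[3 * i + 1] - wd.p[1]) * wd.n[1] +
                    (x[3 * i + 2] - wd.p[2]) * wd.n[2];
        double delta = r[i] - dd;
        if (delta <= 0) continue;
        double cp[3];
        for (int k = 0; k < 3; ++k) cp[k] = x[3 * i + k] - dd * wd.n[k];
        resolve_contact(i, -1, wd.n, delta, cp, dt_hist, false,
                        static_cast<int>(widx));
      }
    }

    // bonds: spring while separated, contact law while overlapping
    for (int b = 0; b < NB; ++b) {
      int i = bi[b], j = bj[b];
      double d[3] = {x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                     x[3 * i + 2] - x[3 * j + 2]};
      minimg(d);
      double dist = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (dist == 0) stop("coincident bonded spheres (%d, %d)", i + 1, j + 1);
      double nrm[3] = {d[0] / dist, d[1] / dist, d[2] / dist};
      // linear spring in tension AND compression: the bond alone carries the
      // bonded-pair interaction (no Hertz handoff), so a stiff-bonded body
      // stays elastic instead of shearing frictionally under load
      double kn = knb * bA[b], kt = ktb * bA[b];
      double u = dist - bL0[b];
      double mstar = m[i] * m[j] / (m[i] + m[j]);
      double mid[3], ri_c[3], rj_c[3];
      for (int k = 0; k < 3; ++k) {
        ri_c[k] = -0.5 * dist * nrm[k];  // from i's center to the midpoint
        rj_c[k] = 0.5 * dist * nrm[k];
        mid[k] = x[3 * i + k] + ri_c[k];
      }
      double wxri[3], wxrj[3];
      cross(&w[3 * i], ri_c, wxri);
      cross(&w[3 * j], rj_c, wxrj);
      double vrel[3];
      for (int k = 0; k < 3; ++k)
        vrel[k] = (v[3 * i + k] + wxri[k]) - (v[3 * j + k] + wxrj[k]);
      double vn = (v[3 * i] - v[3 * j]) * nrm[0] +
                  (v[3 * i + 1] - v[3 * j + 1]) * nrm[1] +
                  (v[3 * i + 2] - v[3 * j + 2]) * nrm[2];
      double vreln = vrel[0] * nrm[0] + vrel[1] * nrm[1] + vrel[2] * nrm[2];
      double vt[3] = {vrel[0] - vreln * nrm[0], vrel[1] - vreln * nrm[1],
                      vrel[2] - vreln * nrm[2]};
      double xi_[3] = {box_[b], boy_[b], boz_[b]};
      double xin = xi_[0] * nrm[0] + xi_[1] * nrm[1] + xi_[2] * nrm[2];
      for (int k = 0; k < 3; ++k)
        xi_[k] = xi_[k] - xin * nrm[k] + vt[k] * dt_hist;
      box_[b] = xi_[0]; boy_[b] = xi_[1]; boz_[b] = xi_[2];
      double cn = 2.0 * bond_zeta * std::sqrt(kn * mstar);
      double ct = 2.0 * bond_zeta * std::sqrt(kt * mstar);
      double fi[3];
      for (int k = 0; k < 3; ++k)
        fi[k] = -kn * u * nrm[k] - kt * xi_[k] - cn * vn * nrm[k] - ct * vt[k];
      for (int k = 0; k < 3; ++k) {
        F[3 * i + k] += fi[k];
        F[3 * j + k] -= fi[k];
      }
      double tqi[3], tqj[3];
      cross(ri_c, fi, tqi);
      double fj[3] = {-fi[0], -fi[1], -fi[2]};
      cross(rj_c, fj, tqj);
      for (int k = 0; k < 3; ++k) {
        T[3 * i + k] += tqi[k];
        T[3 * j + k] += tqj[k];
      }
      add_stress(i, ri_c, fi);
      add_stress(j, rj_c, fj);
    }

    // drop history of separated contacts
    for (auto it = hist.begin(); it != hist.end();) {
      if (!it->second.touched)
        it = hist.erase(it);
      else
        ++it;
    }

    // aggregate rigid bodies
    for (auto &rb : rigids) {
      for (int k = 0; k < 3; ++k) {
        rb.F[k] = rb.mass * grav[k];
        rb.T[k] = 0;
      }
      for (int mi : rb.members) {
        double rel[3] = {x[3 * mi] - rb.com[0], x[3 * mi + 1] - rb.com[1],
                         x[3 * mi + 2] - rb.com[2]};
        double tq[3];
        cross(rel, &F[3 * mi], tq);
        for (int k = 0; k < 3; ++k) {
          rb.F[k] += F[3 * mi + k];
          rb.T[k] += tq[k] + T[3 * mi + k];
        }
      }
    }
  }

  // Relaxed update of the mean-pressure field entering the non-local term.
  // A raw one-step lag turns the force->stress->force loop into an
  // undamped discrete map that can go unstable under deep confinement; the
  // exponential moving average (time constant ~1/alpha steps) damps it while
  // keeping the lag negligible on quasi-static timescales.
  void update_pressures(double alpha = 0.1) {
    for (int i = 0; i < N; ++i) {
      double pinst = (sig[6 * i] + sig[6 * i + 1] + sig[6 * i + 2]) / 3.0;
      P[i] = (1.0 - alpha) * P[i] + alpha * pinst;
    }
  }

  void rigid_sync_members(RigidBody &rb) {
    double R[9];
    quat_to_mat(rb.q, R);
    double wworld[3] = {
        R[0] * rb.wb[0] + R[1] * rb.wb[1] + R[2] * rb.wb[2],
        R[3] * rb.wb[0] + R[4] * rb.wb[1] + R[5] * rb.wb[2],
        R[6] * rb.wb[0] + R[7] * rb.wb[1] + R[8] * rb.wb[2]};
    for (size_t s = 0; s < rb.members.size(); ++s) {
      int i = rb.members[s];
      double off[3] = {rb.off[3 * s], rb.off[3 * s + 1], rb.off[3 * s + 2]};
      double rel[3] = {R[0] * off[0] + R[1] * off[1] + R[2] * off[2],
                       R[3] * off[0] + R[4] * off[1] + R[5] * off[2],
                       R[6] * off[0] + R[7] * off[1] + R[8] * off[2]};
      double wxr[3];
      cross(wworld, rel, wxr);
      for (int k = 0; k < 3; ++k) {
        x[3 * i + k] = rb.com[k] + rel[k];
        v[3 * i + k] = rb.vcom[k] + wxr[k];
        w[3 * i + k] = wworld[k];
      }
    }
  }

  void rigid_half_kick(RigidBody &rb, double dt) {
    for (int k = 0; k < 3; ++k) rb.vcom[k] += 0.5 * dt * rb.F[k] / rb.mass;
    if (rb.fix_lateral) rb.vcom[0] = rb.vcom[1] = 0;
    if (rb.fix_rotation) {
      rb.wb[0] = rb.wb[1] = rb.wb[2] = 0;
      return;
    }
    double R[9];
    quat_to_mat(rb.q, R);
    double tb[3] = {R[0] * rb.T[0] + R[3] * rb.T[1] + R[6] * rb.T[2],
                    R[1] * rb.T[0] + R[4] * rb.T[1] + R[7] * rb.T[2],
                    R[2] * rb.T[0] + R[5] * rb.T[1] + R[8] * rb.T[2]};
    double Iw[3] = {rb.I[0] * rb.wb[0], rb.I[1] * rb.wb[1], rb.I[2] * rb.wb[2]};
    double wxIw[3];
    cross(rb.wb, Iw, wxIw);
    for (int k = 0; k < 3; ++k)
      rb.wb[k] += 0.5 * dt * (tb[k] - wxIw[k]) / rb.I[k];
  }

  void rigid_drift(RigidBody &rb, double dt) {
    for (int k = 0; k < 3; ++k) rb.com[k] += dt * rb.vcom[k];
    double wmag = std::sqrt(rb.wb[0] * rb.wb[0] + rb.wb[1] * rb.wb[1] +
                            rb.wb[2] * rb.wb[2]);
    if (wmag > 0) {
      double half = 0.5 * wmag * dt;
      double sn = std::sin(half) / wmag;
      double dq[4] = {std::cos(half), sn * rb.wb[0], sn * rb.wb[1],
                      sn * rb.wb[2]};
      double qn[4];
      quat_mult(rb.q, dq, qn);
      for (int k = 0; k < 4; ++k) rb.q[k] = qn[k];
      quat_normalize(rb.q);
    }
    rigid_sync_members(rb);
  }

  double kinetic_energy() const {
    double e = 0;
    for (int i = 0; i < N; ++i) {
      if (is_cms[i]) continue;
      e += 0.5 * m[i] *
           (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
            v[3 * i + 2] * v[3 * i + 2]);
      e += 0.5 * inert[i] *
           (w[3 * i] * w[3 * i] + w[3 * i + 1] * w[3 * i + 1] +
            w[3 * i + 2] * w[3 * i + 2]);
    }
    for (const auto &rb : rigids) {
      e += 0.5 * rb.mass *
           (rb.vcom[0] * rb.vcom[0] + rb.vcom[1] * rb.vcom[1] +
            rb.vcom[2] * rb.vcom[2]);
      for (int k = 0; k < 3; ++k) e += 0.5 * rb.I[k] * rb.wb[k] * rb.wb[k];
    }
    return e;
  }

  void wrap_positions() {
    for (int i = 0; i < N; ++i) {
      if (is_cms[i]) continue;
      for (int k = 0; k < 3; ++k) {
        if (!periodic[k]) continue;
        double L = hi[k] - lo[k];
        double &c = x[3 * i + k];
        c = c - L * std::floor((c - lo[k]) / L);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_dem_run(List state, double dt, int n_steps, int record_every,
                 bool use_cells) {
  Engine E;
  NumericMatrix xm = state["x"], vm = state["v"], wm = state["w"];
  NumericVector rv = state["r"], mv = state["m"];
  IntegerVector matv = state["mat"], bodyv = state["body"];
  IntegerVector kindv = state["body_kind"];
  E.N = xm.nrow();
  E.x.resize(3 * E.N); E.v.resize(3 * E.N); E.w.resize(3 * E.N);
  E.r.resize(E.N); E.m.resize(E.N); E.inert.resize(E.N); E.vol.resize(E.N);
  E.mat.resize(E.N); E.body.resize(E.N);
  E.is_cms.assign(E.N, 0);
  for (int i = 0; i < E.N; ++i) {
    for (int k = 0; k < 3; ++k) {
      E.x[3 * i + k] = xm(i, k);
      E.v[3 * i + k] = vm(i, k);
      E.w[3 * i + k] = wm(i, k);
    }
    E.r[i] = rv[i];
    E.m[i] = mv[i];
    E.inert[i] = 0.4 * mv[i] * rv[i] * rv[i];
    E.vol[i] = 4.0 / 3.0 * M_PI * rv[i] * rv[i] * rv[i];
    E.mat[i] = matv[i] - 1;
    E.body[i] = bodyv[i] - 1;  // 0 in R means free -> -1
  }
  E.kind.resize(kindv.size());
  for (int b = 0; b < kindv.size(); ++b) E.kind[b] = kindv[b];

  // rigid bodies
  List cms = state["cms"];
  E.rigid_of_body.assign(std::max(1, (int)kindv.size()), -1);
  for (int c = 0; c < cms.size(); ++c) {
    List rb_in = cms[c];
    RigidBody rb;
    IntegerVector mem = rb_in["members"];
    NumericMatrix off = rb_in["offsets"];
    NumericVector iner = rb_in["inertia"], q = rb_in["quat"],
                  com = rb_in["com"], vcom = rb_in["vcom"],
                  omega = rb_in["omega_body"];
    rb.mass = as<double>(rb_in["mass"]);
    for (int s = 0; s < mem.size(); ++s) {
      rb.members.push_back(mem[s] - 1);
      E.is_cms[mem[s] - 1] = 1;
      for (int k = 0; k < 3; ++k) rb.off.push_back(off(s, k));
    }
    for (int k = 0; k < 3; ++k) {
      rb.I[k] = iner[k];
      rb.com[k] = com[k];
      rb.vcom[k] = vcom[k];
      rb.wb[k] = omega[k];
    }
    for (int k = 0; k < 4; ++k) rb.q[k] = q[k];
    if (rb_in.containsElementNamed("fix_rotation"))
      rb.fix_rotation = as<bool>(rb_in["fix_rotation"]);
    if (rb_in.containsElementNamed("fix_lateral"))
      rb.fix_lateral = as<bool>(rb_in["fix_lateral"]);
    int bid = as<int>(rb_in["body_id"]) - 1;
    E.rigid_of_body[bid] = E.rigids.size();
    E.rigids.push_back(rb);
  }
  for (auto &rb : E.rigids) E.rigid_sync_members(rb);

  // bonds
  List bonds = state["bonds"];
  IntegerVector bbi = bonds["i"], bbj = bonds["j"];
  NumericVector bl = bonds["rest_length"], ba = bonds["area"],
                bx = bonds["ox"], by = bonds["oy"], bz = bonds["oz"];
  E.NB = bbi.size();
  for (int b = 0; b < E.NB; ++b) {
    E.bi.push_back(bbi[b] - 1);
    E.bj.push_back(bbj[b] - 1);
    E.bL0.push_back(bl[b]);
    E.bA.push_back(ba[b]);
    E.box_.push_back(bx[b]);
    E.boy_.push_back(by[b]);
    E.boz_.push_back(bz[b]);
  }
  List bp = state["bond_params"];
  if (E.NB > 0) {
    E.knb = as<double>(bp["knb"]);
    E.ktb = as<double>(bp["ktb"]);
    E.bond_zeta = as<double>(bp["damping_ratio"]);
  }

  // walls
  List wl = state["walls"];
  for (int widx = 0; widx < wl.size(); ++widx) {
    List wd = wl[widx];
    WallDef W;
    NumericVector n = wd["normal"], p = wd["point"], vv = wd["velocity"];
    for (int k = 0; k < 3; ++k) {
      W.n[k] = n[k];
      W.p[k] = p[k];
      W.v[k] = vv[k];
    }
    W.mat = as<int>(wd["material"]) - 1;
    E.walls.push_back(W);
  }

  // domain
  List dom = state["domain"];
  NumericVector lo = dom["lo"], hi = dom["hi"];
  LogicalVector per = dom["periodic"];
  for (int k = 0; k < 3; ++k) {
    E.lo[k] = lo[k];
    E.hi[k] = hi[k];
    E.periodic[k] = per[k];
  }
  NumericVector gv = state["gravity"];
  for (int k = 0; k < 3; ++k) E.grav[k] = gv[k];

  // material pair tables
  List mats = state["materials"];
  E.M = mats.size();
  NumericMatrix pmu = state["pair_mu"], pmur = state["pair_mur"],
                pdamp = state["pair_damp"];
  E.Estar.resize(E.M * E.M);
  E.Gstar.resize(E.M * E.M);
  E.numean.resize(E.M * E.M);
  E.dampA.resize(E.M * E.M);
  E.mu.resize(E.M * E.M);
  E.mur.resize(E.M * E.M);
  std::vector<double> Ev(E.M), nuv(E.M);
  for (int a = 0; a < E.M; ++a) {
    List ma = mats[a];
    Ev[a] = as<double>(ma["young_modulus"]);
    nuv[a] = as<double>(ma["poisson_ratio"]);
  }
  for (int a = 0; a < E.M; ++a)
    for (int b = 0; b < E.M; ++b) {
      int idx = a * E.M + b;
      double invE = (1 - nuv[a] * nuv[a]) / Ev[a] +
                    (1 - nuv[b] * nuv[b]) / Ev[b];
      E.Estar[idx] = 1.0 / invE;
      double Ga = Ev[a] / (2 * (1 + nuv[a])), Gb = Ev[b] / (2 * (1 + nuv[b]));
      double invG = (2 - nuv[a]) / Ga + (2 - nuv[b]) / Gb;
      E.Gstar[idx] = 1.0 / invG;
      E.numean[idx] = 0.5 * (nuv[a] + nuv[b]);
      E.dampA[idx] = pdamp(a, b);
      E.mu[idx] = pmu(a, b);
      E.mur[idx] = pmur(a, b);
    }

  // model
  List model = state["model"];
  std::string nm = as<std::string>(model["normal"]);
  E.normal_model = (nm == "elastoplastic") ? 1 : 0;
  std::string tl = as<std::string>(model["tangential_law"]);
  E.tang_law = (tl == "as_printed") ? 1 : 0;
  if (E.normal_model == 1) {
    List ep = model["ep"];
    E.ep_f0 = as<double>(ep["f0"]);
    E.ep_k1s = as<double>(ep["k1_scale"]);
    E.ep_k2r = as<double>(ep["k2_ratio"]);
    E.ep_kcr = as<double>(ep["kc_ratio"]);
    E.ep_beta = as<double>(ep["beta"]);
    if (E.ep_k2r < 1) stop("k2_ratio must be >= 1");
  }

  // history
  E.stride = E.N + (int64_t)E.walls.size() + 1;
  for (int b = 0; b < E.NB; ++b)
    E.bondkey.insert(E.key(std::min(E.bi[b], E.bj[b]),
                           std::max(E.bi[b], E.bj[b])));
  List hin = state["history"];
  IntegerVector hi_ = hin["i"], hj_ = hin["j"];
  NumericVector hsx = hin["sx"], hsy = hin["sy"], hsz = hin["sz"],
                hd0 = hin["d0"];
  for (int h = 0; h < hi_.size(); ++h) {
    Hist hh;
    hh.sx = hsx[h];
    hh.sy = hsy[h];
    hh.sz = hsz[h];
    hh.d0 = hd0[h];
    E.hist[E.key(hi_[h] - 1, hj_[h] - 1)] = hh;
  }
  NumericVector pin = state["pressures"];
  E.P.assign(E.N, 0.0);
  for (int i = 0; i < E.N && i < pin.size(); ++i) E.P[i] = pin[i];
  E.time = as<double>(state["time"]);

  E.F.resize(3 * E.N); E.T.resize(3 * E.N);
  E.sig.resize(6 * E.N);
  E.wallF.assign(3 * E.walls.size(), 0.0);
  E.use_cells = use_cells;
  E.rmin = 1e300;
  E.rmax = 0;
  for (int i = 0; i < E.N; ++i) {
    E.rmin = std::min(E.rmin, E.r[i]);
    E.rmax = std::max(E.rmax, E.r[i]);
  }
  E.skin = 0.2 * E.rmin;
  for (int k = 0; k < 3; ++k) {
    if (E.periodic[k] && 2 * E.rmax > 0.5 * (E.hi[k] - E.lo[k]))
      stop("sphere diameter exceeds half the periodic box length on axis %d",
           k + 1);
  }

  // recording buffers
  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericVector rec_t(n_rec), rec_ke(n_rec);
  NumericMatrix rec_wf(n_rec, 3 * std::max<size_t>(1, E.walls.size()));
  NumericMatrix rec_wp(n_rec, 3 * std::max<size_t>(1, E.walls.size()));

  E.build_pairs();
  E.eval_forces(0.0);   // forces at entry; no history advance
  E.update_pressures();

  int irec = 0;
  for (int s = 0; s < n_steps; ++s) {
    // half kick
    for (int i = 0; i < E.N; ++i) {
      if (E.is_cms[i]) continue;
      for (int k = 0; k < 3; ++k) {
        E.v[3 * i + k] += 0.5 * dt * E.F[3 * i + k] / E.m[i];
        E.w[3 * i + k] += 0.5 * dt * E.T[3 * i + k] / E.inert[i];
      }
    }
    for (auto &rb : E.rigids) E.rigid_half_kick(rb, dt);
    // drift
    for (int i = 0; i < E.N; ++i) {
      if (E.is_cms[i]) continue;
      for (int k = 0; k < 3; ++k) E.x[3 * i + k] += dt * E.v[3 * i + k];
    }
    for (auto &rb : E.rigids) E.rigid_drift(rb, dt);
    E.wrap_positions();
    for (auto &wd : E.walls)
      for (int k = 0; k < 3; ++k) wd.p[k] += dt * wd.v[k];

    if (E.need_rebuild()) E.build_pairs();
    E.eval_forces(dt);
    E.update_pressures();

    // second half kick
    for (int i = 0; i < E.N; ++i) {
      if (E.is_cms[i]) continue;
      for (int k = 0; k < 3; ++k) {
        E.v[3 * i + k] += 0.5 * dt * E.F[3 * i + k] / E.m[i];
        E.w[3 * i + k] += 0.5 * dt * E.T[3 * i + k] / E.inert[i];
      }
    }
    for (auto &rb : E.rigids) E.rigid_half_kick(rb, dt);
    E.time += dt;

    if (record_every > 0 && (s + 1) % record_every == 0 && irec < n_rec) {
      rec_t[irec] = E.time;
      rec_ke[irec] = E.kinetic_energy();
      for (size_t widx = 0; widx < E.walls.size(); ++widx)
        for (int k = 0; k < 3; ++k) {
          rec_wf(irec, 3 * widx + k) = E.wallF[3 * widx + k];
          rec_wp(irec, 3 * widx + k) = E.walls[widx].p[k];
        }
      ++irec;
      if (!std::isfinite(rec_ke[irec - 1]))
        stop("non-finite kinetic energy at step %d", s + 1);
    }
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // ---- write back ----
  NumericMatrix xo(E.N, 3), vo(E.N, 3), wo(E.N, 3);
  for (int i = 0; i < E.N; ++i)
    for (int k = 0; k < 3; ++k) {
      xo(i, k) = E.x[3 * i + k];
      vo(i, k) = E.v[3 * i + k];
      wo(i, k) = E.w[3 * i + k];
    }
  NumericVector bxo(E.NB), byo(E.NB), bzo(E.NB);
  for (int b = 0; b < E.NB; ++b) {
    bxo[b] = E.box_[b];
    byo[b] = E.boy_[b];
    bzo[b] = E.boz_[b];
  }
  int nh = E.hist.size();
  IntegerVector hio(nh), hjo(nh);
  NumericVector sxo(nh), syo(nh), szo(nh), d0o(nh);
  int hc = 0;
  for (auto &kv : E.hist) {
    hio[hc] = static_cast<int>(kv.first / E.stride) + 1;
    hjo[hc] = static_cast<int>(kv.first % E.stride) + 1;
    sxo[hc] = kv.second.sx;
    syo[hc] = kv.second.sy;
    szo[hc] = kv.second.sz;
    d0o[hc] = kv.second.d0;
    ++hc;
  }
  List cms_out(E.rigids.size());
  {
    List cms_in = state["cms"];
    for (size_t c = 0; c < E.rigids.size(); ++c) {
      List rb_in = cms_in[c];
      RigidBody &rb = E.rigids[c];
      rb_in["quat"] = NumericVector::create(rb.q[0], rb.q[1], rb.q[2], rb.q[3]);
      rb_in["com"] = NumericVector::create(rb.com[0], rb.com[1], rb.com[2]);
      rb_in["vcom"] =
          NumericVector::create(rb.vcom[0], rb.vcom[1], rb.vcom[2]);
      rb_in["omega_body"] =
          NumericVector::create(rb.wb[0], rb.wb[1], rb.wb[2]);
      cms_out[c] = rb_in;
    }
  }
  List walls_out(E.walls.size());
  {
    List wl_in = state["walls"];
    for (size_t widx = 0; widx < E.walls.size(); ++widx) {
      List wd = wl_in[widx];
      wd["point"] = NumericVector::create(
          E.walls[widx].p[0], E.walls[widx].p[1], E.walls[widx].p[2]);
      walls_out[widx] = wd;
    }
  }
  NumericVector pres(E.N);
  NumericMatrix sigout(E.N, 6);
  for (int i = 0; i < E.N; ++i) {
    pres[i] = E.P[i];
    for (int k = 0; k < 6; ++k) sigout(i, k) = E.sig[6 * i + k];
  }
  NumericMatrix fout(E.N, 3);
  for (int i = 0; i < E.N; ++i)
    for (int k = 0; k < 3; ++k) fout(i, k) = E.F[3 * i + k];

  return List::create(
      _["x"] = xo, _["v"] = vo, _["w"] = wo,
      _["bond_offsets"] = List::create(_["ox"] = bxo, _["oy"] = byo,
                                       _["oz"] = bzo),
      _["history"] = List::create(_["i"] = hio, _["j"] = hjo, _["sx"] = sxo,
                                  _["sy"] = syo, _["sz"] = szo,
                                  _["d0"] = d0o),
      _["cms"] = cms_out, _["walls"] = walls_out, _["pressures"] = pres,
      _["stress"] = sigout, _["forces"] = fout,
      _["wall_forces"] = NumericVector(E.wallF.begin(), E.wallF.end()),
      _["time"] = E.time,
      _["rec_time"] = rec_t, _["rec_ke"] = rec_ke, _["rec_wall_force"] = rec_wf,
      _["rec_wall_point"] = rec_wp);
}

// Candidate neighbor pairs for a static configuration (exported so the R
// layer can offer the same search the engine uses, for oracle comparison).
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix xm, NumericVector rv,
                                 NumericVector lo, NumericVector hi,
                                 LogicalVector per, double skin,
                                 bool use_cells) {
  Engine E;
  E.N = xm.nrow();
  E.x.resize(3 * E.N);
  E.r.resize(E.N);
  for (int i = 0; i < E.N; ++i) {
    for (int k = 0; k < 3; ++k) E.x[3 * i + k] = xm(i, k);
    E.r[i] = rv[i];
  }
  E.rmin = 1e300;
  E.rmax = 0;
  for (int i = 0; i < E.N; ++i) {
    E.rmin = std::min(E.rmin, E.r[i]);
    E.rmax = std::max(E.rmax, E.r[i]);
  }
  for (int k = 0; k < 3; ++k) {
    E.lo[k] = lo[k];
    E.hi[k] = hi[k];
    E.periodic[k] = per[k];
    if (E.periodic[k] && 2 * E.rmax > 0.5 * (E.hi[k] - E.lo[k]))
      stop("sphere diameter exceeds half the periodic box length on axis %d",
           k + 1);
  }
  E.skin = skin;
  E.use_cells = use_cells;
  E.build_pairs();
  IntegerMatrix out(E.pairs.size(), 2);
  for (size_t p = 0; p < E.pairs.size(); ++p) {
    out(p, 0) = E.pairs[p].first + 1;
    out(p, 1) = E.pairs[p].second + 1;
  }
  return out;
}
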