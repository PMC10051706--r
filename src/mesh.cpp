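#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ray casting point-in-polyhedron test. The ray direction is a fixed
// irrational-ish vector so axis-aligned meshes do not produce edge hits.
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix pts, NumericMatrix V,
                                 IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  const double dx = 0.57735026918962584,
               dy = 0.62007874015748032,
               dz = 0.53103448275862066;
  LogicalVector out(np);
  std::vector<double> ax(nf), ay(nf), az(nf),
      e1x(nf), e1y(nf), e1z(nf), e2x(nf), e2y(nf), e2z(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    ax[f] = V(i0, 0); ay[f] = V(i0, 1); az[f] = V(i0, 2);
    e1x[f] = V(i1, 0) - ax[f]; e1y[f] = V(i1, 1) - ay[f];
    e1z[f] = V(i1, 2) - az[f];
    e2x[f] = V(i2, 0) - ax[f]; e2y[f] = V(i2, 1) - ay[f];
    e2z[f] = V(i2, 2) - az[f];
  }
  for (int p = 0; p < np; ++p) {
    const double ox = pts(p, 0), oy = pts(p, 1), oz = pts(p, 2);
    int crossings = 0;
    for (int f = 0; f < nf; ++f) {
      // Moeller-Trumbore
      double hx = dy * e2z[f] - dz * e2y[f];
      double hy = dz * e2x[f] - dx * e2z[f];
      double hz = dx * e2y[f] - dy * e2x[f];
      double det = e1x[f] * hx + e1y[f] * hy + e1z[f] * hz;
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      double sx = ox - ax[f], sy = oy - ay[f], sz = oz - az[f];
      double u = (sx * hx + sy * hy + sz * hz) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double qx = sy * e1z[f] - sz * e1y[f];
      double qy = sz * e1x[f] - sx * e1z[f];
      double qz = sx * e1y[f] - sy * e1x[f];
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double t = (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz) * inv;
      if (t > 0.0) ++crossings;
    }
    out[p] = (crossings % 2) == 1;
  }
  return out;
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// squared distance from point p to triangle (a, b, c); Eberly-style closest
// point with barycentric clamping
static double pt_tri_d2(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3], cp[3];
    for (int k = 0; k < 3; ++k) {
      bp[k] = p[k] - b[k];
      cp[k] = p[k] - c[k];
    }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else if (d6 >= 0.0 && d5 <= d6) {
      q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double t = clamp01(d1 / (d1 - d3));
        for (int k = 0; k < 3; ++k) q[k] = a[k] + t * ab[k];
      } else {
        double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          double t = clamp01(d2 / (d2 - d6));
          for (int k = 0; k < 3; ++k) q[k] = a[k] + t * ac[k];
        } else {
          double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            double t = clamp01((d4 - d3) / ((d4 - d3) + (d5 - d6)));
            for (int k = 0; k < 3; ++k)
              q[k] = b[k] + t * (c[k] - b[k]);
          } else {
            double denom = 1.0 / (va + vb + vc);
            double vv = vb * denom, ww = vc * denom;
            for (int k = 0; k < 3; ++k)
              q[k] = a[k] + ab[k] * vv + ac[k] * ww;
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix pts, NumericMatrix V,
                                      IntegerMatrix F) {
  const int np = pts.nrow(), nf = F.nrow();
  std::vector<double> tri(nf * 9);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) {
      int vi = F(f, c) - 1;
      tri[f * 9 + c * 3 + 0] = V(vi, 0);
      tri[f * 9 + c * 3 + 1] = V(vi, 1);
      tri[f * 9 + c * 3 + 2] = V(vi, 2);
    }
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double pp[3] = {pts(p, 0), pts(p, 1), pts(p, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double d2 = pt_tri_d2(pp, &tri[f * 9], &tri[f * 9 + 3], &tri[f * 9 + 6]);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
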