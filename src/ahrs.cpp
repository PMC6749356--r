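// Gradient-descent complementary AHRS fusion (Madgwick-style, 9-axis).
//
// State: unit quaternion q = (w, x, y, z) rotating the sensor frame into the
// earth frame. Prediction integrates the gyroscope via qdot = 0.5 * q ox
// (0, omega); the correction step descends the measurement objective
//   f(q) = [ R(q)^T e3 - acc_hat ; R(q)^T b(q) - mag_hat ]
// where e3 is earth "up" and b(q) = (bx, 0, bz) is the earth-frame magnetic
// reference recomputed from the current estimate (declination absorbed into
// yaw). The Jacobian is evaluated by central differences; at the fusion-gain
// scale this is numerically indistinguishable from the expanded algebra.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline void quat_mult(const double* a, const double* b, double* out) {
  out[0] = a[0]*b[0] - a[1]*b[1] - a[2]*b[2] - a[3]*b[3];
  out[1] = a[0]*b[1] + a[1]*b[0] + a[2]*b[3] - a[3]*b[2];
  out[2] = a[0]*b[2] - a[1]*b[3] + a[2]*b[0] + a[3]*b[1];
  out[3] = a[0]*b[3] + a[1]*b[2] - a[2]*b[1] + a[3]*b[0];
}

// rotate earth-frame vector v into the sensor frame: R(q)^T v
static inline void rot_inv(const double* q, const double* v, double* out) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  out[0] = (1 - 2*(y*y + z*z))*v[0] + 2*(x*y + w*z)*v[1] + 2*(x*z - w*y)*v[2];
  out[1] = 2*(x*y - w*z)*v[0] + (1 - 2*(x*x + z*z))*v[1] + 2*(y*z + w*x)*v[2];
  out[2] = 2*(x*z + w*y)*v[0] + 2*(y*z - w*x)*v[1] + (1 - 2*(x*x + y*y))*v[2];
}

// rotate sensor-frame vector into the earth frame: R(q) v
static inline void rot_fwd(const double* q, const double* v, double* out) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  out[0] = (1 - 2*(y*y + z*z))*v[0] + 2*(x*y - w*z)*v[1] + 2*(x*z + w*y)*v[2];
  out[1] = 2*(x*y + w*z)*v[0] + (1 - 2*(x*x + z*z))*v[1] + 2*(y*z - w*x)*v[2];
  out[2] = 2*(x*z - w*y)*v[0] + 2*(y*z + w*x)*v[1] + (1 - 2*(x*x + y*y))*v[2];
}

static inline double norm3(const double* v) {
  return std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
}

// measurement objective; use_mag selects 6- vs 3-component form
static void objective(const double* q, const double* ah, const double* mh,
                      const double* bref, bool use_mag, double* f) {
  const double e3[3] = {0.0, 0.0, 1.0};
  double g[3];
  rot_inv(q, e3, g);
  f[0] = g[0] - ah[0]; f[1] = g[1] - ah[1]; f[2] = g[2] - ah[2];
  if (use_mag) {
    double m[3];
    rot_inv(q, bref, m);
    f[3] = m[0] - mh[0]; f[4] = m[1] - mh[1]; f[5] = m[2] - mh[2];
  }
}

// [[Rcpp::export]]
List ahrs_fuse(NumericMatrix acc, NumericMatrix gyro, NumericMatrix mag,
               double beta, double dt, NumericVector q0) {
  const int n = acc.nrow();
  NumericMatrix quat(n, 4), euler(n, 3);
  std::vector<int> skipped;
  double q[4] = {q0[0], q0[1], q0[2], q0[3]};
  {
    double nq = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
    for (int k = 0; k < 4; ++k) q[k] /= nq;
  }
  const double h = 1e-6;

  for (int t = 0; t < n; ++t) {
    const double om[4] = {0.0, gyro(t, 0), gyro(t, 1), gyro(t, 2)};
    double qdot[4];
    quat_mult(q, om, qdot);
    for (int k = 0; k < 4; ++k) qdot[k] *= 0.5;

    const double a[3] = {acc(t, 0), acc(t, 1), acc(t, 2)};
    const double m[3] = {mag(t, 0), mag(t, 1), mag(t, 2)};
    const double na = norm3(a), nm = norm3(m);

    if (na > 0.0) {
      const double ah[3] = {a[0]/na, a[1]/na, a[2]/na};
      bool use_mag = nm > 0.0;
      double mh[3] = {0, 0, 0}, bref[3] = {0, 0, 0};
      if (use_mag) {
        mh[0] = m[0]/nm; mh[1] = m[1]/nm; mh[2] = m[2]/nm;
        double he[3];
        rot_fwd(q, mh, he);
        bref[0] = std::sqrt(he[0]*he[0] + he[1]*he[1]);
        bref[1] = 0.0;
        bref[2] = he[2];
      }
      const int nf = use_mag ? 6 : 3;
      double f0[6], fp[6], fm[6], grad[4] = {0, 0, 0, 0};
      objective(q, ah, mh, bref, use_mag, f0);
      for (int k = 0; k < 4; ++k) {
        double qp[4] = {q[0], q[1], q[2], q[3]};
        double qm[4] = {q[0], q[1], q[2], q[3]};
        qp[k] += h; qm[k] -= h;
        objective(qp, ah, mh, bref, use_mag, fp);
        objective(qm, ah, mh, bref, use_mag, fm);
        double s = 0.0;
        for (int r = 0; r < nf; ++r) s += (fp[r] - fm[r]) / (2*h) * f0[r];
        grad[k] = s;
      }
      double ng = std::sqrt(grad[0]*grad[0] + grad[1]*grad[1] +
                            grad[2]*grad[2] + grad[3]*grad[3]);
      if (ng > 0.0)
        for (int k = 0; k < 4; ++k) qdot[k] -= beta * grad[k] / ng;
    } else {
      skipped.push_back(t + 1);
    }

    for (int k = 0; k < 4; ++k) q[k] += qdot[k] * dt;
    double nq = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
    for (int k = 0; k < 4; ++k) q[k] /= nq;

    quat(t, 0) = q[0]; quat(t, 1) = q[1]; quat(t, 2) = q[2]; quat(t, 3) = q[3];
    const double w = q[0], x = q[1], y = q[2], z = q[3];
    euler(t, 0) = std::atan2(2*(w*x + y*z), 1 - 2*(x*x + y*y));   // roll
    double sp = 2*(w*y - z*x);
    if (sp > 1.0) sp = 1.0;
    if (sp < -1.0) sp = -1.0;
    euler(t, 1) = std::asin(sp);                                   // pitch
    euler(t, 2) = std::atan2(2*(w*z + x*y), 1 - 2*(y*y + z*z));   // yaw
  }

  return List::create(_["quaternion"] = quat, _["euler"] = euler,
                      _["skipped"] = IntegerVector(skipped.begin(), skipped.end()));
}
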