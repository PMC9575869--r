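#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with step set {(1,0),(0,1),(1,1)} and squared local
// distances accumulated along the path; the reported cost is the square root
// of the optimal accumulated sum. Backtracking prefers the diagonal
// predecessor on ties, which guarantees a corner-free (minimum-length)
// optimal path of exactly max(m, n) cells.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector p, NumericVector r) {
  const int m = p.size(), n = r.size();
  if (m < 1 || n < 1) stop("dtw: empty series");
  std::vector<double> D((size_t)m * n);
  const double INF = R_PosInf;
  const double *pp = p.begin(), *rr = r.begin();
  for (int i = 0; i < m; ++i) {
    double *row = &D[(size_t)i * n];
    const double *up = i > 0 ? &D[(size_t)(i - 1) * n] : NULL;
    const double pi_ = pp[i];
    for (int j = 0; j < n; ++j) {
      double d = pi_ - rr[j];
      d = d * d;
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else {
        best = INF;
        if (i > 0 && j > 0) best = std::min(best, up[j - 1]);
        if (i > 0) best = std::min(best, up[j]);
        if (j > 0) best = std::min(best, row[j - 1]);
      }
      row[j] = d + best;
    }
  }
  #define DCELL(i, j) D[(size_t)(i) * n + (j)]
  // backtrack, diagonal first on ties
  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double dd = DCELL(i - 1, j - 1), du = DCELL(i - 1, j),
             dl = DCELL(i, j - 1);
      if (dd <= du && dd <= dl) { --i; --j; }
      else if (du <= dl) { --i; }
      else { --j; }
    } else if (i > 0) { --i; }
    else { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  const int k = pi.size();
  IntegerMatrix path(k, 2);
  for (int t = 0; t < k; ++t) {
    path(t, 0) = pi[k - 1 - t];
    path(t, 1) = pj[k - 1 - t];
  }
  return List::create(_["cost"] = std::sqrt(DCELL(m - 1, n - 1)),
                      _["path"] = path, _["k"] = k);
  #undef DCELL
}

static inline void quat_rotmat(const double q[4], double R[3][3]) {
  // body-to-earth rotation matrix, scalar-first quaternion (w, x, y, z)
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0][0] = 1 - 2 * (y * y + z * z); R[0][1] = 2 * (x * y - w * z); R[0][2] = 2 * (x * z + w * y);
  R[1][0] = 2 * (x * y + w * z); R[1][1] = 1 - 2 * (x * x + z * z); R[1][2] = 2 * (y * z - w * x);
  R[2][0] = 2 * (x * z - w * y); R[2][1] = 2 * (y * z + w * x); R[2][2] = 1 - 2 * (x * x + y * y);
}

// residuals of the orientation objective: predicted body-frame gravity and
// (optionally) earth-field directions minus the normalized measurements
static void orient_residual(const double q[4], const double ahat[3],
                            const double mhat[3], bool use_mag,
                            double f[6]) {
  double R[3][3];
  quat_rotmat(q, R);
  // R^T e_z: third row of R
  f[0] = R[2][0] - ahat[0];
  f[1] = R[2][1] - ahat[1];
  f[2] = R[2][2] - ahat[2];
  if (use_mag) {
    // rotate measurement to earth frame, collapse to (bx, 0, bz) reference
    double hx = R[0][0] * mhat[0] + R[0][1] * mhat[1] + R[0][2] * mhat[2];
    double hy = R[1][0] * mhat[0] + R[1][1] * mhat[1] + R[1][2] * mhat[2];
    double hz = R[2][0] * mhat[0] + R[2][1] * mhat[1] + R[2][2] * mhat[2];
    double bx = std::sqrt(hx * hx + hy * hy), bz = hz;
    double bn = std::sqrt(bx * bx + bz * bz);
    if (bn < 1e-12) { f[3] = f[4] = f[5] = 0.0; return; }
    bx /= bn; bz /= bn;
    // predicted body-frame field: R^T (bx, 0, bz)
    f[3] = R[0][0] * bx + R[2][0] * bz - mhat[0];
    f[4] = R[0][1] * bx + R[2][1] * bz - mhat[1];
    f[5] = R[0][2] * bx + R[2][2] * bz - mhat[2];
  } else {
    f[3] = f[4] = f[5] = 0.0;
  }
}

// Gradient-descent complementary orientation filter: integrate the gyroscope
// quaternion kinematics and apply one normalized gradient step of gain beta
// on the accelerometer/magnetometer field-direction objective per sample.
// [[Rcpp::export(name = ".madgwick_core")]]
List madgwick_core(NumericMatrix acc, NumericMatrix gyro,
                   Nullable<NumericMatrix> mag_, NumericVector dt,
                   double beta, NumericVector q0) {
  const int n = acc.nrow();
  if (gyro.nrow() != n) stop("acc and gyro must be time-aligned");
  bool have_mag = mag_.isNotNull();
  NumericMatrix mag;
  if (have_mag) { mag = mag_.get(); if (mag.nrow() != n) stop("mag misaligned"); }
  if (beta < 0) stop("beta must be non-negative");
  NumericMatrix Q(n, 4);
  IntegerVector skipped;
  double q[4] = {q0[0], q0[1], q0[2], q0[3]};
  double qn = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  for (int c = 0; c < 4; ++c) q[c] /= qn;
  for (int t = 0; t < n; ++t) {
    const double gx = gyro(t, 0), gy = gyro(t, 1), gz = gyro(t, 2);
    // quaternion derivative from angular rate
    double qdot[4] = {
      0.5 * (-q[1] * gx - q[2] * gy - q[3] * gz),
      0.5 * ( q[0] * gx + q[2] * gz - q[3] * gy),
      0.5 * ( q[0] * gy - q[1] * gz + q[3] * gx),
      0.5 * ( q[0] * gz + q[1] * gy - q[2] * gx)};
    double anorm = std::sqrt(acc(t, 0) * acc(t, 0) + acc(t, 1) * acc(t, 1) +
                             acc(t, 2) * acc(t, 2));
    if (anorm > 1e-12 && beta > 0) {
      double ahat[3] = {acc(t, 0) / anorm, acc(t, 1) / anorm, acc(t, 2) / anorm};
      double mhat[3] = {0, 0, 0};
      bool use_mag = false;
      if (have_mag) {
        double mn = std::sqrt(mag(t, 0) * mag(t, 0) + mag(t, 1) * mag(t, 1) +
                              mag(t, 2) * mag(t, 2));
        if (mn > 1e-12) {
          use_mag = true;
          for (int c = 0; c < 3; ++c) mhat[c] = mag(t, c) / mn;
        }
      }
      // numeric J^T f of the field-direction objective
      double f0[6];
      orient_residual(q, ahat, mhat, use_mag, f0);
      double grad[4] = {0, 0, 0, 0};
      const double eps = 1e-6;
      for (int c = 0; c < 4; ++c) {
        double qp[4] = {q[0], q[1], q[2], q[3]};
        double qm[4] = {q[0], q[1], q[2], q[3]};
        qp[c] += eps; qm[c] -= eps;
        double fp[6], fm[6];
        orient_residual(qp, ahat, mhat, use_mag, fp);
        orient_residual(qm, ahat, mhat, use_mag, fm);
        double g = 0;
        for (int r2 = 0; r2 < 6; ++r2)
          g += f0[r2] * (fp[r2] - fm[r2]) / (2 * eps);
        grad[c] = g;
      }
      double gn = std::sqrt(grad[0]*grad[0] + grad[1]*grad[1] +
                            grad[2]*grad[2] + grad[3]*grad[3]);
      if (gn > 1e-12)
        for (int c = 0; c < 4; ++c) qdot[c] -= beta * grad[c] / gn;
    } else if (anorm <= 1e-12) {
      skipped.push_back(t + 1);
    }
    for (int c = 0; c < 4; ++c) q[c] += qdot[c] * dt[t];
    qn = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
    for (int c = 0; c < 4; ++c) q[c] /= qn;
    for (int c = 0; c < 4; ++c) Q(t, c) = q[c];
  }
  return List::create(_["quaternions"] = Q, _["skipped"] = skipped);
}
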