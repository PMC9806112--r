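#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Orientation filters for strapdown IMU data.
//
// Quaternions are Hamilton, scalar-first (w, x, y, z) and encode the
// body-to-earth rotation R(q), earth frame z-up.  The accelerometer is
// assumed to read specific force in g, so a static sensor measures
// R(q)^T (0, 0, 1).  Gyroscope input must be in rad/s.
//
// The update equations follow the published gradient-descent (Madgwick)
// and explicit complementary (Mahony) formulations.  Samples with
// non-finite accelerometer (or magnetometer, in 9-DOF mode) values fall
// back to pure gyro integration for that step.

static inline bool finite3(double a, double b, double c) {
  return R_finite(a) && R_finite(b) && R_finite(c);
}

// [[Rcpp::export]]
NumericMatrix fusion_filter_cpp(NumericMatrix acc, NumericMatrix gyr,
                                Nullable<NumericMatrix> mag_,
                                double rate, std::string algorithm,
                                double beta, double kp, double ki,
                                NumericVector qinit) {
  const int n = acc.nrow();
  const double dt = 1.0 / rate;
  const bool use_mag = mag_.isNotNull();
  NumericMatrix mag;
  if (use_mag) mag = NumericMatrix(mag_);
  const bool madgwick = (algorithm == "madgwick");

  NumericMatrix out(n, 4);
  double q0 = qinit[0], q1 = qinit[1], q2 = qinit[2], q3 = qinit[3];
  // Mahony integral feedback terms
  double ix = 0.0, iy = 0.0, iz = 0.0;

  for (int t = 0; t < n; ++t) {
    double gx = gyr(t, 0), gy = gyr(t, 1), gz = gyr(t, 2);
    if (!finite3(gx, gy, gz)) { gx = gy = gz = 0.0; }
    double ax = acc(t, 0), ay = acc(t, 1), az = acc(t, 2);
    bool acc_ok = finite3(ax, ay, az) && (ax != 0.0 || ay != 0.0 || az != 0.0);
    double mx = 0.0, my = 0.0, mz = 0.0;
    bool mag_ok = false;
    if (use_mag) {
      mx = mag(t, 0); my = mag(t, 1); mz = mag(t, 2);
      mag_ok = finite3(mx, my, mz) && (mx != 0.0 || my != 0.0 || mz != 0.0);
    }

    if (madgwick) {
      double qDot0 = 0.5 * (-q1 * gx - q2 * gy - q3 * gz);
      double qDot1 = 0.5 * (q0 * gx + q2 * gz - q3 * gy);
      double qDot2 = 0.5 * (q0 * gy - q1 * gz + q3 * gx);
      double qDot3 = 0.5 * (q0 * gz + q1 * gy - q2 * gx);

      if (acc_ok) {
        double norm = std::sqrt(ax * ax + ay * ay + az * az);
        ax /= norm; ay /= norm; az /= norm;
        double s0, s1, s2, s3;
        if (mag_ok) {
          double norm_m = std::sqrt(mx * mx + my * my + mz * mz);
          mx /= norm_m; my /= norm_m; mz /= norm_m;
          double _2q0mx = 2.0 * q0 * mx, _2q0my = 2.0 * q0 * my;
          double _2q0mz = 2.0 * q0 * mz, _2q1mx = 2.0 * q1 * mx;
          double _2q0 = 2.0 * q0, _2q1 = 2.0 * q1, _2q2 = 2.0 * q2,
                 _2q3 = 2.0 * q3;
          double _2q0q2 = 2.0 * q0 * q2, _2q2q3 = 2.0 * q2 * q3;
          double q0q0 = q0 * q0, q0q1 = q0 * q1, q0q2 = q0 * q2,
                 q0q3 = q0 * q3, q1q1 = q1 * q1, q1q2 = q1 * q2,
                 q1q3 = q1 * q3, q2q2 = q2 * q2, q2q3 = q2 * q3,
                 q3q3 = q3 * q3;

          // reference direction of earth's magnetic field
          double hx = mx * q0q0 - _2q0my * q3 + _2q0mz * q2 + mx * q1q1 +
                      _2q1 * my * q2 + _2q1 * mz * q3 - mx * q2q2 - mx * q3q3;
          double hy = _2q0mx * q3 + my * q0q0 - _2q0mz * q1 + _2q1mx * q2 -
                      my * q1q1 + my * q2q2 + _2q2 * mz * q3 - my * q3q3;
          double _2bx = std::sqrt(hx * hx + hy * hy);
          double _2bz = -_2q0mx * q2 + _2q0my * q1 + mz * q0q0 + _2q1mx * q3 -
                        mz * q1q1 + _2q2 * my * q3 - mz * q2q2 + mz * q3q3;
          double _4bx = 2.0 * _2bx, _4bz = 2.0 * _2bz;

          s0 = -_2q2 * (2.0 * q1q3 - _2q0q2 - ax) +
               _2q1 * (2.0 * q0q1 + _2q2q3 - ay) -
               _2bz * q2 * (_2bx * (0.5 - q2q2 - q3q3) +
                            _2bz * (q1q3 - q0q2) - mx) +
               (-_2bx * q3 + _2bz * q1) *
                   (_2bx * (q1q2 - q0q3) + _2bz * (q0q1 + q2q3) - my) +
               _2bx * q2 * (_2bx * (q0q2 + q1q3) +
                            _2bz * (0.5 - q1q1 - q2q2) - mz);
          s1 = _2q3 * (2.0 * q1q3 - _2q0q2 - ax) +
               _2q0 * (2.0 * q0q1 + _2q2q3 - ay) -
               4.0 * q1 * (1.0 - 2.0 * q1q1 - 2.0 * q2q2 - az) +
               _2bz * q3 * (_2bx * (0.5 - q2q2 - q3q3) +
                            _2bz * (q1q3 - q0q2) - mx) +
               (_2bx * q2 + _2bz * q0) *
                   (_2bx * (q1q2 - q0q3) + _2bz * (q0q1 + q2q3) - my) +
               (_2bx * q3 - _4bz * q1) *
                   (_2bx * (q0q2 + q1q3) + _2bz * (0.5 - q1q1 - q2q2) - mz);
          s2 = -_2q0 * (2.0 * q1q3 - _2q0q2 - ax) +
               _2q3 * (2.0 * q0q1 + _2q2q3 - ay) -
               4.0 * q2 * (1.0 - 2.0 * q1q1 - 2.0 * q2q2 - az) +
               (-_4bx * q2 - _2bz * q0) *
                   (_2bx * (0.5 - q2q2 - q3q3) + _2bz * (q1q3 - q0q2) - mx) +
               (_2bx * q1 + _2bz * q3) *
                   (_2bx * (q1q2 - q0q3) + _2bz * (q0q1 + q2q3) - my) +
               (_2bx * q0 - _4bz * q2) *
                   (_2bx * (q0q2 + q1q3) + _2bz * (0.5 - q1q1 - q2q2) - mz);
          s3 = _2q1 * (2.0 * q1q3 - _2q0q2 - ax) +
               _2q2 * (2.0 * q0q1 + _2q2q3 - ay) +
               (-_4bx * q3 + _2bz * q1) *
                   (_2bx * (0.5 - q2q2 - q3q3) + _2bz * (q1q3 - q0q2) - mx) +
               (-_2bx * q0 + _2bz * q2) *
                   (_2bx * (q1q2 - q0q3) + _2bz * (q0q1 + q2q3) - my) +
               _2bx * q1 * (_2bx * (q0q2 + q1q3) +
                            _2bz * (0.5 - q1q1 - q2q2) - mz);
        } else {
          double _2q0 = 2.0 * q0, _2q1 = 2.0 * q1, _2q2 = 2.0 * q2,
                 _2q3 = 2.0 * q3;
          double _4q0 = 4.0 * q0, _4q1 = 4.0 * q1, _4q2 = 4.0 * q2;
          double _8q1 = 8.0 * q1, _8q2 = 8.0 * q2;
          double q0q0 = q0 * q0, q1q1 = q1 * q1, q2q2 = q2 * q2,
                 q3q3 = q3 * q3;

          s0 = _4q0 * q2q2 + _2q2 * ax + _4q0 * q1q1 - _2q1 * ay;
          s1 = _4q1 * q3q3 - _2q3 * ax + 4.0 * q0q0 * q1 - _2q0 * ay - _4q1 +
               _8q1 * q1q1 + _8q1 * q2q2 + _4q1 * az;
          s2 = 4.0 * q0q0 * q2 + _2q0 * ax + _4q2 * q3q3 - _2q3 * ay - _4q2 +
               _8q2 * q1q1 + _8q2 * q2q2 + _4q2 * az;
          s3 = 4.0 * q1q1 * q3 - _2q1 * ax + 4.0 * q2q2 * q3 - _2q2 * ay;
        }
        double snorm = std::sqrt(s0 * s0 + s1 * s1 + s2 * s2 + s3 * s3);
        if (snorm > 0.0) {
          s0 /= snorm; s1 /= snorm; s2 /= snorm; s3 /= snorm;
          qDot0 -= beta * s0; qDot1 -= beta * s1;
          qDot2 -= beta * s2; qDot3 -= beta * s3;
        }
      }

      q0 += qDot0 * dt; q1 += qDot1 * dt; q2 += qDot2 * dt; q3 += qDot3 * dt;
    } else {  // Mahony
      if (acc_ok) {
        double norm = std::sqrt(ax * ax + ay * ay + az * az);
        ax /= norm; ay /= norm; az /= norm;

        // estimated direction of gravity (half magnitude)
        double halfvx = q1 * q3 - q0 * q2;
        double halfvy = q0 * q1 + q2 * q3;
        double halfvz = q0 * q0 - 0.5 + q3 * q3;

        double halfex = ay * halfvz - az * halfvy;
        double halfey = az * halfvx - ax * halfvz;
        double halfez = ax * halfvy - ay * halfvx;

        if (mag_ok) {
          double norm_m = std::sqrt(mx * mx + my * my + mz * mz);
          mx /= norm_m; my /= norm_m; mz /= norm_m;
          double q0q0 = q0 * q0, q0q1 = q0 * q1, q0q2 = q0 * q2,
                 q0q3 = q0 * q3, q1q1 = q1 * q1, q1q2 = q1 * q2,
                 q1q3 = q1 * q3, q2q2 = q2 * q2, q2q3 = q2 * q3,
                 q3q3 = q3 * q3;
          double hx = 2.0 * (mx * (0.5 - q2q2 - q3q3) + my * (q1q2 - q0q3) +
                             mz * (q1q3 + q0q2));
          double hy = 2.0 * (mx * (q1q2 + q0q3) + my * (0.5 - q1q1 - q3q3) +
                             mz * (q2q3 - q0q1));
          double bx = std::sqrt(hx * hx + hy * hy);
          double bz = 2.0 * (mx * (q1q3 - q0q2) + my * (q2q3 + q0q1) +
                             mz * (0.5 - q1q1 - q2q2));
          double halfwx = bx * (0.5 - q2q2 - q3q3) + bz * (q1q3 - q0q2);
          double halfwy = bx * (q1q2 - q0q3) + bz * (q0q1 + q2q3);
          double halfwz = bx * (q0q2 + q1q3) + bz * (0.5 - q1q1 - q2q2);
          halfex += my * halfwz - mz * halfwy;
          halfey += mz * halfwx - mx * halfwz;
          halfez += mx * halfwy - my * halfwx;
        }

        if (ki > 0.0) {
          ix += 2.0 * ki * halfex * dt;
          iy += 2.0 * ki * halfey * dt;
          iz += 2.0 * ki * halfez * dt;
          gx += ix; gy += iy; gz += iz;
        }
        gx += 2.0 * kp * halfex;
        gy += 2.0 * kp * halfey;
        gz += 2.0 * kp * halfez;
      }

      double hdt = 0.5 * dt;
      double gxh = gx * hdt, gyh = gy * hdt, gzh = gz * hdt;
      double qa = q0, qb = q1, qc = q2;
      q0 += -qb * gxh - qc * gyh - q3 * gzh;
      q1 += qa * gxh + qc * gzh - q3 * gyh;
      q2 += qa * gyh - qb * gzh + q3 * gxh;
      q3 += qa * gzh + qb * gyh - qc * gxh;
    }

    double qnorm = std::sqrt(q0 * q0 + q1 * q1 + q2 * q2 + q3 * q3);
    q0 /= qnorm; q1 /= qnorm; q2 /= qnorm; q3 /= qnorm;
    out(t, 0) = q0; out(t, 1) = q1; out(t, 2) = q2; out(t, 3) = q3;
  }
  return out;
}
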