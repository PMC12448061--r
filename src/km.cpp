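// Keller-Miksis radial dynamics integrator.
//
// Solves, in SI units, the compressibility-corrected bubble equation
//
//   (1 - U/c) R U' + (3/2)(1 - U/(3c)) U^2
//     = (1 + U/c) (p_B - p_inf - p_s(t)) / rho
//       + (R / (rho c)) d/dt (p_B - p_s)
//
// with liquid pressure at the wall
//
//   p_B = p_g0 (R0/R)^{3 kappa} + p_v - 2 sigma / R - 4 mu U / R,
//   p_g0 = p_inf + 2 sigma / R0 - p_v,
//
// i.e. a polytropic gas core set by mechanical equilibrium at R0, surface
// tension and Newtonian viscosity.  The viscous part of the radiation term
// contributes -4 mu U'/ (rho c), which is moved to the left-hand side so the
// acceleration stays explicit.  The drive p_s(t) is a uniformly sampled
// waveform (ultrasound burst plus the photoacoustic transient), linearly
// interpolated; its slope feeds the radiation-damping derivative term.
//
// Integration is adaptive embedded Dormand-Prince 5(4).  Near violent
// collapse the wall speed approaches the liquid sound speed; |U|/c is
// clamped inside the bracketed factors to keep the equation regular, and a
// hard positivity floor on R guards the (rare) steps where the gas term
// alone cannot stop the collapse at the requested tolerance.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Medium {
  double rho, mu, sigma, p_inf, p_v, kappa, c0;
};

struct Drive {
  const double* p;  // Pa
  double t0, dt;
  int n;
  // value at time t (zero outside support)
  inline double val(double t) const {
    double x = (t - t0) / dt;
    if (x <= 0.0 || x >= n - 1) return 0.0;
    int i = (int)x;
    double f = x - i;
    return p[i] * (1.0 - f) + p[i + 1] * f;
  }
  inline double slope(double t) const {
    double x = (t - t0) / dt;
    if (x <= 0.0 || x >= n - 1) return 0.0;
    int i = (int)x;
    return (p[i + 1] - p[i]) / dt;
  }
};

struct KM {
  Medium m;
  double R0, pg0, exp3k;

  inline void rhs(double t, double R, double U, const Drive& d,
                  double& dR, double& dU) const {
    const double c = m.c0;
    double uc = U / c;
    if (uc > 0.9) uc = 0.9;
    if (uc < -0.9) uc = -0.9;

    const double pg = pg0 * std::pow(R0 / R, exp3k);
    const double pB = pg + m.p_v - 2.0 * m.sigma / R - 4.0 * m.mu * U / R;
    const double ps = d.val(t);
    const double dpg = -exp3k * pg * U / R;
    const double dps = d.slope(t);

    double num = (1.0 + uc) * (pB - m.p_inf - ps) / m.rho
      + (R / (m.rho * c)) * (dpg + 2.0 * m.sigma * U / (R * R)
                             + 4.0 * m.mu * U * U / (R * R) - dps)
      - 1.5 * (1.0 - uc / 3.0) * U * U;
    double den = (1.0 - uc) * R + 4.0 * m.mu / (m.rho * c);
    dR = U;
    dU = num / den;
  }
};

}  // namespace

// [[Rcpp::export]]
List km_integrate_cpp(NumericVector drive_p, double drive_t0, double drive_dt,
                      double t_end, double dt_out,
                      double R0, double R_init, double U_init,
                      double rho, double mu, double sigma, double p_inf,
                      double p_v, double kappa, double c0,
                      double rtol, double max_steps) {
  KM km;
  km.m = Medium{rho, mu, sigma, p_inf, p_v, kappa, c0};
  km.R0 = R0;
  km.pg0 = p_inf + 2.0 * sigma / R0 - p_v;
  km.exp3k = 3.0 * kappa;
  if (km.pg0 <= 0.0) stop("equilibrium gas pressure is non-positive");

  Drive d{drive_p.begin(), drive_t0, drive_dt, (int)drive_p.size()};

  // Dormand-Prince 5(4) coefficients
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

  const double R_floor = 1e-3 * R0;
  const double dt_min = 1e-16;
  const double dt_max = dt_out;  // never skip an output sample
  const double U_scale = 1.0;    // m/s, absolute floor in the error norm

  int n_out = (int)std::floor(t_end / dt_out + 1e-9) + 1;
  NumericVector out_t(n_out), out_R(n_out), out_U(n_out);

  double t = 0.0, R = R_init, U = U_init;
  out_t[0] = 0.0; out_R[0] = R; out_U[0] = U;
  int iout = 1;
  long long nstep = 0, nreject = 0, nfloor = 0;
  double dt = 1e-12;

  double k1R, k1U, k2R, k2U, k3R, k3U, k4R, k4U, k5R, k5U, k6R, k6U, k7R, k7U;
  km.rhs(t, R, U, d, k1R, k1U);

  while (iout < n_out) {
    if (nstep > (long long)max_steps) {
      return List::create(_["ok"] = false,
                          _["message"] = "step budget exceeded",
                          _["t"] = out_t[Range(0, iout - 1)],
                          _["R"] = out_R[Range(0, iout - 1)],
                          _["U"] = out_U[Range(0, iout - 1)],
                          _["t_last"] = t, _["R_last"] = R, _["U_last"] = U,
                          _["nstep"] = (double)nstep,
                          _["nfloor"] = (double)nfloor);
    }
    double t_target = iout * dt_out;
    if (t + dt > t_target) dt = t_target - t;
    if (dt < dt_min) dt = dt_min;

    // stages
    double Rt, Ut;
    Rt = R + dt * a21 * k1R; Ut = U + dt * a21 * k1U;
    bool bad = (Rt <= R_floor);
    if (!bad) {
      km.rhs(t + c2 * dt, Rt, Ut, d, k2R, k2U);
      Rt = R + dt * (a31 * k1R + a32 * k2R);
      Ut = U + dt * (a31 * k1U + a32 * k2U);
      bad = (Rt <= R_floor);
    }
    if (!bad) {
      km.rhs(t + c3 * dt, Rt, Ut, d, k3R, k3U);
      Rt = R + dt * (a41 * k1R + a42 * k2R + a43 * k3R);
      Ut = U + dt * (a41 * k1U + a42 * k2U + a43 * k3U);
      bad = (Rt <= R_floor);
    }
    if (!bad) {
      km.rhs(t + c4 * dt, Rt, Ut, d, k4R, k4U);
      Rt = R + dt * (a51 * k1R + a52 * k2R + a53 * k3R + a54 * k4R);
      Ut = U + dt * (a51 * k1U + a52 * k2U + a53 * k3U + a54 * k4U);
      bad = (Rt <= R_floor);
    }
    if (!bad) {
      km.rhs(t + c5 * dt, Rt, Ut, d, k5R, k5U);
      Rt = R + dt * (a61 * k1R + a62 * k2R + a63 * k3R + a64 * k4R + a65 * k5R);
      Ut = U + dt * (a61 * k1U + a62 * k2U + a63 * k3U + a64 * k4U + a65 * k5U);
      bad = (Rt <= R_floor);
    }
    double R5 = 0, U5 = 0, errn = 0;
    if (!bad) {
      km.rhs(t + dt, Rt, Ut, d, k6R, k6U);
      R5 = R + dt * (b1 * k1R + b3 * k3R + b4 * k4R + b5 * k5R + b6 * k6R);
      U5 = U + dt * (b1 * k1U + b3 * k3U + b4 * k4U + b5 * k5U + b6 * k6U);
      bad = (R5 <= R_floor) || !std::isfinite(R5) || !std::isfinite(U5);
    }
    if (!bad) {
      km.rhs(t + dt, R5, U5, d, k7R, k7U);  // FSAL stage
      double eR = dt * (e1 * k1R + e3 * k3R + e4 * k4R + e5 * k5R +
                        e6 * k6R + e7 * k7R);
      double eU = dt * (e1 * k1U + e3 * k3U + e4 * k4U + e5 * k5U +
                        e6 * k6U + e7 * k7U);
      double scR = rtol * (std::fabs(R5) + 0.01 * R0);
      double scU = rtol * (std::fabs(U5) + U_scale);
      errn = std::sqrt(0.5 * ((eR / scR) * (eR / scR) +
                              (eU / scU) * (eU / scU)));
      bad = !std::isfinite(errn);
    }

    if (!bad && errn <= 1.0) {
      t += dt;
      R = R5; U = U5;
      k1R = k7R; k1U = k7U;  // FSAL
      ++nstep;
      if (t >= t_target - 1e-18 || std::fabs(t - t_target) < 1e-6 * dt_out) {
        out_t[iout] = t; out_R[iout] = R; out_U[iout] = U;
        ++iout;
      }
      double fac = 0.9 * std::pow(std::max(errn, 1e-10), -0.2);
      if (fac > 5.0) fac = 5.0;
      dt *= fac;
      if (dt > dt_max) dt = dt_max;
    } else {
      ++nreject;
      if (dt <= dt_min * 2.0) {
        // tolerance floor: take the best available estimate and move on
        t += dt;
        if (std::isfinite(R5) && std::isfinite(U5) && R5 > R_floor) {
          R = R5; U = U5;
        } else {
          R = R_floor;
          if (U < 0) U = 0;
        }
        ++nfloor; ++nstep;
        km.rhs(t, R, U, d, k1R, k1U);
        if (t >= t_target - 1e-18 ||
            std::fabs(t - t_target) < 1e-6 * dt_out) {
          out_t[iout] = t; out_R[iout] = R; out_U[iout] = U;
          ++iout;
        }
        dt = dt_min * 4.0;
      } else {
        dt *= bad ? 0.25 : std::max(0.1, 0.9 * std::pow(errn, -0.2));
      }
      if (dt < dt_min) dt = dt_min;
    }
  }

  return List::create(_["ok"] = true, _["message"] = "",
                      _["t"] = out_t, _["R"] = out_R, _["U"] = out_U,
                      _["t_last"] = t, _["R_last"] = R, _["U_last"] = U,
                      _["nstep"] = (double)nstep,
                      _["nreject"] = (double)nreject,
                      _["nfloor"] = (double)nfloor);
}
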