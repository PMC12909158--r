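// Core ODE machinery for the EVLP lung model.
//
// The model couples four subsystems driven by a pressure-ramp ventilator:
//   - lung mechanics: alveolar pressure P_A and tidal volume V_A behind a
//     single airway resistance against a linear compliance,
//   - alveolar gas fractions F_A_O2 / F_A_CO2 in the gas-exchange volume,
//   - capillary partial pressures P_c_O2 / P_c_CO2 with perfusate
//     refreshment and bicarbonate buffering of CO2 (concentration z),
//   - left-atrial mixing of shunted and end-capillary perfusate.
//
// State layout (8 doubles):
//   0 P_A [cmH2O], 1 F_A_O2 [-], 2 F_A_CO2 [-], 3 P_c_O2 [mmHg],
//   4 P_c_CO2 [mmHg], 5 z [mol/L], 6 V_A [L] (tidal volume above the
//   unstressed volume at the reference state), 7 V_insp [L] (cumulative
//   inspired alveolar volume within the current breath).
//
// Parameter vector layout (30 doubles, canonical units: s, L, L/s,
// cmH2O for airway pressures, mmHg for gas tensions, mol/L):
//   0 Vt, 1 Tinsp, 2 Texp, 3 PEEP, 4 FiO2, 5 Cstat, 6 Q, 7 h,
//   8 PPAO2, 9 PPACO2, 10 Fds, 11 Fsh, 12 VD, 13 VA0, 14 Raw,
//   15 FiCO2, 16 Patm, 17 Pw, 18 VdotO2, 19 VdotCO2, 20 DO2, 21 DCO2,
//   22 DO2p, 23 DCO2p, 24 sigmaO2, 25 sigmaCO2, 26 Vctot, 27 delta,
//   28 r2, 29 l2
//
// The ventilator pressure is discontinuous at the inspiration->expiration
// transition, and the dead-space gas composition is re-frozen at every
// inspiration onset, so the integrator is restarted at each phase boundary
// rather than stepping across it.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double CMH2O_MMHG = 0.7356;
constexpr int NS = 8;
constexpr double TEPS = 1e-9; // time comparison slack [s]

enum MixingModel { MIX_DILUTION = 0, MIX_PLUG = 1 };

// F_D regime within a phase: fresh inspirate, rebreathed dead-space gas
// (plug-flow front not yet washed out), or the constant volume-weighted
// dilution mix.  Expiration always uses FD_FRESH (the term is inactive).
enum FdMode { FD_FRESH = 0, FD_REBREATHE = 1, FD_DILUTION = 2 };

struct Pars {
  double Vt, Tinsp, Texp, PEEP, FiO2, Cstat, Q, h, PPAO2, PPACO2;
  double Fds, Fsh, VD, VA0, Raw;
  double FiCO2, Patm, Pw, VdotO2, VdotCO2, DO2, DCO2, DO2p, DCO2p;
  double sigmaO2, sigmaCO2, Vctot, delta, r2, l2;
  int mixing;
};

Pars make_pars(const NumericVector& p, int mixing) {
  if (p.size() != 30) stop("parameter vector must have length 30");
  Pars q;
  q.Vt = p[0]; q.Tinsp = p[1]; q.Texp = p[2]; q.PEEP = p[3]; q.FiO2 = p[4];
  q.Cstat = p[5]; q.Q = p[6]; q.h = p[7]; q.PPAO2 = p[8]; q.PPACO2 = p[9];
  q.Fds = p[10]; q.Fsh = p[11]; q.VD = p[12]; q.VA0 = p[13]; q.Raw = p[14];
  q.FiCO2 = p[15]; q.Patm = p[16]; q.Pw = p[17];
  q.VdotO2 = p[18]; q.VdotCO2 = p[19];
  q.DO2 = p[20]; q.DCO2 = p[21]; q.DO2p = p[22]; q.DCO2p = p[23];
  q.sigmaO2 = p[24]; q.sigmaCO2 = p[25]; q.Vctot = p[26]; q.delta = p[27];
  q.r2 = p[28]; q.l2 = p[29];
  q.mixing = mixing;
  if (q.Tinsp <= 0 || q.Texp <= 0) stop("T_insp and T_exp must be positive");
  if (q.Cstat <= 0 || q.Raw <= 0) stop("C_stat and R_aw must be positive");
  if (1.0 - q.Fds - q.Fsh <= 0)
    stop("F_ds + F_sh must be < 1 (gas-exchange compartment is empty)");
  return q;
}

// u: time since the start of the current inspiration [s].
// fd: dead-space gas composition frozen at inspiration onset (O2, CO2).
void rhs(const Pars& P, bool insp, int fdmode, const double fd[2],
         double u, const double y[NS], double dy[NS]) {
  const double Pplat = P.PEEP + P.Vt / P.Cstat;
  const double pvent = insp ? P.PEEP + (Pplat - P.PEEP) * u / P.Tinsp
                            : P.PEEP;
  const double flow = (pvent - y[0]) / P.Raw;
  dy[0] = flow / P.Cstat;
  dy[6] = flow;

  const double fge = 1.0 - P.Fds - P.Fsh;
  const double Vge = fge * (P.VA0 + y[6]);
  const double Pdry = P.Patm + CMH2O_MMHG * y[0] - P.Pw;
  const double PAO2 = y[1] * Pdry;
  const double PACO2 = y[2] * Pdry;

  double fin = 0.0, vi = 0.0;
  if (insp && flow > 0.0) {
    fin = flow;
    vi = fin * fge / (fge + P.Fds); // share entering the ge volume
  }
  dy[7] = fin;

  double FDO2 = P.FiO2, FDCO2 = P.FiCO2;
  if (fdmode == FD_REBREATHE) {
    FDO2 = fd[0];
    FDCO2 = fd[1];
  } else if (fdmode == FD_DILUTION) {
    const double w = std::min(P.VD, P.Vt) / P.Vt;
    FDO2 = (1.0 - w) * P.FiO2 + w * fd[0];
    FDCO2 = (1.0 - w) * P.FiCO2 + w * fd[1];
  }

  const double jO2 = P.DO2 * (y[3] - PAO2);   // volumetric flux into alveoli
  const double jCO2 = P.DCO2 * (y[4] - PACO2);
  dy[1] = (jO2 + (FDO2 - y[1]) * vi - y[1] * (jCO2 + jO2)
           + (y[1] - 1.0) * P.VdotO2 - y[1] * P.VdotCO2) / Vge;
  dy[2] = (jCO2 + (FDCO2 - y[2]) * vi - y[2] * (jCO2 + jO2)
           + (1.0 - y[2]) * P.VdotCO2 + y[2] * P.VdotO2) / Vge;

  const double Vcge = (1.0 - P.Fsh) * P.Vctot;
  dy[3] = P.DO2p / (P.sigmaO2 * Vcge) * (PAO2 - y[3])
        + P.Q / P.Vctot * (P.PPAO2 - y[3]);
  dy[4] = P.DCO2p / (P.sigmaCO2 * Vcge) * (PACO2 - y[4])
        + P.Q / P.Vctot * (P.PPACO2 - y[4])
        + P.delta * P.l2 * P.h * y[5] / P.sigmaCO2
        - P.delta * P.r2 * y[4];
  dy[5] = P.delta * P.r2 * P.sigmaCO2 * y[4] - P.delta * P.l2 * P.h * y[5];
}

// Maximal eigenvalue scale of the capillary relaxation: used to switch
// between the explicit and the linearly implicit stepper.  The capillary
// equilibration rate D'/(sigma * V_c_ge) grows like 1/(1 - F_sh) and can
// exceed 1e4 1/s at high shunt fractions, where an explicit pair is
// hopeless at any tolerance.
double stiffness_rate(const Pars& P) {
  const double Vcge = (1.0 - P.Fsh) * P.Vctot;
  double r = P.DO2p / (P.sigmaO2 * Vcge);
  r = std::max(r, P.DCO2p / (P.sigmaCO2 * Vcge));
  r = std::max(r, P.delta * P.r2);
  r = std::max(r, P.delta * P.l2 * P.h);
  return r;
}

constexpr double STIFF_SWITCH = 400.0; // [1/s]

// Dormand-Prince 5(4) coefficients.
const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
const double A21 = 1.0 / 5;
const double A31 = 3.0 / 40, A32 = 9.0 / 40;
const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
             A53 = 64448.0 / 6561, A54 = -212.0 / 729;
const double A61 = 9017.0 / 3168, A62 = -355.0 / 33, A63 = 46732.0 / 5247,
             A64 = 49.0 / 176, A65 = -5103.0 / 18656;
const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
             B5 = -2187.0 / 6784, B6 = 11.0 / 84;
const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
             E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

struct StepWork {
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  double yt[NS], ynew[NS];
};

// One attempted DP5 step of size h from (t, y); fills w.ynew and returns the
// scaled error norm.  u0 is (t - inspiration start).
double dp5_step(const Pars& P, bool insp, int fdmode, const double fd[2],
                double u0, const double y[NS], double h, StepWork& w,
                double rtol, double atol) {
  rhs(P, insp, fdmode, fd, u0, y, w.k1);
  for (int i = 0; i < NS; ++i) w.yt[i] = y[i] + h * A21 * w.k1[i];
  rhs(P, insp, fdmode, fd, u0 + C2 * h, w.yt, w.k2);
  for (int i = 0; i < NS; ++i)
    w.yt[i] = y[i] + h * (A31 * w.k1[i] + A32 * w.k2[i]);
  rhs(P, insp, fdmode, fd, u0 + C3 * h, w.yt, w.k3);
  for (int i = 0; i < NS; ++i)
    w.yt[i] = y[i] + h * (A41 * w.k1[i] + A42 * w.k2[i] + A43 * w.k3[i]);
  rhs(P, insp, fdmode, fd, u0 + C4 * h, w.yt, w.k4);
  for (int i = 0; i < NS; ++i)
    w.yt[i] = y[i] + h * (A51 * w.k1[i] + A52 * w.k2[i] + A53 * w.k3[i]
                          + A54 * w.k4[i]);
  rhs(P, insp, fdmode, fd, u0 + C5 * h, w.yt, w.k5);
  for (int i = 0; i < NS; ++i)
    w.yt[i] = y[i] + h * (A61 * w.k1[i] + A62 * w.k2[i] + A63 * w.k3[i]
                          + A64 * w.k4[i] + A65 * w.k5[i]);
  rhs(P, insp, fdmode, fd, u0 + h, w.yt, w.k6);
  for (int i = 0; i < NS; ++i)
    w.ynew[i] = y[i] + h * (B1 * w.k1[i] + B3 * w.k3[i] + B4 * w.k4[i]
                            + B5 * w.k5[i] + B6 * w.k6[i]);
  rhs(P, insp, fdmode, fd, u0 + h, w.ynew, w.k7);

  double err2 = 0.0;
  for (int i = 0; i < NS; ++i) {
    const double e = h * (E1 * w.k1[i] + E3 * w.k3[i] + E4 * w.k4[i]
                          + E5 * w.k5[i] + E6 * w.k6[i] + E7 * w.k7[i]);
    const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                             std::fabs(w.ynew[i]));
    err2 += (e / sc) * (e / sc);
  }
  return std::sqrt(err2 / NS);
}

// --- L-stable SDIRK4 (Hairer & Wanner, gamma = 1/4) -------------------
// Five stages, order 4 with an embedded order-3 error estimate.  The
// tableau satisfies all order-4 conditions to machine precision and
// R(-inf) = 0 (verified numerically in the test suite).
const double SG = 0.25; // diagonal gamma
const double SA[5][5] = {
    {0.25, 0, 0, 0, 0},
    {0.5, 0.25, 0, 0, 0},
    {17.0 / 50, -1.0 / 25, 0.25, 0, 0},
    {371.0 / 1360, -137.0 / 2720, 15.0 / 544, 0.25, 0},
    {25.0 / 24, -49.0 / 48, 125.0 / 16, -85.0 / 12, 0.25}};
const double SC[5] = {0.25, 0.75, 11.0 / 20, 0.5, 1.0};
const double SB[5] = {25.0 / 24, -49.0 / 48, 125.0 / 16, -85.0 / 12, 0.25};
const double SBH[5] = {59.0 / 48, -17.0 / 96, 225.0 / 32, -85.0 / 12, 0.0};

// typical magnitudes for Jacobian increments and error scaling
const double YSCALE[NS] = {10, 0.1, 0.02, 100, 30, 0.01, 0.5, 0.3};

struct LU8 {
  double m[NS][NS];
  int piv[NS];
  // factor (I - h*gamma*J); returns false if singular
  bool factor(const double J[NS][NS], double hg) {
    for (int i = 0; i < NS; ++i)
      for (int j = 0; j < NS; ++j)
        m[i][j] = (i == j ? 1.0 : 0.0) - hg * J[i][j];
    for (int k = 0; k < NS; ++k) {
      int p = k;
      for (int i = k + 1; i < NS; ++i)
        if (std::fabs(m[i][k]) > std::fabs(m[p][k])) p = i;
      if (std::fabs(m[p][k]) < 1e-300) return false;
      piv[k] = p;
      if (p != k)
        for (int j = 0; j < NS; ++j) std::swap(m[k][j], m[p][j]);
      for (int i = k + 1; i < NS; ++i) {
        m[i][k] /= m[k][k];
        for (int j = k + 1; j < NS; ++j) m[i][j] -= m[i][k] * m[k][j];
      }
    }
    return true;
  }
  void solve(double x[NS]) const {
    for (int k = 0; k < NS; ++k)
      if (piv[k] != k) std::swap(x[k], x[piv[k]]);
    for (int i = 0; i < NS; ++i)
      for (int j = 0; j < i; ++j) x[i] -= m[i][j] * x[j];
    for (int i = NS - 1; i >= 0; --i) {
      for (int j = i + 1; j < NS; ++j) x[i] -= m[i][j] * x[j];
      x[i] /= m[i][i];
    }
  }
};

void num_jacobian(const Pars& P, bool insp, int fdmode, const double fd[2],
                  double u, const double y[NS], const double f0[NS],
                  double J[NS][NS]) {
  double yp[NS], fp[NS];
  for (int j = 0; j < NS; ++j) {
    const double dy = 1e-7 * std::max(std::fabs(y[j]), YSCALE[j]);
    for (int i = 0; i < NS; ++i) yp[i] = y[i];
    yp[j] += dy;
    rhs(P, insp, fdmode, fd, u, yp, fp);
    for (int i = 0; i < NS; ++i) J[i][j] = (fp[i] - f0[i]) / dy;
  }
}

// One attempted SDIRK4 step; returns the scaled error norm, or a negative
// value when the Newton iteration failed (caller should reduce h).
double sdirk_step(const Pars& P, bool insp, int fdmode, const double fd[2],
                  double u0, const double y[NS], double h, StepWork& w,
                  double rtol, double atol) {
  double f0[NS], J[NS][NS];
  rhs(P, insp, fdmode, fd, u0, y, f0);
  num_jacobian(P, insp, fdmode, fd, u0, y, f0, J);
  LU8 lu;
  if (!lu.factor(J, h * SG)) return -1.0;

  double F[5][NS], Y[NS], G[NS];
  for (int s = 0; s < 5; ++s) {
    double r[NS];
    for (int i = 0; i < NS; ++i) {
      r[i] = y[i];
      for (int j = 0; j < s; ++j) r[i] += h * SA[s][j] * F[j][i];
    }
    for (int i = 0; i < NS; ++i) Y[i] = r[i]; // predictor
    bool ok = false;
    for (int it = 0; it < 12; ++it) {
      rhs(P, insp, fdmode, fd, u0 + SC[s] * h, Y, F[s]);
      double nrm = 0.0;
      for (int i = 0; i < NS; ++i) {
        G[i] = r[i] + h * SG * F[s][i] - Y[i];
      }
      lu.solve(G); // Newton increment
      for (int i = 0; i < NS; ++i) {
        Y[i] += G[i];
        const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 YSCALE[i]);
        nrm += (G[i] / sc) * (G[i] / sc);
      }
      nrm = std::sqrt(nrm / NS);
      if (!std::isfinite(nrm)) return -1.0;
      if (nrm < 1e-2) { ok = true; break; }
    }
    if (!ok) return -1.0;
    rhs(P, insp, fdmode, fd, u0 + SC[s] * h, Y, F[s]);
  }
  double err[NS];
  double err2 = 0.0;
  for (int i = 0; i < NS; ++i) {
    w.ynew[i] = y[i];
    for (int s = 0; s < 5; ++s) w.ynew[i] += h * SB[s] * F[s][i];
    err[i] = 0.0;
    for (int s = 0; s < 5; ++s)
      err[i] += h * (SB[s] - SBH[s]) * F[s][i];
  }
  lu.solve(err); // damp the estimate for stiff components
  for (int i = 0; i < NS; ++i) {
    const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                             std::fabs(w.ynew[i]));
    err2 += (err[i] / sc) * (err[i] / sc);
  }
  return std::sqrt(err2 / NS);
}

struct Collector {
  // sample grid (absolute times, sorted); may be empty
  const double* stops = nullptr;
  int nstops = 0;
  int idx = 0;
  std::vector<double>* times = nullptr;
  std::vector<double>* ys = nullptr; // row-major NS per sample
  // trapezoid accumulators for cycle means of the capillary tensions
  bool accumulate = false;
  double accO2 = 0.0, accCO2 = 0.0;

  void record(double t, const double y[NS]) {
    if (times) {
      times->push_back(t);
      for (int i = 0; i < NS; ++i) ys->push_back(y[i]);
    }
  }
  double next_stop(double t, double t_end) const {
    if (stops) {
      for (int j = idx; j < nstops; ++j)
        if (stops[j] > t + TEPS)
          return (stops[j] <= t_end + TEPS) ? std::min(stops[j], t_end)
                                            : t_end;
    }
    return t_end;
  }
  void maybe_record(double t, const double y[NS]) {
    while (stops && idx < nstops && stops[idx] <= t + TEPS) {
      record(stops[idx], y);
      ++idx;
    }
  }
};

// Integrate one ventilator phase from t to t_end.  tins0 is the absolute
// time of the current inspiration onset.  Handles the plug-flow dead-space
// washout event (V_insp crossing V_D) by shortening the step onto the
// crossing and switching the F_D regime.
void advance_phase(const Pars& P, bool insp, double tins0,
                   double& t, double t_end, double y[NS], double fd[2],
                   double& h, double rtol, double atol, double hmax,
                   bool stiff, Collector& col) {
  StepWork w;
  const double expo = stiff ? 0.25 : 0.2; // embedded orders 3 and 4
  int fdmode;
  if (P.mixing == MIX_PLUG)
    fdmode = (insp && y[7] < P.VD - 1e-9) ? FD_REBREATHE : FD_FRESH;
  else
    fdmode = insp ? FD_DILUTION : FD_FRESH;

  long guard = 0;
  while (t < t_end - TEPS) {
    if (++guard > 50000000L)
      stop("integrator stalled near t = %f (h=%g, y=[%g %g %g %g %g %g %g %g])",
           t, h, y[0], y[1], y[2], y[3], y[4], y[5], y[6], y[7]);
    const double target = col.next_stop(t, t_end);
    double hstep = std::min({h, hmax, target - t});
    if (hstep < 1e-14) { t = target; col.maybe_record(t, y); continue; }

    bool accepted = false;
    int crossings = 0;
    while (!accepted) {
      const double err = stiff
          ? sdirk_step(P, insp, fdmode, fd, t - tins0, y, hstep, w, rtol,
                       atol)
          : dp5_step(P, insp, fdmode, fd, t - tins0, y, hstep, w, rtol,
                     atol);
      if (err < 0.0 || !std::isfinite(err)) { // Newton failure / NaN
        hstep *= (err < 0.0 ? 0.25 : 0.1);
        if (hstep < 1e-13)
          stop("non-finite derivative near t = %f (P_A=%g, F_A_O2=%g, "
               "P_c_O2=%g)", t, y[0], y[1], y[3]);
        continue;
      }
      if (err > 1.0) {
        hstep *= std::max(0.2, 0.9 * std::pow(err, -expo));
        if (hstep < 1e-13) stop("step size underflow at t = %f", t);
        continue;
      }
      // dead-space front crossing (plug-flow model only)
      if (fdmode == FD_REBREATHE && w.ynew[7] > P.VD + 1e-9 &&
          (P.VD - y[7]) > 1e-9 && crossings < 20) {
        const double dv = w.ynew[7] - y[7];
        double frac = dv > 0 ? (P.VD - y[7]) / dv : 0.5;
        frac = std::min(std::max(frac, 0.05), 0.95);
        hstep *= frac;
        ++crossings;
        continue;
      }
      // reject trajectories that leave the physically meaningful region
      // (e.g. metabolic demand exceeding supply at extreme shunt
      // fractions drives fractions and tensions negative without bound)
      if (w.ynew[1] < -0.01 || w.ynew[1] > 1.01 || w.ynew[2] < -0.01 ||
          w.ynew[2] > 1.01 || w.ynew[3] < -20.0 || w.ynew[4] < -20.0 ||
          w.ynew[3] > 1e4 || w.ynew[4] > 1e4 || w.ynew[5] < -1e-3 ||
          std::fabs(w.ynew[0]) > 1e3)
        stop("state left the physically valid region at t = %.3f "
             "(F_A_O2=%g, F_A_CO2=%g, P_c_O2=%g, P_c_CO2=%g)", t,
             w.ynew[1], w.ynew[2], w.ynew[3], w.ynew[4]);
      accepted = true;
      if (col.accumulate) {
        col.accO2 += 0.5 * hstep * (y[3] + w.ynew[3]);
        col.accCO2 += 0.5 * hstep * (y[4] + w.ynew[4]);
      }
      for (int i = 0; i < NS; ++i) y[i] = w.ynew[i];
      t = (std::fabs(t + hstep - target) < TEPS) ? target : t + hstep;
      if (fdmode == FD_REBREATHE && y[7] >= P.VD - 1e-9) fdmode = FD_FRESH;
      col.maybe_record(t, y);
      const double fac = (err <= 1e-12)
          ? 5.0
          : std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -expo)));
      h = std::min(hmax, hstep * fac);
    }
  }
  t = t_end;
}

// Walk the ventilator cycle structure from t0 to t1.  At every inspiration
// onset the dead-space composition is frozen to the current alveolar
// fractions and the cumulative inspired volume resets.
void integrate_interval(const Pars& P, double& t, double t1, double y[NS],
                        double fd[2], double& h, double rtol, double atol,
                        double hmax, Collector& col) {
  const double Tcyc = P.Tinsp + P.Texp;
  const bool stiff = stiffness_rate(P) > STIFF_SWITCH;
  while (t < t1 - TEPS) {
    double k = std::floor((t + TEPS) / Tcyc);
    double u = t - k * Tcyc;
    if (u > Tcyc - TEPS) { k += 1.0; u = 0.0; }
    const double tins0 = k * Tcyc;
    bool insp;
    double seg_end;
    if (u <= TEPS) {
      insp = true;
      seg_end = tins0 + P.Tinsp;
      fd[0] = y[1];
      fd[1] = y[2];
      y[7] = 0.0;
    } else if (u < P.Tinsp - TEPS) {
      insp = true;
      seg_end = tins0 + P.Tinsp;
    } else {
      insp = false;
      seg_end = tins0 + Tcyc;
    }
    seg_end = std::min(seg_end, t1);
    advance_phase(P, insp, tins0, t, seg_end, y, fd, h, rtol, atol, hmax,
                  stiff, col);
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_rhs(double t, NumericVector y, NumericVector pars,
                      NumericVector fd, int mixing) {
  const Pars P = make_pars(pars, mixing);
  if (y.size() != NS) stop("state must have length 8");
  if (fd.size() != 2) stop("fd must have length 2");
  const double Tcyc = P.Tinsp + P.Texp;
  const double u = t - std::floor((t + TEPS) / Tcyc) * Tcyc;
  const bool insp = u < P.Tinsp - TEPS || u <= TEPS;
  double yv[NS], dy[NS], fdv[2] = {fd[0], fd[1]};
  for (int i = 0; i < NS; ++i) yv[i] = y[i];
  int fdmode;
  if (P.mixing == MIX_PLUG)
    fdmode = (insp && yv[7] < P.VD) ? FD_REBREATHE : FD_FRESH;
  else
    fdmode = insp ? FD_DILUTION : FD_FRESH;
  const double u0 = (u <= TEPS) ? 0.0 : u;
  rhs(P, insp, fdmode, fdv, u0, yv, dy);
  NumericVector out(NS);
  for (int i = 0; i < NS; ++i) out[i] = dy[i];
  return out;
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector pars, NumericVector y0, NumericVector fd0,
                  double t0, double t1, NumericVector sample_times,
                  double rtol, double atol, double hmax, int mixing) {
  const Pars P = make_pars(pars, mixing);
  if (y0.size() != NS) stop("state must have length 8");
  double y[NS], fd[2] = {fd0[0], fd0[1]};
  for (int i = 0; i < NS; ++i) y[i] = y0[i];

  std::vector<double> st, sy;
  st.reserve(sample_times.size());
  sy.reserve(sample_times.size() * NS);
  Collector col;
  col.stops = sample_times.begin();
  col.nstops = sample_times.size();
  col.times = &st;
  col.ys = &sy;

  double t = t0, h = 1e-3;
  col.maybe_record(t, y); // samples at or before t0
  integrate_interval(P, t, t1, y, fd, h, rtol, atol, hmax, col);
  col.maybe_record(t1, y);

  const int n = (int)st.size();
  NumericMatrix Y(n, NS);
  NumericVector tv(n);
  for (int r = 0; r < n; ++r) {
    tv[r] = st[r];
    for (int i = 0; i < NS; ++i) Y(r, i) = sy[(size_t)r * NS + i];
  }
  NumericVector yend(NS);
  for (int i = 0; i < NS; ++i) yend[i] = y[i];
  return List::create(_["time"] = tv, _["states"] = Y, _["y_end"] = yend,
                      _["fd_end"] = NumericVector::create(fd[0], fd[1]));
}

// [[Rcpp::export]]
List cpp_run_to_steady(NumericVector pars, NumericVector y0,
                       NumericVector fd0, double tol, double max_time,
                       double rtol, double atol, double hmax, int mixing) {
  const Pars P = make_pars(pars, mixing);
  if (y0.size() != NS) stop("state must have length 8");
  const double Tcyc = P.Tinsp + P.Texp;
  double y[NS], fd[2] = {fd0[0], fd0[1]};
  for (int i = 0; i < NS; ++i) y[i] = y0[i];

  std::vector<double> mO2, mCO2;
  double t = 0.0, h = 1e-3;
  bool converged = false;
  const int max_cycles = (int)std::ceil(max_time / Tcyc);
  Collector col;
  col.accumulate = true;
  for (int cyc = 0; cyc < max_cycles; ++cyc) {
    col.accO2 = col.accCO2 = 0.0;
    const double tend = (cyc + 1) * Tcyc;
    integrate_interval(P, t, tend, y, fd, h, rtol, atol, hmax, col);
    const double pcO2 = col.accO2 / Tcyc;
    const double pcCO2 = col.accCO2 / Tcyc;
    mO2.push_back(P.PPAO2 * P.Fsh + (1.0 - P.Fsh) * pcO2);
    mCO2.push_back(P.PPACO2 * P.Fsh + (1.0 - P.Fsh) * pcCO2);
    const size_t n = mO2.size();
    if (n >= 2 && std::fabs(mO2[n - 1] - mO2[n - 2]) < tol &&
        std::fabs(mCO2[n - 1] - mCO2[n - 2]) < tol) {
      converged = true;
      break;
    }
  }
  NumericVector yend(NS);
  for (int i = 0; i < NS; ++i) yend[i] = y[i];
  return List::create(
      _["y_end"] = yend,
      _["fd_end"] = NumericVector::create(fd[0], fd[1]),
      _["mean_pla_o2"] = wrap(mO2), _["mean_pla_co2"] = wrap(mCO2),
      _["n_cycles"] = (int)mO2.size(), _["converged"] = converged,
      _["time"] = t);
}

// Fixed-step classical RK4 reference integrator (solver-independence
// oracle).  Steps are clipped onto phase boundaries and sample times.
// [[Rcpp::export]]
List cpp_simulate_fixed(NumericVector pars, NumericVector y0,
                        NumericVector fd0, double t0, double t1, double dt,
                        NumericVector sample_times, int mixing) {
  const Pars P = make_pars(pars, mixing);
  if (dt <= 0) stop("dt must be positive");
  const double Tcyc = P.Tinsp + P.Texp;
  double y[NS], fd[2] = {fd0[0], fd0[1]};
  for (int i = 0; i < NS; ++i) y[i] = y0[i];

  std::vector<double> st, sy;
  int sidx = 0;
  const int nst = sample_times.size();
  auto rec = [&](double tt) {
    while (sidx < nst && sample_times[sidx] <= tt + TEPS) {
      st.push_back(sample_times[sidx]);
      for (int i = 0; i < NS; ++i) sy.push_back(y[i]);
      ++sidx;
    }
  };

  double t = t0;
  rec(t);
  double k1[NS], k2[NS], k3[NS], k4[NS], yt[NS];
  while (t < t1 - TEPS) {
    double k = std::floor((t + TEPS) / Tcyc);
    double u = t - k * Tcyc;
    if (u > Tcyc - TEPS) { k += 1.0; u = 0.0; }
    const double tins0 = k * Tcyc;
    bool insp;
    double seg_end;
    if (u <= TEPS) {
      insp = true;
      seg_end = tins0 + P.Tinsp;
      fd[0] = y[1]; fd[1] = y[2]; y[7] = 0.0;
    } else if (u < P.Tinsp - TEPS) {
      insp = true;
      seg_end = tins0 + P.Tinsp;
    } else {
      insp = false;
      seg_end = tins0 + Tcyc;
    }
    seg_end = std::min(seg_end, t1);
    double hh = std::min(dt, seg_end - t);
    if (sidx < nst && sample_times[sidx] > t + TEPS)
      hh = std::min(hh, sample_times[sidx] - t);
    int fdmode;
    if (P.mixing == MIX_PLUG)
      fdmode = (insp && y[7] < P.VD) ? FD_REBREATHE : FD_FRESH;
    else
      fdmode = insp ? FD_DILUTION : FD_FRESH;
    const double u0 = t - tins0;
    rhs(P, insp, fdmode, fd, u0, y, k1);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + 0.5 * hh * k1[i];
    rhs(P, insp, fdmode, fd, u0 + 0.5 * hh, yt, k2);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + 0.5 * hh * k2[i];
    rhs(P, insp, fdmode, fd, u0 + 0.5 * hh, yt, k3);
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + hh * k3[i];
    rhs(P, insp, fdmode, fd, u0 + hh, yt, k4);
    for (int i = 0; i < NS; ++i)
      y[i] += hh / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    t += hh;
    rec(t);
  }

  const int n = (int)st.size();
  NumericMatrix Y(n, NS);
  NumericVector tv(n);
  for (int r = 0; r < n; ++r) {
    tv[r] = st[r];
    for (int i = 0; i < NS; ++i) Y(r, i) = sy[(size_t)r * NS + i];
  }
  NumericVector yend(NS);
  for (int i = 0; i < NS; ++i) yend[i] = y[i];
  return List::create(_["time"] = tv, _["states"] = Y, _["y_end"] = yend,
                      _["fd_end"] = NumericVector::create(fd[0], fd[1]));
}
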