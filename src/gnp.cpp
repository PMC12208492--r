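// Model right-hand sides (cHH, fGNP, GNP, vGNP, kvGNP, navGNP, iHH) and an
// adaptive Dormand-Prince 5(4) integrator. All voltages in mV, concentrations
// in mM, currents in uA/cm^2, time in ms. The parameter vector layout is
// produced by .pack_params() on the R side; the two must stay in step.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// parameter vector indices
enum {
  P_VARIANT = 0, P_F, P_RT, P_RTF_MV,
  P_SOV, P_CM, P_AIN,
  P_SIGK, P_SIGNA, P_SIGCL,
  P_PKL, P_PNAL, P_PCLL,
  P_PKG, P_PNAG,
  P_PKV, P_PNAV,
  P_GKM, P_GNAM,
  P_GGLU, P_EGLU,
  P_GLH, P_ELH,
  P_GKL_IHH, P_GNAL_IHH, P_GCLL_IHH,
  P_GKG_IHH, P_GNAG_IHH,
  P_PUMPMODE, P_ICONST, P_MNAK,
  P_FK3, P_FK2, P_FK1, P_FK0,
  P_FNA3, P_FNA2, P_FNA1, P_FNA0,
  P_KO_FIX, P_NAI_FIX, P_CLI_FIX,
  P_NPAR
};

enum { V_CHH = 0, V_FGNP, V_GNP, V_VGNP, V_KVGNP, V_NAVGNP, V_IHH };

// g(x) = (1 - exp(-x))/x, g(0) = 1
static inline double gfun(double x) {
  if (std::fabs(x) < 1e-4) return 1.0 - x / 2.0 + x * x / 6.0;
  return -std::expm1(-x) / x;
}

struct Currents {
  double V, IKV, INaV, IKL, INaL, IClL, IKG, INaG, INaK;
};

// GHK current density in uA/cm^2, model sign convention I = -G (V - Eq)
static inline double ghk_uA(double z, double V_mV, double ci, double co,
                            double P, const double* p) {
  double u = z * V_mV / p[P_RTF_MV];
  double flux; // V * (ci - co e^{-u}) / (1 - e^{-u}) in V*mol/m^3
  if (std::fabs(u) < 1e-4) {
    double RT_zF = p[P_RT] / (z * p[P_F]);
    flux = RT_zF * ((ci - co) + u * (ci + co) / 2.0 + u * u * (ci - co) / 12.0);
  } else {
    double em = std::expm1(-u);
    flux = (V_mV / 1000.0) * ((ci - co) - co * em) / (-em);
  }
  return -100.0 * z * z * p[P_F] * p[P_F] * P * flux / p[P_RT];
}

static inline double cubic(double V, const double* n) {
  return ((n[0] * V + n[1]) * V + n[2]) * V + n[3];
}

static inline double pump_uA(double Nai, double Ko, const double* p) {
  if (p[P_PUMPMODE] < 0.5) return p[P_ICONST];
  double bound = 100.0 * p[P_F] * p[P_MNAK] / p[P_SOV];
  double s1 = 1.0 / (1.0 + std::exp((25.0 - Nai) / 3.0));
  double s2 = 1.0 / (1.0 + std::exp(3.5 - Ko));
  return -bound * s1 * s2;
}

static void gate_rates(double V, double* a, double* b) {
  double x;
  x = (V + 54.0) / 4.0;  a[0] = 0.32 * 4.0 / gfun(x);
  x = -(V + 27.0) / 5.0; b[0] = 0.28 * 5.0 / gfun(x);
  a[1] = 0.128 * std::exp(-(V + 50.0) / 18.0);
  b[1] = 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0));
  x = (V + 52.0) / 5.0;  a[2] = 0.032 * 5.0 / gfun(x);
  b[2] = 0.5 * std::exp(-(V + 57.0) / 40.0);
}

// full RHS; y and dy have the variant's dimension; cur filled if non-null
static void rhs(const double* p, const double* y, double t, double po,
                double* dy, Currents* cur) {
  int variant = (int)(p[P_VARIANT] + 0.5);
  double RTF = p[P_RTF_MV];
  double kconv = p[P_SOV] / (p[P_F] * 1e5); // mM/ms per uA/cm^2
  double V, Ko, Nai, Cli, m, h, n;
  bool conc_dynamic = (variant >= V_GNP && variant <= V_NAVGNP) || variant == V_IHH;

  if (variant == V_CHH || variant == V_FGNP) {
    V = y[0]; m = y[1]; h = y[2]; n = y[3];
    Ko = p[P_KO_FIX]; Nai = p[P_NAI_FIX]; Cli = p[P_CLI_FIX];
  } else if (variant == V_IHH) {
    V = y[0]; Ko = y[1]; Nai = y[2]; Cli = y[3]; m = y[4]; h = y[5]; n = y[6];
  } else { // GNP family: V algebraic
    Ko = y[0]; Nai = y[1]; Cli = y[2]; m = y[3]; h = y[4]; n = y[5];
    V = 0.0; // set below
  }

  double Ki = p[P_SIGK] - Ko, Nao = p[P_SIGNA] - Nai, Clo = p[P_SIGCL] - Cli;

  if (variant >= V_GNP && variant <= V_NAVGNP) {
    double cvc = 1000.0 * p[P_F] / (2.0 * p[P_SOV] * p[P_CM] * 1e-2); // mV/mM
    V = cvc * (-p[P_AIN] + (Ki - Ko) + (Nai - Nao) - (Cli - Clo));
  }

  double EK = RTF * std::log(Ko / Ki);
  double ENa = RTF * std::log(Nao / Nai);
  double ECl = -RTF * std::log(Clo / Cli);

  // leak currents
  double IKL, INaL, IClL;
  if (variant == V_CHH) {
    IKL = -p[P_GLH] * (V - p[P_ELH]); INaL = 0.0; IClL = 0.0; // lumped in IKL slot
  } else if (variant == V_IHH) {
    IKL = -p[P_GKL_IHH] * (V - EK);
    INaL = -p[P_GNAL_IHH] * (V - ENa);
    IClL = -p[P_GCLL_IHH] * (V - ECl);
  } else {
    IKL = ghk_uA(+1, V, Ki, Ko, p[P_PKL], p);
    INaL = ghk_uA(+1, V, Nai, Nao, p[P_PNAL], p);
    IClL = ghk_uA(-1, V, Cli, Clo, p[P_PCLL], p);
  }

  // glutamatergic currents
  double IKG, INaG;
  if (variant == V_CHH || variant == V_FGNP) {
    IKG = -po * p[P_GGLU] * (V - p[P_EGLU]); INaG = 0.0; // lumped
  } else if (variant == V_IHH) {
    IKG = -po * p[P_GKG_IHH] * (V - EK);
    INaG = -po * p[P_GNAG_IHH] * (V - ENa);
  } else {
    IKG = po * ghk_uA(+1, V, Ki, Ko, p[P_PKG], p);
    INaG = po * ghk_uA(+1, V, Nai, Nao, p[P_PNAG], p);
  }

  // voltage-gated currents
  double n4 = n * n * n * n, m3h = m * m * m * h;
  double IKV, INaV;
  bool k_ghk = (variant == V_VGNP || variant == V_KVGNP);
  bool na_ghk = (variant == V_VGNP || variant == V_NAVGNP);
  if (k_ghk) {
    double fK = cubic(V, p + P_FK3);
    IKV = n4 * ghk_uA(+1, V, Ki, Ko, p[P_PKV], p) / fK;
  } else {
    IKV = -p[P_GKM] * n4 * (V - EK);
  }
  if (na_ghk) {
    double fNa = cubic(V, p + P_FNA3);
    INaV = m3h * ghk_uA(+1, V, Nai, Nao, p[P_PNAV], p) / fNa;
  } else {
    INaV = -p[P_GNAM] * m3h * (V - ENa);
  }

  double INaK = pump_uA(Nai, Ko, p);

  // gate derivatives
  double a[3], b[3];
  gate_rates(V, a, b);
  double dm = a[0] * (1.0 - m) - b[0] * m;
  double dh = a[1] * (1.0 - h) - b[1] * h;
  double dn = a[2] * (1.0 - n) - b[2] * n;

  // Chloride carries charge -1: a (positive-inward) chloride current IClL
  // corresponds to chloride LEAVING the cell, so d[Cl-]i/dt = -(S/vF) IClL.
  // Only this sign is consistent with Cm dV/dt = sum(Iq) under the
  // charge-voltage relation (and keeps the chloride leak diffusive).
  if (variant == V_CHH || variant == V_FGNP) {
    // cHH lumps the linear leak in the IKL slot (INaL = IClL = 0); fGNP has
    // all three GHK leak components
    double Itot = IKV + INaV + IKL + INaL + IClL + IKG + INaK;
    dy[0] = Itot / p[P_CM];
    dy[1] = dm; dy[2] = dh; dy[3] = dn;
  } else if (variant == V_IHH) {
    double Itot = IKV + INaV + IKL + INaL + IClL + IKG + INaG + INaK;
    dy[0] = Itot / p[P_CM];
    dy[1] = kconv * (-IKV - IKL - IKG + 2.0 * INaK);
    dy[2] = kconv * (INaV + INaL + INaG + 3.0 * INaK);
    dy[3] = -kconv * IClL;
    dy[4] = dm; dy[5] = dh; dy[6] = dn;
  } else {
    dy[0] = kconv * (-IKV - IKL - IKG + 2.0 * INaK);
    dy[1] = kconv * (INaV + INaL + INaG + 3.0 * INaK);
    dy[2] = -kconv * IClL;
    dy[3] = dm; dy[4] = dh; dy[5] = dn;
  }

  if (cur) {
    cur->V = V; cur->IKV = IKV; cur->INaV = INaV;
    cur->IKL = IKL; cur->INaL = INaL; cur->IClL = IClL;
    cur->IKG = IKG; cur->INaG = INaG; cur->INaK = INaK;
  }
  (void)conc_dynamic;
}

static double stim_po(double t, const NumericVector& t0,
                      const NumericVector& t1, const NumericVector& po) {
  for (int i = 0; i < t0.size(); ++i)
    if (t >= t0[i] && t < t1[i]) return po[i];
  return 0.0;
}

// [[Rcpp::export(name = ".rhs_eval_cpp")]]
List rhs_eval_cpp(NumericVector par, NumericVector y, double t, double po) {
  if (par.size() != P_NPAR) stop("parameter vector has wrong length");
  int nv = y.size();
  std::vector<double> dy(nv);
  Currents cur;
  rhs(REAL(par), REAL(y), t, po, dy.data(), &cur);
  return List::create(
    _["dy"] = NumericVector(dy.begin(), dy.end()),
    _["V"] = cur.V,
    _["IKV"] = cur.IKV, _["INaV"] = cur.INaV,
    _["IKL"] = cur.IKL, _["INaL"] = cur.INaL, _["IClL"] = cur.IClL,
    _["IKG"] = cur.IKG, _["INaG"] = cur.INaG, _["INaK"] = cur.INaK);
}

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
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// [[Rcpp::export(name = ".integrate_cpp")]]
List integrate_cpp(NumericVector par, NumericVector y0,
                   double t_start, double t_end, double dt_sample,
                   NumericVector stim_t0, NumericVector stim_t1,
                   NumericVector stim_po_v,
                   double rtol, NumericVector atol,
                   double h_init, double h_max, double h_min,
                   bool record_currents) {
  if (par.size() != P_NPAR) stop("parameter vector has wrong length");
  int nv = y0.size();
  if (atol.size() != nv) stop("atol must have one entry per state variable");
  const double* p = REAL(par);

  int nsamp = (int)std::floor((t_end - t_start) / dt_sample + 0.5) + 1;
  NumericVector tout(nsamp);
  NumericMatrix Y(nsamp, nv);
  NumericMatrix C(record_currents ? nsamp : 1, 10); // V + 9 currents

  std::vector<double> y(y0.begin(), y0.end()), ynew(nv), yerr(nv);
  std::vector<double> k1(nv), k2(nv), k3(nv), k4(nv), k5(nv), k6(nv), k7(nv),
      ytmp(nv);

  // breakpoints where the RHS is discontinuous in t (stimulus switches)
  std::vector<double> breaks;
  for (int i = 0; i < stim_t0.size(); ++i) {
    breaks.push_back(stim_t0[i]);
    breaks.push_back(stim_t1[i]);
  }
  breaks.push_back(t_end + 1.0);
  std::sort(breaks.begin(), breaks.end());

  double t = t_start, h = h_init;
  int isamp = 0;
  Currents cur;

  auto record = [&](int idx) {
    tout[idx] = t;
    for (int j = 0; j < nv; ++j) Y(idx, j) = y[j];
    if (record_currents) {
      double po = stim_po(t, stim_t0, stim_t1, stim_po_v);
      std::vector<double> dd(nv);
      rhs(p, y.data(), t, po, dd.data(), &cur);
      C(idx, 0) = cur.V; C(idx, 1) = cur.IKV; C(idx, 2) = cur.INaV;
      C(idx, 3) = cur.IKL; C(idx, 4) = cur.INaL; C(idx, 5) = cur.IClL;
      C(idx, 6) = cur.IKG; C(idx, 7) = cur.INaG; C(idx, 8) = cur.INaK;
      C(idx, 9) = po;
    }
  };
  record(isamp++);

  bool have_k1 = false;
  long nsteps = 0, nreject = 0;
  while (isamp < nsamp) {
    double t_target = t_start + isamp * dt_sample;
    // next discontinuity after t
    double t_break = t_end;
    for (double br : breaks)
      if (br > t + 1e-12) { t_break = std::min(t_end, br); break; }
    double t_stop = std::min(t_target, t_break);
    if (h > t_stop - t) h = t_stop - t;
    if (h < h_min) h = h_min;

    double po = stim_po(t + 0.5 * h, stim_t0, stim_t1, stim_po_v);
    if (!have_k1) {
      rhs(p, y.data(), t, po, k1.data(), nullptr);
      have_k1 = true;
    }
    for (int j = 0; j < nv; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
    rhs(p, ytmp.data(), t + c2 * h, po, k2.data(), nullptr);
    for (int j = 0; j < nv; ++j)
      ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    rhs(p, ytmp.data(), t + c3 * h, po, k3.data(), nullptr);
    for (int j = 0; j < nv; ++j)
      ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    rhs(p, ytmp.data(), t + c4 * h, po, k4.data(), nullptr);
    for (int j = 0; j < nv; ++j)
      ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
    rhs(p, ytmp.data(), t + c5 * h, po, k5.data(), nullptr);
    for (int j = 0; j < nv; ++j)
      ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                            a64 * k4[j] + a65 * k5[j]);
    rhs(p, ytmp.data(), t + h, po, k6.data(), nullptr);
    for (int j = 0; j < nv; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
    rhs(p, ynew.data(), t + h, po, k7.data(), nullptr);

    double err = 0.0;
    for (int j = 0; j < nv; ++j) {
      double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                       e6 * k6[j] + e7 * k7[j]);
      double sc = atol[j] + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      double r = ej / sc;
      err += r * r;
    }
    err = std::sqrt(err / nv);

    if (err <= 1.0 || h <= h_min * (1.0 + 1e-10)) {
      t += h;
      y = ynew;
      k1 = k7; // FSAL
      nsteps++;
      if (t >= t_target - 1e-9 * std::max(1.0, std::fabs(t_target))) {
        t = t_target;
        record(isamp++);
      }
      if (t >= t_break - 1e-12 && t < t_break + 1e-12) have_k1 = false;
    } else {
      nreject++;
      have_k1 = true; // k1 still valid at (t, y)
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h = std::min(h * fac, h_max);
    if (!R_FINITE(h) || h <= 0) stop("integrator step size collapsed at t = %f", t);
    bool bad = false;
    for (int j = 0; j < nv; ++j) if (!R_FINITE(y[j])) bad = true;
    if (bad) stop("non-finite state at t = %f (integration failure)", t);
    if (nsteps + nreject > 500000000L) stop("step budget exceeded");
  }

  return List::create(_["t"] = tout, _["Y"] = Y, _["C"] = C,
                      _["nsteps"] = (double)nsteps, _["nreject"] = (double)nreject);
}
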