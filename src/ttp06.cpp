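// Ten Tusscher-Panfilov 2006 human ventricular myocyte kinetics and
// monodomain tissue runners (1-D cable and tetrahedral FEM with lumped mass).
//
// State layout (19 doubles):
//   0 V (mV), 1 Nai, 2 Ki, 3 Cai, 4 CaSS, 5 CaSR (mM),
//   6 m, 7 h, 8 j, 9 xr1, 10 xr2, 11 xs, 12 r, 13 s, 14 d, 15 f, 16 f2,
//   17 fCaSS, 18 Rq (RyR adaptation).
// Gates use Rush-Larsen exponential updates; V and concentrations forward
// Euler. Stimulus convention: `amp` > 0 depolarizes (internally a negative
// transmembrane current, also booked into the K+ balance as in the original
// model code).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 19;

// physical constants
static const double Rgas = 8314.472, Temp = 310.0, Frd = 96485.3415;
static const double RTONF = Rgas * Temp / Frd;  // 26.7137 mV
static const double inverseVcF2 = 1.0 / (2.0 * 0.016404 * Frd);
static const double inverseVcF = 1.0 / (0.016404 * Frd);
static const double inversevssF2 = 1.0 / (2.0 * 0.00005468 * Frd);
static const double CAPACITANCE = 0.185;  // uF/cm^2, cell-level bookkeeping
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;

// extracellular concentrations (mM)
static const double Ko = 5.4, Nao = 140.0, Cao = 2.0;

// maximal conductances / fluxes (common)
static const double Gkr = 0.153, GK1 = 5.405, GNa = 14.838, GbNa = 0.00029;
static const double KmK = 1.0, KmNa = 40.0, knak = 2.724;
static const double GCaL = 0.00003980, GbCa = 0.000592;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
                    n_gamma = 0.35;
static const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
static const double pKNa = 0.03;
// SR handling
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
// buffering
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;

// variant: 0 epicardial, 1 endocardial, 2 mid-myocardial
static inline double Gks_of(int variant) {
  return (variant == 2) ? 0.098 : 0.392;
}
static inline double Gto_of(int variant) {
  return (variant == 1) ? 0.073 : 0.294;
}

// One reaction step. y: state (modified in place). Istim: depolarizing
// stimulus in pA/pF (positive raises V). Returns dV/dt used (mV/ms).
static inline double tt_step(double* y, double dt, double Istim, int variant) {
  const double V = y[0];
  const double Nai = y[1], Ki = y[2];
  const double Cai = y[3], CaSS = y[4], CaSR = y[5];

  const double Ek = RTONF * std::log(Ko / Ki);
  const double Ena = RTONF * std::log(Nao / Nai);
  const double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  // fast sodium
  const double INa = GNa * y[6] * y[6] * y[6] * y[7] * y[8] * (V - Ena);
  // L-type calcium (GHK-like driving term, on CaSS)
  double ICaL;
  {
    const double Vm15 = V - 15.0;
    if (std::fabs(Vm15) < 1e-6) {
      // evaluate just off the removable singularity at V == 15 mV
      const double ee = 1e-4;
      const double expv = std::exp(2.0 * ee / RTONF);
      ICaL = GCaL * y[14] * y[15] * y[16] * y[17] * 4.0 * ee * (Frd / RTONF) *
             (0.25 * CaSS * expv - Cao) / (expv - 1.0);
    } else {
      const double expv = std::exp(2.0 * Vm15 / RTONF);
      ICaL = GCaL * y[14] * y[15] * y[16] * y[17] * 4.0 * Vm15 * (Frd / RTONF) *
             (0.25 * CaSS * expv - Cao) / (expv - 1.0);
    }
  }
  const double Ito = Gto_of(variant) * y[12] * y[13] * (V - Ek);
  const double IKr = Gkr * std::sqrt(Ko / 5.4) * y[9] * y[10] * (V - Ek);
  const double IKs = Gks_of(variant) * y[11] * y[11] * (V - Eks);
  double IK1;
  {
    const double aK1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
    const double bK1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                        std::exp(0.1 * (V - Ek - 10.0))) /
                       (1.0 + std::exp(-0.5 * (V - Ek)));
    IK1 = GK1 * std::sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - Ek);
  }
  const double INaCa =
      knaca *
      (std::exp(n_gamma * V / RTONF) * Nai * Nai * Nai * Cao -
       std::exp((n_gamma - 1.0) * V / RTONF) * Nao * Nao * Nao * Cai * 2.5) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((n_gamma - 1.0) * V / RTONF)));
  const double INaK =
      knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
      (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
       0.0353 * std::exp(-V / RTONF));
  const double IpCa = GpCa * Cai / (KpCa + Cai);
  const double IpK = GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * (V - Ena);
  const double IbCa = GbCa * (V - Eca);

  const double Iion = IKr + IKs + IK1 + Ito + INa + IbNa + ICaL + IbCa + INaK +
                      INaCa + IpCa + IpK;
  const double Istim_neg = -Istim;  // original-code sign convention

  // calcium subsystem
  const double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  const double k1 = k1p / kCaSR;
  const double k2 = k2p * kCaSR;
  const double dRq = k4 * (1.0 - y[18]) - k2 * CaSS * y[18];
  y[18] += dt * dRq;
  const double OO = k1 * CaSS * CaSS * y[18] / (k3 + k1 * CaSS * CaSS);
  const double Irel = Vrel * OO * (CaSR - CaSS);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  const double Ixfer = Vxfer * (CaSS - Cai);

  const double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
  const double dCaSR = dt * (Iup - Irel - Ileak);
  const double bjsr = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
  const double cjsr = Kbufsr * (CaCSQN + dCaSR + CaSR);
  y[5] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

  const double CaSSBuf = Bufss * CaSS / (CaSS + Kbufss);
  const double dCaSS =
      dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
            (-ICaL * inversevssF2 * CAPACITANCE));
  const double bcss = Bufss - CaSSBuf - dCaSS - CaSS + Kbufss;
  const double ccss = Kbufss * (CaSSBuf + dCaSS + CaSS);
  y[4] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

  const double CaBuf = Bufc * Cai / (Cai + Kbufc);
  const double dCai =
      dt * ((-(IbCa + IpCa - 2.0 * INaCa) * inverseVcF2 * CAPACITANCE) -
            (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  const double bc = Bufc - CaBuf - dCai - Cai + Kbufc;
  const double cc = Kbufc * (CaBuf + dCai + Cai);
  y[3] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  y[1] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * inverseVcF *
                CAPACITANCE);
  y[2] += dt * (-(Istim_neg + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) *
                inverseVcF * CAPACITANCE);

  // gate updates (Rush-Larsen)
  {
    const double m_inf =
        1.0 / ((1.0 + std::exp((-56.86 - V) / 9.03)) *
               (1.0 + std::exp((-56.86 - V) / 9.03)));
    const double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                      0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
    const double tau_m = am * bm;
    double h_inf = 1.0 / ((1.0 + std::exp((V + 71.55) / 7.43)) *
                          (1.0 + std::exp((V + 71.55) / 7.43)));
    double ah, bh, aj, bj;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    const double tau_h = 1.0 / (ah + bh);
    const double tau_j = 1.0 / (aj + bj);
    const double j_inf = h_inf;

    const double xr1_inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    const double tau_xr1 = axr1 * bxr1;
    const double xr2_inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    const double tau_xr2 = axr2 * bxr2;
    const double xs_inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    const double axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    const double bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    const double tau_xs = axs * bxs + 80.0;

    const double r_inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
    const double tau_r =
        9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    double s_inf, tau_s;
    if (variant == 1) {  // endocardial
      s_inf = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
      tau_s = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
    } else {
      s_inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      tau_s = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
              5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    }

    const double d_inf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    const double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    const double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    const double gd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    const double tau_d = ad * bd + gd;
    const double f_inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    const double tau_f =
        1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
        200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
        180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    const double f2_inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    const double tau_f2 =
        562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
        31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
        80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    const double fcass_inf = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
    const double tau_fcass =
        80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;

    y[6] = m_inf - (m_inf - y[6]) * std::exp(-dt / tau_m);
    y[7] = h_inf - (h_inf - y[7]) * std::exp(-dt / tau_h);
    y[8] = j_inf - (j_inf - y[8]) * std::exp(-dt / tau_j);
    y[9] = xr1_inf - (xr1_inf - y[9]) * std::exp(-dt / tau_xr1);
    y[10] = xr2_inf - (xr2_inf - y[10]) * std::exp(-dt / tau_xr2);
    y[11] = xs_inf - (xs_inf - y[11]) * std::exp(-dt / tau_xs);
    y[12] = r_inf - (r_inf - y[12]) * std::exp(-dt / tau_r);
    y[13] = s_inf - (s_inf - y[13]) * std::exp(-dt / tau_s);
    y[14] = d_inf - (d_inf - y[14]) * std::exp(-dt / tau_d);
    y[15] = f_inf - (f_inf - y[15]) * std::exp(-dt / tau_f);
    y[16] = f2_inf - (f2_inf - y[16]) * std::exp(-dt / tau_f2);
    y[17] = fcass_inf - (fcass_inf - y[17]) * std::exp(-dt / tau_fcass);
    // clamp gates (RL keeps them in [0,1] analytically; guard roundoff)
    for (int g = 6; g <= 18; ++g) {
      if (y[g] < 0.0) y[g] = 0.0;
      if (y[g] > 1.0) y[g] = 1.0;
    }
  }

  const double dV = -(Iion + Istim_neg);
  y[0] = V + dt * dV;
  return dV;
}

// published steady resting state (epicardial cell, long quiescence)
// [[Rcpp::export]]
NumericVector ttp06_initial_state_cpp() {
  NumericVector y(NSTATE);
  y[0] = -85.23;  y[1] = 8.604;   y[2] = 136.89;
  y[3] = 0.000126; y[4] = 0.00036; y[5] = 3.64;
  y[6] = 0.00172; y[7] = 0.7444;  y[8] = 0.7045;
  y[9] = 0.00621; y[10] = 0.4712; y[11] = 0.0095;
  y[12] = 2.42e-8; y[13] = 0.999998; y[14] = 3.373e-5;
  y[15] = 0.7888; y[16] = 0.9755; y[17] = 0.9953; y[18] = 0.9073;
  y.attr("names") =
      CharacterVector::create("V", "Nai", "Ki", "Cai", "CaSS", "CaSR", "m",
                              "h", "j", "xr1", "xr2", "xs", "r", "s", "d",
                              "f", "f2", "fCass", "Rq");
  return y;
}

static void check_state(const NumericVector& s) {
  if (s.size() != NSTATE)
    stop("state vector must have length %d", NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(s[i])) stop("non-finite state entry at position %d", i + 1);
}

// [[Rcpp::export]]
NumericVector ttp06_step_cpp(NumericVector state, double stim, double dt,
                             int variant) {
  check_state(state);
  NumericVector out = clone(state);
  tt_step(REAL(out), dt, stim, variant);
  for (int i = 0; i < NSTATE; ++i)
    if (!std::isfinite(out[i]))
      stop("membrane integration diverged (state %d non-finite; V was %g mV)",
           i + 1, state[0]);
  out.attr("names") = state.attr("names");
  return out;
}

// Single-cell run with periodic stimuli. Records V every record_dt.
// [[Rcpp::export]]
List ttp06_cell_run_cpp(NumericVector state0, double t_end, double dt,
                        NumericVector stim_onsets, double stim_dur,
                        double stim_amp, double record_dt, int variant) {
  check_state(state0);
  std::vector<double> y(state0.begin(), state0.end());
  const int nrec = (int)std::floor(t_end / record_dt) + 1;
  NumericVector tout(nrec), vout(nrec), caout(nrec);
  int irec = 0;
  const long nstep = (long)std::llround(t_end / dt);
  for (long k = 0; k <= nstep; ++k) {
    const double t = k * dt;
    if (irec < nrec && t + 1e-9 >= irec * record_dt) {
      tout[irec] = t; vout[irec] = y[0]; caout[irec] = y[3]; ++irec;
    }
    if (k == nstep) break;
    double stim = 0.0;
    for (int q = 0; q < stim_onsets.size(); ++q) {
      if (t >= stim_onsets[q] && t < stim_onsets[q] + stim_dur) {
        stim = stim_amp; break;
      }
      if (stim_onsets[q] > t) break;
    }
    tt_step(y.data(), dt, stim, variant);
    if (!std::isfinite(y[0]))
      stop("membrane integration diverged at t = %g ms", t);
  }
  NumericVector fin(y.begin(), y.end());
  fin.attr("names") = state0.attr("names");
  return List::create(_["time"] = tout, _["vm"] = vout, _["cai"] = caout,
                      _["state"] = fin);
}

// Helper: update activation time on upward threshold crossing.
static inline void record_activation(double* act, double vprev, double vnow,
                                     double t, double dt, double thr,
                                     int node) {
  if (std::isnan(act[node]) && vprev < thr && vnow >= thr) {
    const double frac = (thr - vprev) / (vnow - vprev);
    act[node] = t + frac * dt;
  }
}

// 1-D monodomain cable, uniform spacing h (cm), diffusivity D (cm^2/ms).
// Returns per-node activation times (NA when unactivated).
// [[Rcpp::export]]
List strand_run_cpp(int n, double h, double D, NumericVector state0,
                    double dt, IntegerVector stim_nodes,
                    NumericVector stim_onsets, double stim_dur,
                    double stim_amp, double t_end, double act_start,
                    double vthresh, bool stop_when_activated) {
  check_state(state0);
  if (n < 3) stop("strand needs at least 3 nodes");
  const double r = D * dt / (h * h);
  if (r > 0.5) stop("explicit diffusion unstable: D*dt/h^2 = %g > 0.5", r);
  std::vector<double> Y((std::size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < NSTATE; ++s) Y[(std::size_t)i * NSTATE + s] = state0[s];
  std::vector<double> act((std::size_t)n, NA_REAL);
  std::vector<double> vold((std::size_t)n), lap((std::size_t)n);
  std::vector<char> is_stim((std::size_t)n, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) {
    int idx = stim_nodes[k];
    if (idx < 0 || idx >= n) stop("stimulus node out of range");
    is_stim[idx] = 1;
  }
  const long nstep = (long)std::llround(t_end / dt);
  const int variant = 0;  // tissue default: epicardial
  for (long kstep = 0; kstep < nstep; ++kstep) {
    const double t = kstep * dt;
    double stim_on = 0.0;
    for (int q = 0; q < stim_onsets.size(); ++q)
      if (t >= stim_onsets[q] && t < stim_onsets[q] + stim_dur) {
        stim_on = stim_amp; break;
      }
    for (int i = 0; i < n; ++i) vold[i] = Y[(std::size_t)i * NSTATE];
    // diffusion (no-flux ends)
    lap[0] = 2.0 * (vold[1] - vold[0]);
    lap[n - 1] = 2.0 * (vold[n - 2] - vold[n - 1]);
    for (int i = 1; i < n - 1; ++i)
      lap[i] = vold[i - 1] - 2.0 * vold[i] + vold[i + 1];
    for (int i = 0; i < n; ++i) {
      double* y = &Y[(std::size_t)i * NSTATE];
      const double stim = is_stim[i] ? stim_on : 0.0;
      tt_step(y, dt, stim, variant);
      y[0] += r * lap[i];
      if (!std::isfinite(y[0]))
        stop("monodomain cable diverged at t = %g ms (node %d)", t, i + 1);
      if (t + dt >= act_start)
        record_activation(act.data(), vold[i], y[0], t, dt, vthresh, i);
    }
    if (stop_when_activated) {
      bool all = true;
      for (int i = 0; i < n; ++i)
        if (std::isnan(act[i])) { all = false; break; }
      if (all) break;
    }
  }
  return List::create(_["activation"] = NumericVector(act.begin(), act.end()));
}

// Tetrahedral monodomain: reaction stepping per node plus explicit lumped-mass
// FEM diffusion (V <- V - dt_diff * (K V) / mass) every dt_diff.
// K passed in CSR form (0-based), mass = lumped mass vector.
// [[Rcpp::export]]
List tet_monodomain_cpp(IntegerVector Kp, IntegerVector Kj, NumericVector Kx,
                        NumericVector mass, NumericVector state0, double dt,
                        int diff_every, IntegerVector stim_nodes,
                        NumericVector stim_onsets, double stim_dur,
                        double stim_amp, double t_end, double act_start,
                        double vthresh, bool stop_when_activated) {
  check_state(state0);
  const int n = mass.size();
  if (Kp.size() != n + 1) stop("CSR row pointer length mismatch");
  std::vector<double> Y((std::size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < NSTATE; ++s) Y[(std::size_t)i * NSTATE + s] = state0[s];
  std::vector<double> act((std::size_t)n, NA_REAL);
  std::vector<double> v((std::size_t)n), kv((std::size_t)n);
  std::vector<char> is_stim((std::size_t)n, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) {
    int idx = stim_nodes[k];
    if (idx < 0 || idx >= n) stop("stimulus node out of range");
    is_stim[idx] = 1;
  }
  const double dt_diff = dt * diff_every;
  const long nstep = (long)std::llround(t_end / dt);
  const int variant = 0;
  for (long kstep = 0; kstep < nstep; ++kstep) {
    const double t = kstep * dt;
    double stim_on = 0.0;
    for (int q = 0; q < stim_onsets.size(); ++q)
      if (t >= stim_onsets[q] && t < stim_onsets[q] + stim_dur) {
        stim_on = stim_amp; break;
      }
    for (int i = 0; i < n; ++i) {
      double* y = &Y[(std::size_t)i * NSTATE];
      v[i] = y[0];
      tt_step(y, dt, is_stim[i] ? stim_on : 0.0, variant);
    }
    if ((kstep + 1) % diff_every == 0) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int p = Kp[i]; p < Kp[i + 1]; ++p) acc += Kx[p] * Y[(std::size_t)Kj[p] * NSTATE];
        kv[i] = acc;
      }
      for (int i = 0; i < n; ++i)
        Y[(std::size_t)i * NSTATE] -= dt_diff * kv[i] / mass[i];
    }
    bool all = stop_when_activated;
    for (int i = 0; i < n; ++i) {
      const double vn = Y[(std::size_t)i * NSTATE];
      if (!std::isfinite(vn))
        stop("monodomain solver diverged at t = %g ms (node %d)", t, i + 1);
      if (t + dt >= act_start)
        record_activation(act.data(), v[i], vn, t, dt, vthresh, i);
      if (all && std::isnan(act[i])) all = false;
    }
    if (all) break;
  }
  return List::create(_["activation"] = NumericVector(act.begin(), act.end()));
}
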