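// Courtemanche-Ramirez-Nattel (1998) human atrial cell model, Rush-Larsen
// integration, a 1-D cable monodomain solver (implicit diffusion via the
// Thomas algorithm) and small numeric helpers.  Units: mV, ms, mM, pA/pF.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NSTATE = 21;
// state layout: 0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
// 10 d, 11 f, 12 fca, 13 u, 14 v, 15 w, 16 Nai, 17 Ki, 18 Cai, 19 Caup,
// 20 Carel

// physical constants and model parameters
static const double Rgas = 8.3143, Temp = 310.0, Frdy = 96.4867;
static const double Cmem = 100.0;                  // pF
static const double Vi = 13668.0, Vup = 1109.52, Vrel = 96.48; // um^3
static const double Ko = 5.4, Nao = 140.0, Cao = 1.8;          // mM
static const double gNa = 7.8, gK1 = 0.09, gto = 0.1652;
static const double gKr = 0.029411765, gKs = 0.12941176, gCaL = 0.12375;
static const double gbCa = 0.001131, gbNa = 0.0006744375;
static const double INaK_max = 0.59933874, KmNai = 10.0, KmKo = 1.5;
static const double INaCa_max = 1600.0, KmNa = 87.5, KmCa = 1.38;
static const double ksat = 0.1, gam = 0.35;
static const double IpCa_max = 0.275;
static const double krel = 30.0, tau_tr = 180.0;
static const double Iup_max = 0.005, Kup = 0.00092, Caup_max = 15.0;
static const double Cmdn_max = 0.05, Trpn_max = 0.07, Csqn_max = 10.0;
static const double KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8;
static const double KQ10 = 3.0;

struct Rates {
  double inf[16], tau[16];   // gate slots 1..15 used
  double dV, dNai, dKi, dCai, dCaup, dCarel;
  double Iion;               // total membrane current, pA/pF
};

static inline double safe_ratio(double num, double den, double lim) {
  return (std::fabs(den) < 1e-10) ? lim : num / den;
}

// Full CRN right-hand side: gate steady states / time constants and
// concentration + voltage derivatives.  stim in pA/pF, positive depolarizes.
static void crn_rates(const double* s, double stim, Rates& r) {
  const double V = s[0];
  const double Nai = s[16], Ki = s[17], Cai = s[18], Caup = s[19], Carel = s[20];
  const double RTF = Rgas * Temp / Frdy;
  const double FVRT = V / RTF;

  const double ENa = RTF * std::log(Nao / Nai);
  const double EK  = RTF * std::log(Ko / Ki);
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  const double INa = gNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
  const double IK1 = gK1 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  const double Ito = gto * s[4] * s[4] * s[4] * s[5] * (V - EK);
  const double gKur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  const double IKur = gKur * s[6] * s[6] * s[6] * s[7] * (V - EK);
  const double IKr = gKr * s[8] * (V - EK) / (1.0 + std::exp((V + 15.0) / 22.4));
  const double IKs = gKs * s[9] * s[9] * (V - EK);
  const double ICaL = gCaL * s[10] * s[11] * s[12] * (V - 65.0);
  const double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * FVRT) +
                             0.0365 * sig * std::exp(-FVRT));
  const double INaK = INaK_max * fNaK * (Ko / (Ko + KmKo)) /
                      (1.0 + std::pow(KmNai / Nai, 1.5));
  const double INaCa = INaCa_max *
      (std::exp(gam * FVRT) * Nai * Nai * Nai * Cao -
       std::exp((gam - 1.0) * FVRT) * Nao * Nao * Nao * Cai) /
      ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * std::exp((gam - 1.0) * FVRT)));
  const double IbNa = gbNa * (V - ENa);
  const double IbCa = gbCa * (V - ECa);
  const double IpCa = IpCa_max * Cai / (0.0005 + Cai);

  r.Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK + INaCa +
           IbNa + IbCa;
  r.dV = -r.Iion + stim;

  // fast sodium gates (alpha/beta form)
  double am = safe_ratio(0.32 * (V + 47.13),
                         1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  r.tau[1] = 1.0 / (am + bm); r.inf[1] = am / (am + bm);
  r.tau[2] = 1.0 / (ah + bh); r.inf[2] = ah / (ah + bh);
  r.tau[3] = 1.0 / (aj + bj); r.inf[3] = aj / (aj + bj);

  // transient outward / ultrarapid gates
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  r.tau[4] = 1.0 / ((aoa + boa) * KQ10);
  r.inf[4] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  r.tau[5] = 1.0 / ((aoi + boi) * KQ10);
  r.inf[5] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  r.tau[6] = r.tau[4];  // same alpha/beta as oa
  r.inf[6] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  r.tau[7] = 1.0 / ((aui + bui) * KQ10);
  r.inf[7] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));

  // delayed rectifiers
  double axr = safe_ratio(0.0003 * (V + 14.1),
                          1.0 - std::exp(-(V + 14.1) / 5.0), 0.0015);
  double bxr = safe_ratio(7.3898e-5 * (V - 3.3328),
                          std::exp((V - 3.3328) / 5.1237) - 1.0, 3.7863e-4);
  r.tau[8] = 1.0 / (axr + bxr);
  r.inf[8] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  double axs = safe_ratio(4e-5 * (V - 19.9),
                          1.0 - std::exp(-(V - 19.9) / 17.0), 6.8e-4);
  double bxs = safe_ratio(3.5e-5 * (V - 19.9),
                          std::exp((V - 19.9) / 9.0) - 1.0, 3.15e-4);
  r.tau[9] = 0.5 / (axs + bxs);
  r.inf[9] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));

  // L-type calcium gates
  double dx = (V + 10.0) / 6.24;
  double ed = std::exp(-dx);
  r.tau[10] = (std::fabs(V + 10.0) < 1e-10)
      ? 1.0 / (0.035 * 6.24 * 2.0)
      : (1.0 - ed) / (0.035 * (V + 10.0) * (1.0 + ed));
  r.inf[10] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  r.tau[11] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  r.inf[11] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  r.tau[12] = 2.0;
  r.inf[12] = 1.0 / (1.0 + Cai / 0.00035);

  // SR release gates driven by Fn
  const double Irel = krel * s[13] * s[13] * s[14] * s[15] * (Carel - Cai);
  const double ICaL_pA = ICaL * Cmem, INaCa_pA = INaCa * Cmem;
  const double Fn = 1e3 * (1e-15 * Vrel * Irel -
                           (1e-15 / (2.0 * Frdy)) * (0.5 * ICaL_pA - 0.2 * INaCa_pA));
  const double fn_arg1 = (Fn - 3.4175e-13) / 13.67e-16;
  r.tau[13] = 8.0;
  r.inf[13] = 1.0 / (1.0 + std::exp(-fn_arg1));
  r.tau[14] = 1.91 + 2.09 / (1.0 + std::exp(-fn_arg1));
  r.inf[14] = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double ew = std::exp(-(V - 7.9) / 5.0);
  r.tau[15] = (std::fabs(V - 7.9) < 1e-10)
      ? 6.0 * 0.2 / 1.3
      : 6.0 * (1.0 - ew) / ((1.0 + 0.3 * ew) * (V - 7.9));
  r.inf[15] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));

  // calcium handling fluxes (mM/ms)
  const double Itr = (Caup - Carel) / tau_tr;
  const double Iup = Iup_max / (1.0 + Kup / Cai);
  const double Iupleak = Iup_max * Caup / Caup_max;

  const double INa_pA = INa * Cmem, IbNa_pA = IbNa * Cmem, INaK_pA = INaK * Cmem;
  const double IK1_pA = IK1 * Cmem, Ito_pA = Ito * Cmem, IKur_pA = IKur * Cmem;
  const double IKr_pA = IKr * Cmem, IKs_pA = IKs * Cmem;
  const double IbCa_pA = IbCa * Cmem, IpCa_pA = IpCa * Cmem;

  r.dNai = (-3.0 * INaK_pA - 3.0 * INaCa_pA - IbNa_pA - INa_pA) / (Frdy * Vi);
  r.dKi  = (2.0 * INaK_pA - IK1_pA - Ito_pA - IKur_pA - IKr_pA - IKs_pA) / (Frdy * Vi);
  const double B1 = (2.0 * INaCa_pA - IpCa_pA - ICaL_pA - IbCa_pA) / (2.0 * Frdy * Vi) +
                    (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
  const double B2 = 1.0 + Trpn_max * KmTrpn / ((Cai + KmTrpn) * (Cai + KmTrpn)) +
                    Cmdn_max * KmCmdn / ((Cai + KmCmdn) * (Cai + KmCmdn));
  r.dCai = B1 / B2;
  r.dCaup = Iup - Iupleak - Itr * Vrel / Vup;
  r.dCarel = (Itr - Irel) /
             (1.0 + Csqn_max * KmCsqn / ((Carel + KmCsqn) * (Carel + KmCsqn)));
}

// one Rush-Larsen step (gates exponential, V and concentrations explicit)
static inline void crn_step(double* s, double dt, double stim) {
  Rates r;
  crn_rates(s, stim, r);
  s[0] += dt * r.dV;
  for (int g = 1; g <= 15; ++g)
    s[g] = r.inf[g] + (s[g] - r.inf[g]) * std::exp(-dt / r.tau[g]);
  s[16] += dt * r.dNai;
  s[17] += dt * r.dKi;
  s[18] += dt * r.dCai;
  s[19] += dt * r.dCaup;
  s[20] += dt * r.dCarel;
}

// [[Rcpp::export(name = ".crn_initial_state")]]
NumericVector crn_initial_state_cpp() {
  NumericVector s(NSTATE);
  s[0] = -81.18;  s[1] = 2.908e-3; s[2] = 9.649e-1; s[3] = 9.775e-1;
  s[4] = 3.043e-2; s[5] = 9.992e-1; s[6] = 4.966e-3; s[7] = 9.986e-1;
  s[8] = 3.296e-5; s[9] = 1.869e-2; s[10] = 1.367e-4; s[11] = 9.996e-1;
  s[12] = 7.755e-1; s[13] = 0.0;    s[14] = 1.0;      s[15] = 9.992e-1;
  s[16] = 11.17;   s[17] = 139.0;   s[18] = 1.013e-4; s[19] = 1.488;
  s[20] = 1.488;
  s.attr("names") = CharacterVector::create(
      "V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f",
      "fca", "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel");
  return s;
}

// [[Rcpp::export(name = ".crn_rhs")]]
List crn_rhs_cpp(NumericVector state, double stim = 0.0) {
  if (state.size() != NSTATE) stop("crn_rhs: state must have 21 entries");
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i])) stop("crn_rhs: non-finite state");
  Rates r;
  crn_rates(REAL(state), stim, r);
  NumericVector ds(NSTATE);
  ds[0] = r.dV;
  for (int g = 1; g <= 15; ++g) ds[g] = (r.inf[g] - state[g]) / r.tau[g];
  ds[16] = r.dNai; ds[17] = r.dKi; ds[18] = r.dCai;
  ds[19] = r.dCaup; ds[20] = r.dCarel;
  return List::create(_["dstate"] = ds, _["Iion"] = r.Iion);
}

// Single-cell integration with optional periodic stimulation.
// [[Rcpp::export(name = ".crn_integrate")]]
List crn_integrate_cpp(NumericVector init, double t_end, double dt,
                       double bcl = 0.0, double stim_amp = 0.0,
                       double stim_dur = 0.0, double stim_start = 0.0,
                       double record_dt = 1.0) {
  if (init.size() != NSTATE) stop("crn_integrate: state must have 21 entries");
  std::vector<double> s(REAL(init), REAL(init) + NSTATE);
  const int nsteps = (int)std::llround(t_end / dt);
  const int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  std::vector<double> tv, vv;
  std::vector<double> end_prev(NSTATE, NA_REAL);
  long long beats_done = 0;
  for (int k = 0; k < nsteps; ++k) {
    double t = k * dt;
    double stim = 0.0;
    if (bcl > 0.0 && stim_amp != 0.0) {
      // (avoid std::fmod: versioned symbol newer than the runtime glibc)
      double te = t - stim_start;
      double tb = te - bcl * std::floor(te / bcl);
      if (t >= stim_start && tb >= 0.0 && tb < stim_dur) stim = stim_amp;
      // snapshot state at the end of each cycle for convergence metrics
      long long beat = (t >= stim_start) ? (long long)((t - stim_start) / bcl) : -1;
      if (beat > beats_done) {
        beats_done = beat;
        end_prev.assign(s.begin(), s.end());
      }
    }
    if (k % rec_every == 0) { tv.push_back(t); vv.push_back(s[0]); }
    crn_step(s.data(), dt, stim);
    if (!R_finite(s[0]) || std::fabs(s[0]) > 300.0)
      stop("crn_integrate: divergence at t=%f ms (V=%f); reduce dt", t, s[0]);
  }
  NumericVector out(NSTATE);
  std::copy(s.begin(), s.end(), out.begin());
  out.attr("names") = crn_initial_state_cpp().attr("names");
  NumericVector prev(NSTATE);
  std::copy(end_prev.begin(), end_prev.end(), prev.begin());
  return List::create(_["state"] = out, _["t"] = wrap(tv), _["V"] = wrap(vv),
                      _["state_prev_beat"] = prev);
}

// 1-D cable monodomain: implicit (backward Euler) diffusion by the Thomas
// algorithm, Rush-Larsen reaction, lumped-mass Neumann ends.
// D in mm^2/ms, dx in mm, dt in ms; stimulus applied to nodes [0, n_stim).
// Returns per-node LAT (linear interpolation of the -20 mV upward crossing)
// and V traces at probe nodes.
// [[Rcpp::export(name = ".cable_monodomain")]]
List cable_monodomain_cpp(int n, double dx, double D, double dt, double t_end,
                          NumericVector init, int n_stim, double stim_amp,
                          double stim_start, double stim_dur,
                          double lat_threshold, IntegerVector probes,
                          double record_dt = 0.1, bool stim_from_end = false) {
  if (init.size() != NSTATE) stop("cable_monodomain: init must have 21 entries");
  if (n < 3) stop("cable_monodomain: need at least 3 nodes");
  std::vector<double> S((size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) S[(size_t)i * NSTATE + k] = init[k];

  const double a = dt * D / (dx * dx);
  // tridiagonal system (I + dt*L), Neumann ends
  std::vector<double> diag(n), cp(n), dpv(n), Vold(n);
  NumericVector lat(n, NA_REAL);
  const int nsteps = (int)std::llround(t_end / dt);
  const int rec_every = std::max(1, (int)std::llround(record_dt / dt));
  std::vector<std::vector<double>> traces(probes.size());
  std::vector<double> tv;

  for (int k = 0; k < nsteps; ++k) {
    double t = k * dt;
    bool stim_on = (t >= stim_start && t < stim_start + stim_dur);
    if (k % rec_every == 0) {
      tv.push_back(t);
      for (int p = 0; p < probes.size(); ++p)
        traces[p].push_back(S[(size_t)probes[p] * NSTATE]);
    }
    for (int i = 0; i < n; ++i) Vold[i] = S[(size_t)i * NSTATE];
    // reaction
    for (int i = 0; i < n; ++i) {
      bool in_stim = stim_from_end ? (i >= n - n_stim) : (i < n_stim);
      double stim = (stim_on && in_stim) ? stim_amp : 0.0;
      crn_step(&S[(size_t)i * NSTATE], dt, stim);
      if (!R_finite(S[(size_t)i * NSTATE]) || std::fabs(S[(size_t)i * NSTATE]) > 300.0)
        stop("cable_monodomain: divergence at t=%f ms node %d; reduce dt", t, i);
    }
    // implicit diffusion on V
    for (int i = 0; i < n; ++i) {
      diag[i] = (i == 0 || i == n - 1) ? 1.0 + a : 1.0 + 2.0 * a;
      dpv[i] = S[(size_t)i * NSTATE];
    }
    cp[0] = -a / diag[0];
    dpv[0] = dpv[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      double mlt = diag[i] - (-a) * cp[i - 1];
      cp[i] = -a / mlt;
      dpv[i] = (dpv[i] - (-a) * dpv[i - 1]) / mlt;
    }
    for (int i = n - 2; i >= 0; --i) dpv[i] -= cp[i] * dpv[i + 1];
    for (int i = 0; i < n; ++i) S[(size_t)i * NSTATE] = dpv[i];
    // LAT: first upward crossing over the full step
    for (int i = 0; i < n; ++i) {
      double Vn = S[(size_t)i * NSTATE];
      if (R_IsNA(lat[i]) && Vold[i] < lat_threshold && Vn >= lat_threshold)
        lat[i] = t + dt * (lat_threshold - Vold[i]) / (Vn - Vold[i]);
    }
  }
  NumericMatrix tr(tv.size(), probes.size());
  for (int p = 0; p < probes.size(); ++p)
    for (size_t q = 0; q < tv.size(); ++q) tr(q, p) = traces[p][q];
  NumericMatrix states(n, NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k2 = 0; k2 < NSTATE; ++k2) states(i, k2) = S[(size_t)i * NSTATE + k2];
  return List::create(_["lat"] = lat, _["t"] = wrap(tv), _["traces"] = tr,
                      _["states"] = states);
}

// One operator-splitting reaction step for a mesh simulation: advances every
// row of `states` (n x 21) by dt with per-node stimulus rates (pA/pF).
// Modifies `states` in place and returns it.
// [[Rcpp::export(name = ".crn_react_step")]]
NumericMatrix crn_react_step_cpp(NumericMatrix states, double dt,
                                 NumericVector stim) {
  const int n = states.nrow();
  if (states.ncol() != NSTATE) stop("crn_react_step: states must have 21 columns");
  if (stim.size() != n) stop("crn_react_step: stim length mismatch");
  std::vector<double> s(NSTATE);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < NSTATE; ++k) s[k] = states(i, k);
    crn_step(s.data(), dt, stim[i]);
    if (!R_finite(s[0]) || std::fabs(s[0]) > 300.0)
      stop("crn_react_step: divergence at node %d (V=%f); reduce dt", i + 1, s[0]);
    for (int k = 0; k < NSTATE; ++k) states(i, k) = s[k];
  }
  return states;
}

// Minimum Euclidean distance from each query point to a reference point set.
// [[Rcpp::export(name = ".nn_min_dist")]]
NumericVector nn_min_dist_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (query.ncol() != 3 || ref.ncol() != 3) stop("nn_min_dist: points must be n x 3");
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Index (1-based) of the nearest reference point for each query point;
// ties broken toward the lowest index.
// [[Rcpp::export(name = ".nn_index")]]
IntegerVector nn_index_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (query.ncol() != 3 || ref.ncol() != 3) stop("nn_index: points must be n x 3");
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf; int bj = 1;
    for (int j = 0; j < nr; ++j) {
      double dx = query(i, 0) - ref(j, 0), dy = query(i, 1) - ref(j, 1),
             dz = query(i, 2) - ref(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best - 1e-300 || (d2 < best)) { best = d2; bj = j + 1; }
    }
    out[i] = bj;
  }
  return out;
}
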