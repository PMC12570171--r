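// Monodomain tissue stepper with the Courtemanche-Ramirez-Nattel (CRN)
// human atrial ionic model.  Operator splitting: Rush-Larsen for gating
// variables, forward Euler for concentrations and Vm, explicit anisotropic
// finite-difference diffusion with no-flux boundaries (absent edges).
// Voltage-dependent rate expressions are tabulated per time step (lookup
// tables over V in [-100, 70] mV) for speed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NSTATE = 21;
// state order: V m h j oa oi ua ui xr xs d f fCa u v w Nai Ki Cai Caup Carel
enum { iV, im, ih, ij, ioa, ioi, iua, iui, ixr, ixs, id_, if_, ifCa,
       iu, iv, iw, iNai, iKi, iCai, iCaup, iCarel };

struct CrnConst {
  double R = 8.3143, T = 310.0, F = 96.4867, Cm = 100.0;
  double Vi = 13668.0, Vup = 1109.52, Vrel = 96.48;
  double Ko = 5.4, Nao = 140.0, Cao = 1.8;
  double gNa = 7.8, gK1 = 0.09, gto = 0.1652, gKr = 0.029411765;
  double gKs = 0.12941176, gCaL = 0.12375, gbCa = 0.001131,
         gbNa = 0.0006744375;
  double INaK_max = 0.59933874, KmNai = 10.0, KmKo = 1.5;
  double IpCa_max = 0.275;
  double INaCa_max = 1600.0, KmNa = 87.5, KmCa = 1.38, ksat = 0.1,
         gam = 0.35;
  double krel = 30.0, Iup_max = 0.005, Kup = 0.00092, Caup_max = 15.0,
         tau_tr = 180.0;
  double Cmdn_max = 0.05, Trpn_max = 0.07, Csqn_max = 10.0;
  double KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8;
  double KQ10 = 3.0;
  // remodeling multipliers
  double f_gto = 1.0, f_gCaL = 1.0, f_gK1 = 1.0;
};

static inline double sdiv(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

// per-dt lookup tables over voltage
struct CrnLut {
  static const int N = 8501;       // -100 .. 70 mV, step 0.02
  double vmin = -100.0, step = 0.02;
  // 12 voltage gates: steady state and Rush-Larsen factor exp(-dt/tau)
  std::vector<double> inf[12], rl[12];
  std::vector<double> gkur, k1d, krd, fnak, e1, e2; // V-dependent factors
  double rl_fca;                                    // exp(-dt/2)
  double rl_u;                                      // exp(-dt/8)
  CrnConst c;

  void build(const CrnConst& cc, double dt) {
    c = cc;
    double RTF = c.R * c.T / c.F;
    for (int g = 0; g < 12; ++g) { inf[g].resize(N); rl[g].resize(N); }
    gkur.resize(N); k1d.resize(N); krd.resize(N); fnak.resize(N);
    e1.resize(N); e2.resize(N);
    rl_fca = std::exp(-dt / 2.0);
    rl_u = std::exp(-dt / 8.0);
    double sig = (std::exp(c.Nao / 67.3) - 1.0) / 7.0;
    for (int k = 0; k < N; ++k) {
      double V = vmin + k * step;
      double a, b, tau, infv;
      // m
      a = sdiv(0.32 * (V + 47.13), 1.0 - std::exp(-0.1 * (V + 47.13)), 3.2);
      b = 0.08 * std::exp(-V / 11.0);
      tau = 1.0 / (a + b); infv = a * tau;
      inf[0][k] = infv; rl[0][k] = std::exp(-dt / tau);
      // h, j
      double ah, bh, aj, bj;
      if (V >= -40.0) {
        ah = 0.0;
        bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
        aj = 0.0;
        bj = 0.3 * std::exp(-2.535e-7 * V) /
             (1.0 + std::exp(-0.1 * (V + 32.0)));
      } else {
        ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
        bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
        aj = (-1.2714e5 * std::exp(0.2444 * V) -
              3.474e-5 * std::exp(-0.04391 * V)) * (V + 37.78) /
             (1.0 + std::exp(0.311 * (V + 79.23)));
        bj = 0.1212 * std::exp(-0.01052 * V) /
             (1.0 + std::exp(-0.1378 * (V + 40.14)));
      }
      tau = 1.0 / (ah + bh); inf[1][k] = ah * tau;
      rl[1][k] = std::exp(-dt / tau);
      tau = 1.0 / (aj + bj); inf[2][k] = aj * tau;
      rl[2][k] = std::exp(-dt / tau);
      // oa
      a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
      b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
      tau = 1.0 / ((a + b) * c.KQ10);
      inf[3][k] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
      rl[3][k] = std::exp(-dt / tau);
      // oi
      a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
      b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
      tau = 1.0 / ((a + b) * c.KQ10);
      inf[4][k] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
      rl[4][k] = std::exp(-dt / tau);
      // ua
      a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
      b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
      tau = 1.0 / ((a + b) * c.KQ10);
      inf[5][k] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
      rl[5][k] = std::exp(-dt / tau);
      // ui
      a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
      b = std::exp((V - 158.0) / 16.0);
      tau = 1.0 / ((a + b) * c.KQ10);
      inf[6][k] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
      rl[6][k] = std::exp(-dt / tau);
      // xr
      a = sdiv(0.0003 * (V + 14.1), 1.0 - std::exp(-(V + 14.1) / 5.0),
               0.0015);
      b = sdiv(7.3898e-5 * (V - 3.3328),
               std::exp((V - 3.3328) / 5.1237) - 1.0, 3.7862e-4);
      tau = 1.0 / (a + b);
      inf[7][k] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
      rl[7][k] = std::exp(-dt / tau);
      // xs
      a = sdiv(4e-5 * (V - 19.9), 1.0 - std::exp(-(V - 19.9) / 17.0),
               6.8e-4);
      b = sdiv(3.5e-5 * (V - 19.9), std::exp((V - 19.9) / 9.0) - 1.0,
               3.15e-4);
      tau = 0.5 / (a + b);
      inf[8][k] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
      rl[8][k] = std::exp(-dt / tau);
      // d
      tau = sdiv(1.0 - std::exp(-(V + 10.0) / 6.24),
                 0.035 * (V + 10.0) * (1.0 + std::exp(-(V + 10.0) / 6.24)),
                 1.0 / (0.035 * 6.24 * 2.0));
      inf[9][k] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
      rl[9][k] = std::exp(-dt / tau);
      // f
      tau = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) *
                                     (V + 10.0)) + 0.02);
      inf[10][k] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
      rl[10][k] = std::exp(-dt / tau);
      // w
      tau = sdiv(6.0 * (1.0 - std::exp(-(V - 7.9) / 5.0)),
                 (1.0 + 0.3 * std::exp(-(V - 7.9) / 5.0)) * (V - 7.9),
                 (6.0 / 5.0) / 1.3);
      inf[11][k] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
      rl[11][k] = std::exp(-dt / tau);
      // current factors
      gkur[k] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
      k1d[k] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
      krd[k] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
      fnak[k] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                       0.0365 * sig * std::exp(-V / RTF));
      e1[k] = std::exp(c.gam * V / RTF);
      e2[k] = std::exp((c.gam - 1.0) * V / RTF);
    }
  }
  inline int idx(double V) const {
    int k = (int)((V - vmin) / step + 0.5);
    if (k < 0) k = 0;
    if (k >= N) k = N - 1;
    return k;
  }
};

// advance one cell by dt; s points at its 21 states; returns -dV ionic part
// aux cache per node: ENa, EK, ECa, INaK Nai-saturation, Nai^3 -- these
// depend only on slowly varying concentrations and are refreshed
// periodically rather than every step
static const int NAUX = 5;
static inline void refresh_aux(const double* s, const CrnConst& c,
                               double* a) {
  double RTF = c.R * c.T / c.F;
  a[0] = RTF * std::log(c.Nao / s[iNai]);
  a[1] = RTF * std::log(c.Ko / s[iKi]);
  a[2] = 0.5 * RTF * std::log(c.Cao / s[iCai]);
  a[3] = 1.0 / (1.0 + std::pow(c.KmNai / s[iNai], 1.5));
  a[4] = s[iNai] * s[iNai] * s[iNai];
}

static inline void cell_step(double* s, const CrnLut& L, double dt,
                             double gna_factor, double istim,
                             double lap_term, double* aux, bool refresh) {
  const CrnConst& c = L.c;
  double V = s[iV];
  int k = L.idx(V);

  if (refresh) refresh_aux(s, c, aux);
  double ENa = aux[0];
  double EK = aux[1];
  double ECa = aux[2];

  double INa = c.gNa * gna_factor * s[im] * s[im] * s[im] * s[ih] * s[ij] *
               (V - ENa);
  double IK1 = c.gK1 * c.f_gK1 * (V - EK) * L.k1d[k];
  double Ito = c.gto * c.f_gto * s[ioa] * s[ioa] * s[ioa] * s[ioi] * (V - EK);
  double IKur = L.gkur[k] * s[iua] * s[iua] * s[iua] * s[iui] * (V - EK);
  double IKr = c.gKr * s[ixr] * (V - EK) * L.krd[k];
  double IKs = c.gKs * s[ixs] * s[ixs] * (V - EK);
  double ICaL = c.gCaL * c.f_gCaL * s[id_] * s[if_] * s[ifCa] * (V - 65.0);
  double INaK = c.INaK_max * L.fnak[k] * aux[3] * c.Ko / (c.Ko + c.KmKo);
  double nai3 = aux[4];
  double INaCa = c.INaCa_max *
                 (L.e1[k] * nai3 * c.Cao - L.e2[k] * c.Nao * c.Nao * c.Nao *
                  s[iCai]) /
                 ((c.KmNa * c.KmNa * c.KmNa + c.Nao * c.Nao * c.Nao) *
                  (c.KmCa + c.Cao) * (1.0 + c.ksat * L.e2[k]));
  double IbNa = c.gbNa * (V - ENa);
  double IbCa = c.gbCa * (V - ECa);
  double IpCa = c.IpCa_max * s[iCai] / (0.0005 + s[iCai]);

  double Irel = c.krel * s[iu] * s[iu] * s[iv] * s[iw] *
                (s[iCarel] - s[iCai]);
  double Iup = c.Iup_max / (1.0 + c.Kup / s[iCai]);
  double Iup_leak = c.Iup_max * s[iCaup] / c.Caup_max;
  double Itr = (s[iCaup] - s[iCarel]) / c.tau_tr;

  // Fn and Ca-release gates (currents in pA)
  double Fn = 1e-12 * c.Vrel * Irel -
              (5e-13 / c.F) * (0.5 * ICaL * c.Cm - 0.2 * INaCa * c.Cm);
  double ex = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
  double u_inf = 1.0 / (1.0 + ex);
  double tau_v = 1.91 + 2.09 / (1.0 + ex);
  double v_inf = 1.0 -
      1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));

  // concentrations (forward Euler)
  double CmF = c.Cm / (c.F * c.Vi);
  double dNai = (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * CmF;
  double dKi = (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * CmF;
  double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * CmF * 0.5 +
              (c.Vup * (Iup_leak - Iup) + Irel * c.Vrel) / c.Vi;
  double trp = s[iCai] + c.KmTrpn, cmd = s[iCai] + c.KmCmdn;
  double B2 = 1.0 + c.Trpn_max * c.KmTrpn / (trp * trp) +
              c.Cmdn_max * c.KmCmdn / (cmd * cmd);
  double dCaup = Iup - Iup_leak - Itr * c.Vrel / c.Vup;
  double csq = s[iCarel] + c.KmCsqn;
  double dCarel = (Itr - Irel) /
                  (1.0 + c.Csqn_max * c.KmCsqn / (csq * csq));

  double iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK +
                INaCa + IbNa + IbCa;

  // Rush-Larsen gate updates
  for (int g = 0; g < 12; ++g) {
    int si = g + 1;   // m..f occupy 1..11, w is 15
    if (g == 11) si = iw;
    s[si] = L.inf[g][k] + (s[si] - L.inf[g][k]) * L.rl[g][k];
  }
  double fCa_inf = 1.0 / (1.0 + s[iCai] / 0.00035);
  s[ifCa] = fCa_inf + (s[ifCa] - fCa_inf) * L.rl_fca;
  s[iu] = u_inf + (s[iu] - u_inf) * L.rl_u;
  s[iv] = v_inf + (s[iv] - v_inf) * std::exp(-dt / tau_v);

  s[iNai] += dt * dNai;
  s[iKi] += dt * dKi;
  s[iCai] += dt * B1 / B2;
  if (s[iCai] < 1e-10) s[iCai] = 1e-10;
  s[iCaup] += dt * dCaup;
  s[iCarel] += dt * dCarel;
  s[iV] = V + dt * (-iion + istim + lap_term);
}

static void fill_const(CrnConst& c, List ion) {
  c.f_gto = as<double>(ion["f_gto"]);
  c.f_gCaL = as<double>(ion["f_gCaL"]);
  c.f_gK1 = as<double>(ion["f_gK1"]);
}

// [[Rcpp::export]]
List crn_cell_cpp(NumericVector state0, List ion, double gna_factor,
                  double dt, double duration_ms, NumericVector stim_times,
                  double stim_dur, double stim_amp, double record_every_ms) {
  CrnConst c; fill_const(c, ion);
  CrnLut L; L.build(c, dt);
  std::vector<double> s(state0.begin(), state0.end());
  double aux[NAUX];
  refresh_aux(s.data(), c, aux);
  int n_steps = (int)std::round(duration_ms / dt);
  int rec_every = std::max(1, (int)std::round(record_every_ms / dt));
  std::vector<double> vm, tms;
  vm.reserve(n_steps / rec_every + 2);
  size_t si = 0;
  for (int st = 0; st < n_steps; ++st) {
    double t = st * dt;
    double istim = 0.0;
    while (si < (size_t)stim_times.size() &&
           t >= stim_times[si] + stim_dur) ++si;
    if (si < (size_t)stim_times.size() && t >= stim_times[si] &&
        t < stim_times[si] + stim_dur)
      istim = stim_amp;
    if (st % rec_every == 0) { vm.push_back(s[iV]); tms.push_back(t); }
    cell_step(s.data(), L, dt, gna_factor, istim, 0.0, aux, st % 10 == 0);
    if (!std::isfinite(s[iV]))
      stop("non-finite Vm at t = %f ms", t);
  }
  vm.push_back(s[iV]); tms.push_back(n_steps * dt);
  return List::create(_["vm"] = wrap(vm), _["t"] = wrap(tms),
                      _["state"] = wrap(s));
}

// connected components of suprathreshold nodes, 4-neighbor grid
static int count_waves_grid(const std::vector<double>& V, int nx, int ny,
                            double thr, std::vector<int>& label,
                            std::vector<int>& stack) {
  int n = nx * ny;
  label.assign(n, 0);
  int ncomp = 0;
  for (int i = 0; i < n; ++i) {
    if (V[i] <= thr || label[i]) continue;
    ++ncomp;
    stack.clear();
    stack.push_back(i);
    label[i] = ncomp;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int x = p % nx, y = p / nx;
      int nb[4] = {x > 0 ? p - 1 : -1, x < nx - 1 ? p + 1 : -1,
                   y > 0 ? p - nx : -1, y < ny - 1 ? p + nx : -1};
      for (int q : nb) {
        if (q >= 0 && !label[q] && V[q] > thr) {
          label[q] = ncomp;
          stack.push_back(q);
        }
      }
    }
  }
  return ncomp;
}

// [[Rcpp::export]]
IntegerVector count_waves_cpp(NumericVector vm, int nx, int ny,
                              double threshold) {
  std::vector<double> V(vm.begin(), vm.end());
  std::vector<int> lab, stk;
  int n = count_waves_grid(V, nx, ny, threshold, lab, stk);
  return IntegerVector::create(n);
}

// Full tissue run: burst pacing at one site, per-ms wave counts.
// wx: (nx-1) x ny edge weights (1/ms), wy: nx x (ny-1); row-major node
// index p = y*nx + x.
// [[Rcpp::export]]
List tissue_run_cpp(NumericMatrix state0, List ion, NumericVector gna_factor,
                    int nx, int ny, NumericVector wx, NumericVector wy,
                    double dt, double duration_ms,
                    IntegerVector stim_nodes, NumericVector stim_times,
                    double stim_dur, double stim_amp,
                    double wave_threshold, double snapshot_every_ms,
                    bool early_stop) {
  int n = nx * ny;
  if (state0.nrow() != NSTATE || state0.ncol() != n)
    stop("state0 must be 21 x (nx*ny)");
  CrnConst c; fill_const(c, ion);
  CrnLut L; L.build(c, dt);
  std::vector<double> S(state0.begin(), state0.end()); // col-major: node*21
  std::vector<double> V(n), lap(n);
  std::vector<double> aux(n * NAUX);
  for (int i = 0; i < n; ++i) refresh_aux(&S[i * NSTATE], c, &aux[i * NAUX]);
  std::vector<char> is_stim(n, 0);
  for (int i = 0; i < stim_nodes.size(); ++i) is_stim[stim_nodes[i]] = 1;

  int n_steps = (int)std::round(duration_ms / dt);
  int steps_per_ms = std::max(1, (int)std::round(1.0 / dt));
  int n_ms = n_steps / steps_per_ms;
  std::vector<int> wave_counts(n_ms, 0);
  std::vector<int> lab, stk;
  double last_stim_end = 0.0;
  for (int i = 0; i < stim_times.size(); ++i)
    last_stim_end = std::max(last_stim_end, stim_times[i] + stim_dur);

  int snap_every = snapshot_every_ms > 0
                       ? (int)std::round(snapshot_every_ms / dt) : 0;
  std::vector<std::vector<double> > snaps;
  std::vector<double> snap_t;

  size_t si = 0;
  int quiet_ms = 0;
  bool stopped = false;
  int ms_done = 0;
  for (int st = 0; st < n_steps; ++st) {
    double t = st * dt;
    // per-ms bookkeeping
    if (st % steps_per_ms == 0) {
      int m = st / steps_per_ms;
      if (m < n_ms) {
        for (int i = 0; i < n; ++i) V[i] = S[i * NSTATE + iV];
        wave_counts[m] = count_waves_grid(V, nx, ny, wave_threshold, lab,
                                          stk);
        ms_done = m + 1;
        if (early_stop && t > last_stim_end) {
          if (wave_counts[m] == 0) {
            if (++quiet_ms >= 3) { stopped = true; break; }
          } else quiet_ms = 0;
        }
      }
    }
    if (snap_every > 0 && st % snap_every == 0) {
      std::vector<double> fr(n);
      for (int i = 0; i < n; ++i) fr[i] = S[i * NSTATE + iV];
      snaps.push_back(fr);
      snap_t.push_back(t);
    }
    // stimulus window
    double istim_now = 0.0;
    while (si < (size_t)stim_times.size() &&
           t >= stim_times[si] + stim_dur) ++si;
    bool stim_on = si < (size_t)stim_times.size() &&
                   t >= stim_times[si] && t < stim_times[si] + stim_dur;
    // diffusion term from current V
    for (int i = 0; i < n; ++i) {
      V[i] = S[i * NSTATE + iV];
      lap[i] = 0.0;
    }
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx - 1; ++x) {
        double w = wx[y * (nx - 1) + x];
        if (w == 0.0) continue;
        int p = y * nx + x;
        double d = w * (V[p + 1] - V[p]);
        lap[p] += d;
        lap[p + 1] -= d;
      }
    }
    for (int y = 0; y < ny - 1; ++y) {
      for (int x = 0; x < nx; ++x) {
        double w = wy[y * nx + x];
        if (w == 0.0) continue;
        int p = y * nx + x;
        double d = w * (V[p + nx] - V[p]);
        lap[p] += d;
        lap[p + nx] -= d;
      }
    }
    bool refresh = st % 10 == 0;
    for (int i = 0; i < n; ++i) {
      double istim = (stim_on && is_stim[i]) ? stim_amp : 0.0;
      cell_step(&S[i * NSTATE], L, dt, gna_factor[i], istim, lap[i],
                &aux[i * NAUX], refresh);
    }
    if (st % (steps_per_ms * 25) == 0) {
      if (!std::isfinite(S[iV]))
        stop("non-finite Vm at t = %f ms", t);
      Rcpp::checkUserInterrupt();
    }
  }
  // remaining ms after an early stop are quiescent (count 0): already 0
  NumericMatrix state_out(NSTATE, n);
  std::copy(S.begin(), S.end(), state_out.begin());
  List snap_list(snaps.size());
  for (size_t k = 0; k < snaps.size(); ++k) snap_list[k] = wrap(snaps[k]);
  return List::create(_["wave_counts"] = wrap(wave_counts),
                      _["state"] = state_out,
                      _["stopped_early"] = stopped,
                      _["ms_done"] = ms_done,
                      _["snapshots"] = snap_list,
                      _["snapshot_t"] = wrap(snap_t));
}
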