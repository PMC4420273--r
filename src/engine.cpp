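// Compartmental network integrator for olfactory-bulb cell and circuit models.
//
// Design:
//  * SI units throughout (V, s, S, F, m, A); calcium in mM.
//  * Voltage tree solved implicitly per time step (theta method, default
//    backward Euler) with Hines elimination; compartments are ordered so a
//    parent always precedes its children, which makes the elimination a
//    single reverse sweep plus a forward back-substitution.
//  * Gating variables advance by exponential Euler on their own (inf, tau)
//    evaluated from per-channel lookup tables built at setup.
//  * Synapses are "receptor pools": one dual-exponential conductance state
//    per (compartment, kinetics, reversal); events deposit weights into the
//    pool, which is exact under linear superposition of conductances.
//  * Spikes are upward crossings of a threshold (default 0 mV) at the soma
//    with a 1 ms refractory; each spike schedules the cell's outgoing
//    connection events through a delay ring buffer.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Channel kinetics.  Voltages in volts here; rates in 1/s, tau in s.
// Types (keep in sync with R's channel registry):
//   0 NA_MIT   m^3 h   mitral Na of the parent model family (re-derived)
//   1 K2      m^2 h   slow delayed rectifier (re-derived)
//   2 K_FAST  n^2     fast K (re-derived)
//   3 LCA3    s       L-type Ca (re-derived), feeds Ca pool
//   4 KA_BSG  m h     A-type K, mitral/PG (re-derived)
//   5 KCA     m x Ca/(Ca+Kd)  Ca-and-voltage dependent K
//   6 NA_IS   m^3 h   mitral initial-segment Na (printed trap kinetics)
//   7 NA_RAT  m^3 h   granule/PG Na (printed trap kinetics)
//   8 KA_MS   m h     granule A-type (printed)
//   9 TCA_D   m^2 h   PG low-threshold Ca (printed), feeds Ca pool
//  10 IH_CB   l       PG hyperpolarization-activated cation (printed)

static const double TEMP_C = 35.0;
static const double Q10_TRAP = std::pow(2.0, (TEMP_C - 24.0) / 10.0);
static const double PHI3 = std::pow(3.0, (TEMP_C - 24.0) / 10.0);
static const double PHI5 = std::pow(5.0, (TEMP_C - 24.0) / 10.0);
static const double PHI45 = std::pow(4.5, (TEMP_C - 30.0) / 10.0);

// trap(V, th, a, q): a*(V-th)/(1-exp(-(V-th)/q)) * 2^((T-24)/10), with the
// analytic limit a*q*Q10 within 1 uV of the singularity.  V, th, q in volts;
// a in s^-1 V^-1.
static inline double trapf(double v, double th, double a, double q) {
  double x = v - th;
  if (std::fabs(x) <= 1e-6) return a * q * Q10_TRAP;
  return a * x / (1.0 - std::exp(-x / q)) * Q10_TRAP;
}

struct InfTau { double inf; double tau; };

// number of gates per channel type and gate exponents
static int chan_ngates(int type) {
  switch (type) {
    case 2: case 3: case 5: case 10: return 1;
    default: return 2;
  }
}
static void chan_powers(int type, int* p) {
  p[0] = 1; p[1] = 1;
  switch (type) {
    case 0: case 6: case 7: p[0] = 3; p[1] = 1; break;  // m^3 h
    case 1: p[0] = 2; p[1] = 1; break;                   // m^2 h
    case 2: p[0] = 2; break;                             // n^2
    case 9: p[0] = 2; p[1] = 1; break;                   // m^2 h
    default: break;
  }
}

static InfTau gate_kinetics(int type, int gate, double v) {
  InfTau r; r.inf = 0.0; r.tau = 1e-3;
  const double mV = 1e-3;
  switch (type) {
  case 0: { // NA_MIT (re-derived Traub-style; higher-threshold than the
            // initial-segment channel so spike initiation favours the IS)
    if (gate == 0) {
      double a = trapf(v, -25.0 * mV, 3.2e5, 4.0 * mV);
      double b = trapf(-v, -2.0 * mV, 2.8e5, 5.0 * mV);
      r.tau = std::max(1.0 / (a + b), 0.02e-3);
      r.inf = a / (a + b);
    } else {
      double a = 128.0 * std::exp(-(v + 21.0 * mV) / (18.0 * mV)) * Q10_TRAP;
      double b = 4000.0 / (1.0 + std::exp(-(v + 2.0 * mV) / (5.0 * mV))) * Q10_TRAP;
      r.tau = std::max(1.0 / (a + b), 0.5e-3);
      r.inf = a / (a + b);
    }
    break;
  }
  case 1: { // K2 slow delayed rectifier with slow inactivation (re-derived)
    if (gate == 0) {
      double a = trapf(v, -35.0 * mV, 2.0e4, 5.0 * mV);
      double b = 250.0 * std::exp(-(v + 20.0 * mV) / (40.0 * mV)) * Q10_TRAP;
      r.tau = std::max(1.0 / (a + b), 1e-3);
      r.inf = a / (a + b);
    } else {
      r.inf = 1.0 / (1.0 + std::exp((v + 58.0 * mV) / (10.6 * mV)));
      r.tau = 0.6;
    }
    break;
  }
  case 2: { // K_FAST n^2 (re-derived)
    r.inf = 1.0 / (1.0 + std::exp(-(v + 28.0 * mV) / (9.0 * mV)));
    double z = (v + 28.0 * mV) / (40.0 * mV);
    r.tau = 1e-3 + 4e-3 * std::exp(-z * z);
    break;
  }
  case 3: { // LCA3 L-type Ca activation (re-derived)
    r.inf = 1.0 / (1.0 + std::exp(-(v + 10.0 * mV) / (7.0 * mV)));
    double z = (v + 10.0 * mV) / (30.0 * mV);
    r.tau = 2e-3 + 5e-3 * std::exp(-z * z);
    break;
  }
  case 4: { // KA_BSG A-type (re-derived)
    if (gate == 0) {
      r.inf = 1.0 / (1.0 + std::exp(-(v + 42.0 * mV) / (13.0 * mV)));
      r.tau = 1.4e-3;
    } else {
      r.inf = 1.0 / (1.0 + std::exp((v + 110.0 * mV) / (18.0 * mV)));
      r.tau = 50e-3;
    }
    break;
  }
  case 5: { // KCA voltage part (Ca factor applied separately)
    r.inf = 1.0 / (1.0 + std::exp(-(v + 15.0 * mV) / (10.0 * mV)));
    r.tau = 5e-3;
    break;
  }
  case 6: { // NA_IS, printed trap kinetics
    if (gate == 0) {
      double a = trapf(v, -30.0 * mV, 4.0e5, 7.2 * mV);
      double b = trapf(-v, 30.0 * mV, 1.24e5, 7.2 * mV);
      r.tau = std::max(1.0 / (a + b), 0.02e-3);
      r.inf = a / (a + b);
    } else {
      double a = trapf(v, -45.0 * mV, 3.0e4, 1.5 * mV);
      double b = trapf(-v, 45.0 * mV, 1.0e4, 1.5 * mV);
      r.tau = std::max(1.0 / (a + b), 0.5e-3);
      r.inf = 1.0 / (1.0 + std::exp((v + 50.0 * mV) / (4.0 * mV)));
    }
    break;
  }
  case 7: { // NA_RAT, printed trap kinetics
    if (gate == 0) {
      double a = trapf(v, -15.0 * mV, 4.0e5, 7.2 * mV);
      double b = trapf(-v, 15.0 * mV, 1.24e5, 7.2 * mV);
      r.tau = std::max(1.0 / (a + b), 0.02e-3);
      r.inf = a / (a + b);
    } else {
      double a = trapf(v, -30.0 * mV, 3.0e4, 1.5 * mV);
      double b = trapf(-v, 30.0 * mV, 1.0e4, 1.5 * mV);
      r.tau = std::max(1.0 / (a + b), 0.5e-3);
      r.inf = 1.0 / (1.0 + std::exp((v + 35.0 * mV) / (4.0 * mV)));
    }
    break;
  }
  case 8: { // KA_MS, printed
    if (gate == 0) {
      r.inf = 1.0 / (1.0 + std::exp(-(v - 17.5 * mV) / (14.0 * mV)));
      double x = (v + 45.0 * mV) / (10.0 * mV);
      r.tau = std::exp(0.75 * x) / (PHI3 * 0.04e3 * (1.0 + std::exp(x)));
    } else {
      r.inf = 1.0 / (1.0 + std::exp((v + 41.3 * mV) / (6.0 * mV)));
      double x = (v + 70.0 * mV) / (5.0 * mV);
      r.tau = std::exp(0.99 * x) / (PHI3 * 0.018e3 * (1.0 + std::exp(x)));
    }
    break;
  }
  case 9: { // TCA_D, printed
    if (gate == 0) {
      r.inf = 1.0 / (1.0 + std::exp(-(v + 50.0 * mV) / (7.4 * mV)));
      r.tau = (3e-3 + 1e-3 / (std::exp((v + 25.0 * mV) / (10.0 * mV)) +
                              std::exp(-(v + 100.0 * mV) / (15.0 * mV)))) / PHI5;
    } else {
      r.inf = 1.0 / (1.0 + std::exp((v + 78.0 * mV) / (5.0 * mV)));
      r.tau = (85e-3 + 1e-3 / (std::exp((v + 46.0 * mV) / (4.0 * mV)) +
                               std::exp(-(v + 405.0 * mV) / (50.0 * mV)))) / PHI3;
    }
    break;
  }
  case 10: { // IH_CB, printed
    r.inf = 1.0 / (1.0 + std::exp((v + 80.0 * mV) / (10.0 * mV)));
    // rate expression is in 1/s, so tau comes out in seconds
    double num = std::exp((v + 65.0 * mV) / (23.529411765 * mV));
    double den = 0.85 * (1.0 + std::exp((v + 65.0 * mV) / (11.764705882 * mV)));
    r.tau = (num / den) / PHI45;
    break;
  }
  default:
    stop("unknown channel type %d", type);
  }
  if (r.tau < 1e-6) r.tau = 1e-6;
  return r;
}

// [[Rcpp::export(name = ".engine_gate_table")]]
List engine_gate_table(int type, NumericVector v_volts) {
  int ng = chan_ngates(type);
  List out(ng);
  for (int g = 0; g < ng; ++g) {
    NumericVector inf(v_volts.size()), tau(v_volts.size());
    for (int i = 0; i < v_volts.size(); ++i) {
      InfTau r = gate_kinetics(type, g, v_volts[i]);
      inf[i] = r.inf; tau[i] = r.tau;
    }
    out[g] = List::create(_["inf"] = inf, _["tau"] = tau);
  }
  return out;
}

// Jahr-Stevens magnesium block, [Mg] in mM, V in volts.
static inline double mg_block(double v, double mg_mM) {
  return 1.0 / (1.0 + (mg_mM / 3.57) * std::exp(-0.062 * v * 1e3));
}

// [[Rcpp::export(name = ".engine_mg_block")]]
NumericVector engine_mg_block(NumericVector v_volts, double mg_mM) {
  NumericVector out(v_volts.size());
  for (int i = 0; i < v_volts.size(); ++i) out[i] = mg_block(v_volts[i], mg_mM);
  return out;
}

// ---------------------------------------------------------------------------
// Lookup tables for gate kinetics (GENESIS-style tabchannels).

static const double TAB_VMIN = -0.150, TAB_VMAX = 0.100;
static const int TAB_N = 2501; // 0.1 mV resolution

// ---------------------------------------------------------------------------
// The simulator.

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List net, List stim, double duration, double dt,
                IntegerVector record, double rec_dt,
                double spike_thresh, double refractory,
                bool debug_gates, double theta) {
  // --- unpack network ------------------------------------------------------
  IntegerVector parent = net["parent"], cell = net["cell"];
  NumericVector Lc = net["L"], Dc = net["d"], Cm = net["Cm"], Rm = net["Rm"],
                Ra = net["Ra"], Em = net["Em"];
  IntegerVector soma_comp = net["soma_comp"];
  IntegerVector chan_comp = net["chan_comp"], chan_type = net["chan_type"];
  NumericVector chan_gbar = net["chan_gbar"], chan_E = net["chan_E"],
                chan_kd = net["chan_kd"];
  IntegerVector pool_comp = net["pool_comp"];
  NumericVector pool_tau = net["pool_tau"], pool_base = net["pool_base"],
                pool_B = net["pool_B"];
  IntegerVector syn_comp = net["syn_comp"];
  NumericVector syn_taur = net["syn_taur"], syn_taud = net["syn_taud"],
                syn_E = net["syn_E"];
  IntegerVector syn_nmda = net["syn_nmda"];
  IntegerVector conn_src = net["conn_src_cell"], conn_pool = net["conn_pool"];
  NumericVector conn_w = net["conn_w"], conn_delay = net["conn_delay"];
  int n_cells = as<int>(net["n_cells"]);
  double mg_mM = net.containsElementNamed("mg_mM") ? as<double>(net["mg_mM"]) : 1.0;

  const int nc = parent.size();
  const int nch = chan_comp.size();
  const int npool = pool_comp.size();
  const int nsyn = syn_comp.size();
  const int nconn = conn_src.size();
  const int nsteps = (int)std::round(duration / dt);

  // plain arrays for the hot loops
  std::vector<int> v_parent(parent.begin(), parent.end());
  std::vector<int> v_chan_comp(chan_comp.begin(), chan_comp.end());
  std::vector<int> v_chan_type(chan_type.begin(), chan_type.end());
  std::vector<int> v_syn_comp(syn_comp.begin(), syn_comp.end());
  std::vector<int> v_syn_nmda(syn_nmda.begin(), syn_nmda.end());
  std::vector<double> v_syn_E(syn_E.begin(), syn_E.end());

  // --- geometry-derived quantities -----------------------------------------
  std::vector<double> area(nc), cap(nc), gleak(nc), gax(nc);
  for (int i = 0; i < nc; ++i) {
    area[i] = M_PI * Dc[i] * Lc[i];
    cap[i] = Cm[i] * area[i];
    gleak[i] = area[i] / Rm[i];
  }
  for (int i = 0; i < nc; ++i) {
    int p = v_parent[i];
    if (p < 0) { gax[i] = 0.0; continue; }
    if (p >= i) stop("compartments must be ordered parent-before-child");
    double ri = Ra[i] * (Lc[i] / 2.0) / (M_PI * Dc[i] * Dc[i] / 4.0);
    double rp = Ra[p] * (Lc[p] / 2.0) / (M_PI * Dc[p] * Dc[p] / 4.0);
    gax[i] = 1.0 / (ri + rp);
  }

  // --- channel state -------------------------------------------------------
  std::vector<int> ch_ng(nch), ch_p0(nch), ch_p1(nch), ch_pool(nch, -1);
  std::vector<double> ch_gmax(nch);
  std::vector<double> gate_state; // concatenated
  std::vector<int> gate_off(nch);
  // pool index per compartment
  std::vector<int> comp_pool(nc, -1);
  for (int q = 0; q < npool; ++q) comp_pool[pool_comp[q]] = q;

  int gtot = 0;
  for (int k = 0; k < nch; ++k) {
    int tp = chan_type[k];
    int p[2]; chan_powers(tp, p);
    ch_ng[k] = chan_ngates(tp); ch_p0[k] = p[0]; ch_p1[k] = p[1];
    ch_gmax[k] = chan_gbar[k] * area[chan_comp[k]];
    if (tp == 3 || tp == 9 || tp == 5) ch_pool[k] = comp_pool[chan_comp[k]];
    gate_off[k] = gtot; gtot += ch_ng[k];
  }
  gate_state.assign(gtot, 0.0);
  // flat per-gate arrays for the hot update loop
  std::vector<int> gat_comp(gtot), gat_tab(gtot);
  std::vector<const double*> gat_ptr(gtot, (const double*)0);
  {
    int gi = 0;
    for (int k = 0; k < nch; ++k)
      for (int g = 0; g < ch_ng[k]; ++g, ++gi) {
        gat_comp[gi] = chan_comp[k];
        gat_tab[gi] = chan_type[k] * 2 + g;
      }
  }

  // gate kinetic tables per (type, gate), flat indexing tp*2+g; entries are
  // interleaved (inf, mul) pairs for cache locality in the hot loop
  std::vector<std::vector<double> > tabs(22);
  std::vector<bool> type_used(11, false);
  for (int k = 0; k < nch; ++k) type_used[chan_type[k]] = true;
  for (int tp = 0; tp < 11; ++tp) {
    if (!type_used[tp]) continue;
    int ng = chan_ngates(tp);
    for (int g = 0; g < ng; ++g) {
      std::vector<double>& t = tabs[tp * 2 + g];
      t.resize(2 * TAB_N);
      for (int i = 0; i < TAB_N; ++i) {
        double v = TAB_VMIN + (TAB_VMAX - TAB_VMIN) * i / (TAB_N - 1);
        InfTau r = gate_kinetics(tp, g, v);
        t[2 * i] = r.inf;
        t[2 * i + 1] = 1.0 - std::exp(-dt / r.tau);
      }
    }
  }
  for (int gi = 0; gi < gtot; ++gi) gat_ptr[gi] = tabs[gat_tab[gi]].data();
  // magnesium-block lookup on the same voltage grid
  std::vector<double> mgtab(TAB_N);
  for (int i = 0; i < TAB_N; ++i) {
    double v = TAB_VMIN + (TAB_VMAX - TAB_VMIN) * i / (TAB_N - 1);
    mgtab[i] = mg_block(v, mg_mM);
  }

  // --- initial state -------------------------------------------------------
  std::vector<double> V(nc);
  for (int i = 0; i < nc; ++i) V[i] = Em[i];
  for (int k = 0; k < nch; ++k) {
    int tp = chan_type[k]; double v = V[chan_comp[k]];
    for (int g = 0; g < ch_ng[k]; ++g)
      gate_state[gate_off[k] + g] = gate_kinetics(tp, g, v).inf;
  }
  std::vector<double> Ca(npool), pool_e(npool);
  for (int q = 0; q < npool; ++q) {
    Ca[q] = pool_base[q];
    pool_e[q] = std::exp(-dt / pool_tau[q]);
  }

  // synapse pool states and discrete propagators
  std::vector<double> sh(nsyn, 0.0), sg(nsyn, 0.0);
  std::vector<double> se1(nsyn), se2(nsyn), scoef(nsyn);
  std::vector<bool> s_equal(nsyn);
  for (int s = 0; s < nsyn; ++s) {
    double t1 = syn_taur[s], t2 = syn_taud[s];
    se1[s] = std::exp(-dt / t1);
    se2[s] = std::exp(-dt / t2);
    if (std::fabs(t1 - t2) < 1e-9 * t2) { s_equal[s] = true; scoef[s] = dt; }
    else { s_equal[s] = false; scoef[s] = (se1[s] - se2[s]) / (1.0 / t2 - 1.0 / t1); }
  }

  // --- connections grouped by source cell ----------------------------------
  std::vector<int> conn_off(n_cells + 1, 0);
  {
    std::vector<int> cnt(n_cells, 0);
    for (int c = 0; c < nconn; ++c) cnt[conn_src[c]]++;
    for (int c = 0; c < n_cells; ++c) conn_off[c + 1] = conn_off[c] + cnt[c];
  }
  std::vector<int> conn_idx(nconn);
  {
    std::vector<int> pos(conn_off.begin(), conn_off.end() - 1);
    for (int c = 0; c < nconn; ++c) conn_idx[pos[conn_src[c]]++] = c;
  }

  // --- event ring buffer ---------------------------------------------------
  double max_delay = 0.0;
  for (int c = 0; c < nconn; ++c) max_delay = std::max(max_delay, conn_delay[c]);
  int ring_n = (int)(max_delay / dt) + 2;
  std::vector<std::vector<std::pair<int, double> > > ring(ring_n);

  // external events, sorted by time
  NumericVector ext_time = stim["time"];
  IntegerVector ext_pool = stim["pool"];
  NumericVector ext_w = stim["w"];
  int next = ext_time.size(), ext_i = 0;

  // current injections
  IntegerVector inj_comp = stim["inj_comp"];
  NumericVector inj_t0 = stim["inj_t0"], inj_t1 = stim["inj_t1"],
                inj_I0 = stim["inj_I0"], inj_I1 = stim["inj_I1"];
  int ninj = inj_comp.size();

  // --- recording -----------------------------------------------------------
  int rec_every = std::max(1, (int)std::round(rec_dt / dt));
  int nrec_t = nsteps / rec_every + 1;
  NumericMatrix vrec(nrec_t, record.size());
  NumericVector trec(nrec_t);
  int rec_row = 0;
  for (int j = 0; j < record.size(); ++j) vrec(rec_row, j) = V[record[j]];
  trec[rec_row++] = 0.0;

  std::vector<double> last_spike(n_cells, -1e9);
  std::vector<double> prevV_soma(n_cells);
  for (int c = 0; c < n_cells; ++c) prevV_soma[c] = V[soma_comp[c]];
  std::vector<int> spike_cell_out;
  std::vector<double> spike_t_out;

  double gate_min = 1.0, gate_max = 0.0;

  // work arrays for the Hines solve
  std::vector<double> diag(nc), rhs(nc), gsum(nc), gesum(nc), inj_cur(nc);
  std::vector<double> syn_g_comp(nc), ca_cur(npool);

  // --- time stepping -------------------------------------------------------
  for (int n = 0; n < nsteps; ++n) {
    double t = n * dt;

    // deliver ring-buffer events for this step
    int slot = n % ring_n;
    for (size_t e = 0; e < ring[slot].size(); ++e)
      sh[ring[slot][e].first] += ring[slot][e].second;
    ring[slot].clear();
    // deliver external events with time in [t, t+dt)
    while (ext_i < next && ext_time[ext_i] < t + dt) {
      if (ext_time[ext_i] >= t - 1e-12) sh[ext_pool[ext_i]] += ext_w[ext_i];
      ++ext_i;
    }

    // advance synapse states (exact linear propagator), then use g for step
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    for (int s = 0; s < nsyn; ++s) {
      if (sg[s] < 1e-16 && sh[s] < 1e-16) {
        sg[s] = 0.0; sh[s] = 0.0;
        continue;
      }
      double g;
      if (s_equal[s]) g = se2[s] * (sg[s] + scoef[s] * sh[s]);
      else            g = sg[s] * se2[s] + sh[s] * scoef[s];
      sg[s] = g;
      sh[s] *= se1[s];
      if (v_syn_nmda[s]) {
        double x = (V[v_syn_comp[s]] - TAB_VMIN) *
          ((TAB_N - 1) / (TAB_VMAX - TAB_VMIN));
        int ii = (int)x;
        if (ii < 0) ii = 0; else if (ii > TAB_N - 2) ii = TAB_N - 2;
        double f = x - ii;
        g *= mgtab[ii] * (1 - f) + mgtab[ii + 1] * f;
      }
      int ic = v_syn_comp[s];
      gsum[ic] += g;
      gesum[ic] += g * v_syn_E[s];
    }

    // channel conductances at current gate states
    std::fill(ca_cur.begin(), ca_cur.end(), 0.0);
    for (int k = 0; k < nch; ++k) {
      int ic = v_chan_comp[k];
      double go = ch_gmax[k];
      double m = gate_state[gate_off[k]];
      double mm = m;
      for (int r = 1; r < ch_p0[k]; ++r) mm *= m;
      go *= mm;
      if (ch_ng[k] > 1) {
        double h = gate_state[gate_off[k] + 1];
        double hh = h;
        for (int r = 1; r < ch_p1[k]; ++r) hh *= h;
        go *= hh;
      }
      if (v_chan_type[k] == 5 && ch_pool[k] >= 0) {
        double ca = Ca[ch_pool[k]];
        go *= ca / (ca + chan_kd[k]);
      }
      gsum[ic] += go;
      gesum[ic] += go * chan_E[k];
      // calcium current bookkeeping (inward positive), explicit at old V
      if ((v_chan_type[k] == 3 || v_chan_type[k] == 9) && ch_pool[k] >= 0)
        ca_cur[ch_pool[k]] += go * (chan_E[k] - V[ic]);
    }

    // injected currents
    std::fill(inj_cur.begin(), inj_cur.end(), 0.0);
    for (int j = 0; j < ninj; ++j) {
      if (t >= inj_t0[j] && t < inj_t1[j]) {
        double f = (t - inj_t0[j]) / (inj_t1[j] - inj_t0[j]);
        inj_cur[inj_comp[j]] += inj_I0[j] + f * (inj_I1[j] - inj_I0[j]);
      }
    }

    // theta-method tree solve: (C/dt + theta*G) V' = C/dt V + b - (1-theta)*G V
    // with G including leak, channels, synapses and axial coupling.
    for (int i = 0; i < nc; ++i) {
      double gm = gleak[i] + gsum[i];
      double be = gleak[i] * Em[i] + gesum[i] + inj_cur[i];
      diag[i] = cap[i] / dt + theta * gm;
      rhs[i] = cap[i] / dt * V[i] + be - (1.0 - theta) * gm * V[i];
    }
    if (theta < 1.0) {
      for (int i = 0; i < nc; ++i) {
        int p = v_parent[i];
        if (p < 0) continue;
        double gx = (1.0 - theta) * gax[i];
        rhs[i] += gx * (V[p] - V[i]);
        rhs[p] += gx * (V[i] - V[p]);
      }
    }
    // add implicit axial part and eliminate children into parents
    for (int i = nc - 1; i >= 0; --i) {
      int p = v_parent[i];
      if (p < 0) continue;
      double gx = theta * gax[i];
      diag[i] += gx;
      diag[p] += gx;
      double f = gx / diag[i];
      diag[p] -= f * gx;
      rhs[p] += f * rhs[i];
    }
    for (int i = 0; i < nc; ++i) {
      int p = v_parent[i];
      if (p < 0) V[i] = rhs[i] / diag[i];
      else V[i] = (rhs[i] + theta * gax[i] * V[p]) / diag[i];
      if (!std::isfinite(V[i]))
        stop("integration failure: non-finite voltage in compartment %d at t=%f s",
             i + 1, t);
    }

    // gate update (exponential Euler at new V)
    {
      const double sc = (TAB_N - 1) / (TAB_VMAX - TAB_VMIN);
      for (int gi = 0; gi < gtot; ++gi) {
        double x = (V[gat_comp[gi]] - TAB_VMIN) * sc;
        if (x < 0) x = 0; else if (x > TAB_N - 1) x = TAB_N - 1;
        int i = (int)x; double f = x - i;
        if (i >= TAB_N - 1) { i = TAB_N - 2; f = 1.0; }
        const double* t = gat_ptr[gi] + 2 * i;
        double inf = t[0] * (1 - f) + t[2] * f;
        double mul = t[1] * (1 - f) + t[3] * f;
        double& g = gate_state[gi];
        g += (inf - g) * mul;
        if (debug_gates) {
          if (g < gate_min) gate_min = g;
          if (g > gate_max) gate_max = g;
        }
      }
    }

    // calcium pools: dCa/dt = B*I_Ca - (Ca-base)/tau, exponential update
    for (int q = 0; q < npool; ++q) {
      double ss = pool_base[q] + pool_B[q] * ca_cur[q] * pool_tau[q];
      Ca[q] = ss + (Ca[q] - ss) * pool_e[q];
      if (Ca[q] < 0) Ca[q] = 0;
    }

    // spike detection + event scheduling
    double tnew = t + dt;
    for (int c = 0; c < n_cells; ++c) {
      double v0 = prevV_soma[c], v1 = V[soma_comp[c]];
      if (v0 < spike_thresh && v1 >= spike_thresh &&
          tnew - last_spike[c] >= refractory) {
        double frac = (spike_thresh - v0) / (v1 - v0);
        double tsp = t + frac * dt;
        last_spike[c] = tnew;
        spike_cell_out.push_back(c);
        spike_t_out.push_back(tsp);
        for (int e = conn_off[c]; e < conn_off[c + 1]; ++e) {
          int ci = conn_idx[e];
          int target_step = n + 1 + (int)std::round(conn_delay[ci] / dt);
          if (target_step < nsteps)
            ring[target_step % ring_n].push_back(
              std::make_pair(conn_pool[ci], conn_w[ci]));
        }
      }
      prevV_soma[c] = v1;
    }

    // recording
    if ((n + 1) % rec_every == 0 && rec_row < nrec_t) {
      for (int j = 0; j < record.size(); ++j) vrec(rec_row, j) = V[record[j]];
      trec[rec_row++] = tnew;
    }
  }

  List out = List::create(
    _["time"] = trec[Range(0, rec_row - 1)],
    _["v"] = vrec(Range(0, rec_row - 1), _),
    _["spike_cell"] = wrap(spike_cell_out),
    _["spike_t"] = wrap(spike_t_out));
  if (debug_gates) {
    out["gate_min"] = gate_min;
    out["gate_max"] = gate_max;
  }
  return out;
}

// Dead-time (refractory) filter for event trains: input sorted by
// (train, time); returns a keep mask enforcing a minimum interval within
// each train.
// [[Rcpp::export(name = ".dead_time_filter")]]
LogicalVector dead_time_filter(IntegerVector train, NumericVector time,
                               double refrac) {
  int n = train.size();
  LogicalVector keep(n);
  int cur = -1; double last = -1e18;
  for (int i = 0; i < n; ++i) {
    if (train[i] != cur) { cur = train[i]; last = -1e18; }
    if (time[i] - last >= refrac) { keep[i] = true; last = time[i]; }
  }
  return keep;
}
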