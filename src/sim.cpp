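// Time-stepped integrators for the thermally modulated Hodgkin-Huxley
// neuron, the Tsodyks-Markram synapse, and the recurrent E/I network.
// Scheme: exponential update for gating variables, explicit midpoint (RK2)
// for the membrane potential, shared fixed clock. Temperature protocols are
// sampled in R at half-step resolution and passed in as arrays.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// x / (e^x - 1), finite at x = 0 (removable singularity)
static inline double inv_exprel(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 - 0.5 * x;
  return x / std::expm1(x);
}

struct NeuronPar {
  double g_leak, g_Na, g_K, E_leak, E_Na, E_K;
  double V_detect, dead_time;
  int nernst;       // 0 off, 1 linear absolute-temperature scaling
  double T_ref;
};

struct ThermalPar {
  double T_ref, q_base, C0, k, Tc, Vs, cap_coeff;
  int fractional;   // cap_mode: 0 literal, 1 fractional
};

static inline double phi_of(double T, const ThermalPar& tp) {
  return std::pow(tp.q_base, (T - tp.T_ref) / 10.0);
}

static inline double cm_of(double T, const ThermalPar& tp) {
  return tp.C0 + tp.k / (tp.Tc - T);
}

struct Rates { double an, bn, am, bm, ah, bh; };

static inline Rates gating(double v, double ph) {
  Rates r;
  r.an = 0.032 * ph * 5.0 * inv_exprel((-48.0 - v) / 5.0);
  r.bn = 0.5 * ph * std::exp((-53.0 - v) / 40.0);
  r.am = 0.32 * ph * 4.0 * inv_exprel((-50.0 - v) / 4.0);
  r.bm = 0.28 * ph * 5.0 * inv_exprel((v + 23.0) / 5.0);
  r.ah = 0.128 * ph * std::exp((-46.0 - v) / 18.0);
  r.bh = 4.0 * ph / (1.0 + std::exp((-23.0 - v) / 5.0));
  return r;
}

static inline double rhs_v(double v, double m, double n, double h,
                           double T, double dTdt, double i_ext,
                           double i_syn, const NeuronPar& np,
                           const ThermalPar& tp) {
  double Cm = cm_of(T, tp);
  double coeff = tp.cap_coeff;
  if (tp.fractional) coeff *= Cm;
  double Im = coeff * dTdt * (v - tp.Vs);
  double e_na = np.E_Na, e_k = np.E_K;
  if (np.nernst) {
    double s = (T + 273.15) / (np.T_ref + 273.15);
    e_na *= s; e_k *= s;
  }
  double i_ion = -np.g_leak * (v - np.E_leak)
               - np.g_Na * m * m * m * h * (v - e_na)
               - np.g_K * n * n * n * n * (v - e_k);
  return (i_ion + i_ext + i_syn - Im) / Cm;
}

static NeuronPar as_neuron_par(const List& np) {
  NeuronPar p;
  p.g_leak = np["g_leak"]; p.g_Na = np["g_Na"]; p.g_K = np["g_K"];
  p.E_leak = np["E_leak"]; p.E_Na = np["E_Na"]; p.E_K = np["E_K"];
  p.V_detect = np["V_detect"]; p.dead_time = np["dead_time"];
  std::string ns = as<std::string>(np["nernst_scaling"]);
  p.nernst = (ns == "linear") ? 1 : 0;
  return p;
}

static ThermalPar as_thermal_par(const List& tp) {
  ThermalPar p;
  p.T_ref = tp["T_ref"]; p.q_base = tp["q_base"]; p.C0 = tp["C0"];
  p.k = tp["k"]; p.Tc = tp["Tc"]; p.Vs = tp["Vs"];
  p.cap_coeff = tp["cap_coeff"];
  std::string cm = as<std::string>(tp["cap_mode"]);
  p.fractional = (cm == "fractional") ? 1 : 0;
  return p;
}

// Advance one neuron by one step: exponential gate update at (v, T_k),
// then RK2 midpoint for the voltage with the fresh gates.
static inline double step_neuron(double& v, double& m, double& n, double& h,
                                 double Tk, double dTk, double Tm,
                                 double dTm, double dt, double i_ext,
                                 double i_syn, const NeuronPar& np,
                                 const ThermalPar& tp) {
  Rates r = gating(v, phi_of(Tk, tp));
  double sm = r.am + r.bm, sn = r.an + r.bn, sh = r.ah + r.bh;
  m = r.am / sm + (m - r.am / sm) * std::exp(-dt * sm);
  n = r.an / sn + (n - r.an / sn) * std::exp(-dt * sn);
  h = r.ah / sh + (h - r.ah / sh) * std::exp(-dt * sh);
  double k1 = rhs_v(v, m, n, h, Tk, dTk, i_ext, i_syn, np, tp);
  double vmid = v + 0.5 * dt * k1;
  double k2 = rhs_v(vmid, m, n, h, Tm, dTm, i_ext, i_syn, np, tp);
  double v_new = v + dt * k2;
  return v_new;
}

// [[Rcpp::export]]
List cpp_sim_neuron(NumericVector T_half, NumericVector dTdt_half,
                    double dt, int n_steps, List neuron, List thermal,
                    double i_ext, double v0, double m0, double n0,
                    double h0, bool record) {
  NeuronPar np = as_neuron_par(neuron);
  ThermalPar tp = as_thermal_par(thermal);
  if (T_half.size() < 2 * n_steps + 1)
    stop("temperature trace shorter than the simulation");

  double v = v0, m = m0, n = n0, h = h0;
  std::vector<double> spikes;
  double last_spike = -1e18;
  NumericVector tr_v, tr_m, tr_n, tr_h;
  if (record) {
    tr_v = NumericVector(n_steps + 1);
    tr_m = NumericVector(n_steps + 1);
    tr_n = NumericVector(n_steps + 1);
    tr_h = NumericVector(n_steps + 1);
    tr_v[0] = v; tr_m[0] = m; tr_n[0] = n; tr_h[0] = h;
  }
  for (int kstep = 0; kstep < n_steps; ++kstep) {
    double Tk = T_half[2 * kstep], dTk = dTdt_half[2 * kstep];
    double Tm = T_half[2 * kstep + 1], dTm = dTdt_half[2 * kstep + 1];
    if (Tk >= tp.Tc || Tm >= tp.Tc)
      stop("temperature reached the Curie temperature during integration");
    double v_new = step_neuron(v, m, n, h, Tk, dTk, Tm, dTm, dt, i_ext,
                               0.0, np, tp);
    double t_new = (kstep + 1) * dt;
    if (!R_finite(v_new))
      stop("non-finite membrane potential at t = %f ms", t_new);
    if (v < np.V_detect && v_new >= np.V_detect &&
        t_new - last_spike >= np.dead_time) {
      spikes.push_back(t_new);
      last_spike = t_new;
    }
    v = v_new;
    if (record) {
      tr_v[kstep + 1] = v; tr_m[kstep + 1] = m;
      tr_n[kstep + 1] = n; tr_h[kstep + 1] = h;
    }
  }
  List out = List::create(_["spikes_ms"] = wrap(spikes));
  if (record)
    out["trace"] = List::create(_["vm"] = tr_v, _["m"] = tr_m,
                                _["n"] = tr_n, _["h"] = tr_h);
  return out;
}

struct SynPar {
  double U0, tau_f_ms, tau_r_ms, Omega_c_ms, Qc_YT_uM;
  double a_ampa, b_ampa, g_ampa, E_ampa;
  double a_nmda, b_nmda, g_nmda, E_nmda;
  double a_gaba, b_gaba, g_gaba, E_gaba;
  double mg, inv_area;          // inv_area: pA -> uA/cm^2 factor
};

static SynPar as_syn_par(const List& sp) {
  SynPar p;
  p.U0 = sp["U0"];
  p.tau_f_ms = as<double>(sp["tau_f"]) * 1000.0;
  p.tau_r_ms = as<double>(sp["tau_r"]) * 1000.0;
  p.Omega_c_ms = as<double>(sp["Omega_c"]) / 1000.0;
  p.Qc_YT_uM = as<double>(sp["Q_c"]) * as<double>(sp["Y_T"]) * 1000.0;
  List a = sp["ampa"], nm = sp["nmda"], g = sp["gaba"];
  p.a_ampa = as<double>(a["alpha"]) / 1000.0; p.b_ampa = as<double>(a["beta"]) / 1000.0;
  p.g_ampa = a["g_max"]; p.E_ampa = a["E"];
  p.a_nmda = as<double>(nm["alpha"]) / 1000.0; p.b_nmda = as<double>(nm["beta"]) / 1000.0;
  p.g_nmda = nm["g_max"]; p.E_nmda = nm["E"];
  p.a_gaba = as<double>(g["alpha"]) / 1000.0; p.b_gaba = as<double>(g["beta"]) / 1000.0;
  p.g_gaba = g["g_max"]; p.E_gaba = g["E"];
  p.mg = sp["mg_conc"];
  p.inv_area = 1e-6 / as<double>(sp["membrane_area"]);
  return p;
}

static inline double mg_unblock(double v, double mg) {
  return 1.0 / (1.0 + std::exp(-0.062 * v) * mg / 3.57);
}

// exact relaxation of dr/dt = aGs (1 - r) - b r over dt with Gs frozen
static inline double receptor_relax(double r, double aGs, double b,
                                    double dt) {
  double rate = aGs + b;
  if (rate <= 0.0) return r;
  double rinf = aGs / rate;
  return rinf + (r - rinf) * std::exp(-rate * dt);
}

// One glutamatergic synapse driven by a given presynaptic spike train,
// postsynaptic side voltage-clamped. Returns the EPSC trace (pA, inward
// negative) and per-event released fractions.
// [[Rcpp::export]]
List cpp_sim_synapse(NumericVector spike_times_ms, double dt, int n_steps,
                     List synapse, double v_clamp) {
  SynPar sp = as_syn_par(synapse);
  double u = 0.0, x = 1.0, Gs = 0.0, r1 = 0.0, r2 = 0.0;
  NumericVector epsc(n_steps + 1), gs_trace(n_steps + 1);
  std::vector<double> ev_t, ev_rs;
  int next_spike = 0, n_spk = spike_times_ms.size();
  double mgf = mg_unblock(v_clamp, sp.mg);
  for (int kstep = 0; kstep <= n_steps; ++kstep) {
    double t = kstep * dt;
    // spikes scheduled within (t - dt, t] land at the start of this step
    while (next_spike < n_spk && spike_times_ms[next_spike] <= t + 1e-12) {
      u += sp.U0 * (1.0 - u);
      double r_s = u * x;
      x -= r_s;
      Gs += r_s * sp.Qc_YT_uM;
      ev_t.push_back(spike_times_ms[next_spike]);
      ev_rs.push_back(r_s);
      ++next_spike;
    }
    epsc[kstep] = sp.g_ampa * r1 * (v_clamp - sp.E_ampa)
                + sp.g_nmda * mgf * r2 * (v_clamp - sp.E_nmda);
    gs_trace[kstep] = Gs;
    if (kstep == n_steps) break;
    r1 = receptor_relax(r1, sp.a_ampa * Gs, sp.b_ampa, dt);
    r2 = receptor_relax(r2, sp.a_nmda * Gs, sp.b_nmda, dt);
    Gs *= std::exp(-sp.Omega_c_ms * dt);
    u *= std::exp(-dt / sp.tau_f_ms);
    x = 1.0 - (1.0 - x) * std::exp(-dt / sp.tau_r_ms);
  }
  return List::create(_["epsc_pA"] = epsc, _["Gs_uM"] = gs_trace,
                      _["event_t_ms"] = wrap(ev_t),
                      _["event_r_s"] = wrap(ev_rs));
}

// Recurrent network: shared clock, per-edge Tsodyks-Markram state with
// AMPA+NMDA receptors on excitatory edges and GABA-A on inhibitory ones.
// Presynaptic spikes reach their edges at the end of the step in which
// they are detected (no axonal delay).
// [[Rcpp::export]]
List cpp_sim_network(NumericVector T_half, NumericVector dTdt_half,
                     double dt, int n_steps, List neuron, List thermal,
                     List synapse, NumericVector i_ext,
                     IntegerVector edge_pre, IntegerVector edge_post,
                     LogicalVector edge_exc, double w_exc, double w_inh,
                     NumericVector v0, NumericVector m0, NumericVector n0,
                     NumericVector h0, IntegerVector record_idx) {
  NeuronPar np = as_neuron_par(neuron);
  ThermalPar tp = as_thermal_par(thermal);
  SynPar sp = as_syn_par(synapse);
  const int N = v0.size();
  const int E = edge_pre.size();
  if (T_half.size() < 2 * n_steps + 1)
    stop("temperature trace shorter than the simulation");

  // CSR outgoing adjacency
  std::vector<int> out_count(N, 0), out_start(N + 1, 0), out_edges(E);
  for (int e = 0; e < E; ++e) out_count[edge_pre[e]]++;
  for (int i = 0; i < N; ++i) out_start[i + 1] = out_start[i] + out_count[i];
  {
    std::vector<int> fill(out_start.begin(), out_start.end() - 1);
    for (int e = 0; e < E; ++e) out_edges[fill[edge_pre[e]]++] = e;
  }

  std::vector<double> v(v0.begin(), v0.end()), m(m0.begin(), m0.end()),
      n(n0.begin(), n0.end()), h(h0.begin(), h0.end());
  std::vector<double> su(E, 0.0), sx(E, 1.0), sGs(E, 0.0),
      sr1(E, 0.0), sr2(E, 0.0), s_last(E, 0.0);
  std::vector<char> active(E, 0);
  std::vector<int> active_list;
  active_list.reserve(E);
  std::vector<double> i_syn(N, 0.0), last_spike(N, -1e18), mgv(N, 0.0);
  std::vector<std::vector<double> > spikes(N);

  const double gs_fac = std::exp(-sp.Omega_c_ms * dt);
  const double g_a = sp.g_ampa * w_exc, g_n = sp.g_nmda * w_exc,
               g_g = sp.g_gaba * w_inh;

  int n_rec = record_idx.size();
  NumericMatrix traces(n_rec > 0 ? n_steps + 1 : 0, n_rec);
  for (int j = 0; j < n_rec; ++j)
    if (n_rec > 0) traces(0, j) = v[record_idx[j]];

  for (int kstep = 0; kstep < n_steps; ++kstep) {
    double Tk = T_half[2 * kstep], dTk = dTdt_half[2 * kstep];
    double Tm = T_half[2 * kstep + 1], dTm = dTdt_half[2 * kstep + 1];
    if (Tk >= tp.Tc || Tm >= tp.Tc)
      stop("temperature reached the Curie temperature during integration");
    double t_new = (kstep + 1) * dt;

    // synaptic currents from edge states at step start, then advance edges
    std::fill(i_syn.begin(), i_syn.end(), 0.0);
    for (int i = 0; i < N; ++i) mgv[i] = mg_unblock(v[i], sp.mg);
    for (size_t a = 0; a < active_list.size();) {
      int e = active_list[a];
      int post = edge_post[e];
      double vp = v[post];
      double i_pA;
      if (edge_exc[e]) {
        i_pA = g_a * sr1[e] * (vp - sp.E_ampa)
             + g_n * mgv[post] * sr2[e] * (vp - sp.E_nmda);
        sr1[e] = receptor_relax(sr1[e], sp.a_ampa * sGs[e], sp.b_ampa, dt);
        sr2[e] = receptor_relax(sr2[e], sp.a_nmda * sGs[e], sp.b_nmda, dt);
      } else {
        i_pA = g_g * sr1[e] * (vp - sp.E_gaba);
        sr1[e] = receptor_relax(sr1[e], sp.a_gaba * sGs[e], sp.b_gaba, dt);
      }
      i_syn[post] -= i_pA * sp.inv_area;   // inward (negative) depolarizes
      sGs[e] *= gs_fac;
      if (sGs[e] < 1e-10 && sr1[e] < 1e-10 && sr2[e] < 1e-10) {
        active[e] = 0;
        active_list[a] = active_list.back();
        active_list.pop_back();
      } else {
        ++a;
      }
    }

    for (int i = 0; i < N; ++i) {
      double v_new = step_neuron(v[i], m[i], n[i], h[i], Tk, dTk, Tm, dTm,
                                 dt, i_ext[i], i_syn[i], np, tp);
      if (!R_finite(v_new))
        stop("non-finite membrane potential for neuron %d at t = %f ms",
             i + 1, t_new);
      bool spk = (v[i] < np.V_detect && v_new >= np.V_detect &&
                  t_new - last_spike[i] >= np.dead_time);
      v[i] = v_new;
      if (spk) {
        spikes[i].push_back(t_new);
        last_spike[i] = t_new;
        for (int a = out_start[i]; a < out_start[i + 1]; ++a) {
          int e = out_edges[a];
          // lazy inter-spike relaxation of u, x since the last event
          double gap = t_new - s_last[e];
          if (gap > 0) {
            su[e] *= std::exp(-gap / sp.tau_f_ms);
            sx[e] = 1.0 - (1.0 - sx[e]) * std::exp(-gap / sp.tau_r_ms);
          }
          s_last[e] = t_new;
          su[e] += sp.U0 * (1.0 - su[e]);
          double r_s = su[e] * sx[e];
          sx[e] -= r_s;
          sGs[e] += r_s * sp.Qc_YT_uM;
          if (!active[e]) { active[e] = 1; active_list.push_back(e); }
        }
      }
    }
    for (int j = 0; j < n_rec; ++j) traces(kstep + 1, j) = v[record_idx[j]];
    if ((kstep & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  // flatten spikes
  std::vector<int> sid; std::vector<double> st;
  for (int i = 0; i < N; ++i)
    for (size_t j = 0; j < spikes[i].size(); ++j) {
      sid.push_back(i + 1);
      st.push_back(spikes[i][j]);
    }
  List out = List::create(_["neuron"] = wrap(sid), _["time_ms"] = wrap(st));
  if (n_rec > 0) out["traces"] = traces;
  return out;
}
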