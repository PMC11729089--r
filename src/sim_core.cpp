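// Fixed-step network integration core.
//
// Units: time ms, voltage mV, conductance uS, current nA, capacitance nF.
// Per step: gating variables advance by exact exponential relaxation toward
// table-interpolated steady states; synaptic open fractions integrate the
// pulse-transmitter kinetics in closed form; compartment voltages advance by
// a linearised implicit (backward-Euler) step with all membrane conductances
// frozen over the step, solved exactly on each cell's compartment tree
// (Hines elimination).  Presynaptic spikes are delivered through a ring
// buffer after their conduction delay (quantised to the dt grid).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct RNG {
  std::uint64_t s;
  bool have_cached = false;
  double cached = 0.0;
  explicit RNG(std::uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  // splitmix64
  double unif() {
    s += 0x9E3779B97F4A7C15ULL;
    std::uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z = z ^ (z >> 31);
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    have_cached = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

inline double interp(const std::vector<double>& tab, double x, double x0,
                     double dx) {
  double u = (x - x0) / dx;
  int n = (int)tab.size();
  if (u <= 0) return tab[0];
  if (u >= n - 1) return tab[n - 1];
  int k = (int)u;
  double f = u - k;
  return tab[k] + f * (tab[k + 1] - tab[k]);
}

inline double powi(double x, int p) {
  switch (p) {
    case 0: return 1.0;
    case 1: return x;
    case 2: return x * x;
    case 3: return x * x * x;
    case 4: { double x2 = x * x; return x2 * x2; }
    default: return std::pow(x, p);
  }
}

} // namespace

// [[Rcpp::export]]
List sim_core(List net, List opts) {
  // --- unpack compartments -------------------------------------------------
  IntegerVector comp_cell = net["comp_cell"];      // 0-based cell id
  NumericVector comp_C = net["comp_C"];
  NumericVector comp_gL = net["comp_gL"];
  NumericVector comp_EL = net["comp_EL"];
  IntegerVector comp_parent = net["comp_parent"];  // 0-based, -1 root
  NumericVector comp_gc = net["comp_gc"];
  NumericVector comp_v0 = net["comp_v0"];
  NumericVector comp_clfp = net["comp_clfp"];
  IntegerVector cell_soma = net["cell_soma"];      // soma comp per cell
  const int n_comp = comp_cell.size();
  const int n_cell = cell_soma.size();

  // --- channels ------------------------------------------------------------
  IntegerVector ch_comp = net["ch_comp"];
  NumericVector ch_g = net["ch_g"];                // uS
  NumericVector ch_E = net["ch_E"];
  IntegerVector ch_p = net["ch_p"];
  IntegerVector ch_q = net["ch_q"];
  IntegerVector ch_mtab = net["ch_mtab"];
  IntegerVector ch_htab = net["ch_htab"];          // -1 none
  IntegerVector ch_cagate = net["ch_cagate"];
  NumericVector ch_cagain = net["ch_cagain"];
  const int n_chan = ch_comp.size();

  // --- gate tables ---------------------------------------------------------
  List tabs = net["gate_tables"];
  NumericMatrix tinf = tabs["inf"];   // ntab x n
  NumericMatrix ttau = tabs["tau"];
  IntegerVector tisca = tabs["is_ca"];
  double v0g = tabs["v0"], dvg = tabs["dv"];
  double lc0 = tabs["lc0"], dlc = tabs["dlc"];
  const int ntab = tinf.nrow();

  // --- calcium pools -------------------------------------------------------
  double ca_rest = net["ca_rest"], ca_floor = net["ca_floor"];
  double tau_ca = net["tau_ca"];

  // --- synapses ------------------------------------------------------------
  IntegerVector sy_comp = net["sy_comp"];
  NumericVector sy_g = net["sy_g"];                // w * gmax * ach, uS
  NumericVector sy_E = net["sy_E"];
  NumericVector sy_aT = net["sy_aT"];
  NumericVector sy_beta = net["sy_beta"];
  IntegerVector sy_onsteps = net["sy_onsteps"];
  IntegerVector sy_mg = net["sy_mg"];
  IntegerVector sy_stp = net["sy_stp"];            // 0 none, 1 dep, 2 fac
  NumericVector sy_f = net["sy_f"];
  NumericVector sy_tauF = net["sy_tauF"];
  NumericVector sy_d1 = net["sy_d1"];
  NumericVector sy_taud1 = net["sy_taud1"];
  NumericVector sy_d2 = net["sy_d2"];
  NumericVector sy_taud2 = net["sy_taud2"];
  IntegerVector sy_pre = net["sy_pre"];            // 0-based cell, -1 afferent
  IntegerVector sy_delay = net["sy_delay"];        // steps, >= 1
  const int n_syn = sy_comp.size();

  // afferent events (sorted by step)
  IntegerVector ev_step = net["ev_step"];
  IntegerVector ev_syn = net["ev_syn"];
  const int n_ev = ev_step.size();

  // --- OU background -------------------------------------------------------
  NumericVector ou_ge_mean = net["ou_ge_mean"];
  NumericVector ou_ge_sd = net["ou_ge_sd"];
  NumericVector ou_gi_mean = net["ou_gi_mean"];
  NumericVector ou_gi_sd = net["ou_gi_sd"];
  double ou_taue = net["ou_taue"], ou_taui = net["ou_taui"];
  double ou_Ee = net["ou_Ee"], ou_Ei = net["ou_Ei"];

  // --- injections ----------------------------------------------------------
  IntegerVector inj_comp = net["inj_comp"];
  NumericVector inj_amp = net["inj_amp"];
  IntegerVector inj_on = net["inj_on"];
  IntegerVector inj_off = net["inj_off"];
  const int n_inj = inj_comp.size();

  // --- options -------------------------------------------------------------
  const double dt = opts["dt"];
  const int n_steps = opts["n_steps"];
  const std::uint64_t seed = (std::uint64_t)(double)opts["seed"];
  IntegerVector rec_v = opts["record_v"];          // 0-based comp indices
  const int lfp_bin = opts["lfp_bin_steps"];       // 0 = no LFP
  const bool rec_i = as<bool>(opts["record_currents"]);
  const double thresh = opts["spike_threshold"];
  const int refrac = opts["refractory_steps"];

  // --- precompute ----------------------------------------------------------
  // exponential relaxation factors per gate table for this dt
  std::vector<std::vector<double>> tab_inf(ntab), tab_efac(ntab);
  for (int t = 0; t < ntab; ++t) {
    int n = tinf.ncol();
    tab_inf[t].resize(n); tab_efac[t].resize(n);
    for (int k = 0; k < n; ++k) {
      tab_inf[t][k] = tinf(t, k);
      tab_efac[t][k] = std::exp(-dt / ttau(t, k));
    }
  }
  std::vector<double> sy_eoff(n_syn), sy_eF(n_syn), sy_eD1(n_syn), sy_eD2(n_syn);
  std::vector<double> sy_rinf(n_syn), sy_eon(n_syn);
  for (int s = 0; s < n_syn; ++s) {
    sy_eoff[s] = std::exp(-sy_beta[s] * dt);
    double lam = sy_aT[s] + sy_beta[s];
    sy_rinf[s] = sy_aT[s] / lam;
    sy_eon[s] = std::exp(-lam * dt);
    sy_eF[s] = std::exp(-dt / sy_tauF[s]);
    sy_eD1[s] = std::exp(-dt / sy_taud1[s]);
    sy_eD2[s] = std::exp(-dt / sy_taud2[s]);
  }
  // efferent synapse lists per cell (CSR)
  std::vector<int> eff_ptr(n_cell + 1, 0), eff_idx;
  {
    std::vector<int> cnt(n_cell, 0);
    for (int s = 0; s < n_syn; ++s) if (sy_pre[s] >= 0) cnt[sy_pre[s]]++;
    for (int c = 0; c < n_cell; ++c) eff_ptr[c + 1] = eff_ptr[c] + cnt[c];
    eff_idx.resize(eff_ptr[n_cell]);
    std::vector<int> pos(eff_ptr.begin(), eff_ptr.end() - 1);
    for (int s = 0; s < n_syn; ++s)
      if (sy_pre[s] >= 0) eff_idx[pos[sy_pre[s]]++] = s;
  }
  int max_delay = 1;
  for (int s = 0; s < n_syn; ++s) if (sy_delay[s] > max_delay) max_delay = sy_delay[s];
  std::vector<std::vector<int>> ring(max_delay + 1);

  // --- state ---------------------------------------------------------------
  std::vector<double> V(comp_v0.begin(), comp_v0.end()), Vn(n_comp);
  std::vector<double> Ca(n_comp, ca_rest);
  std::vector<double> gm(n_chan), gh(n_chan);
  for (int c = 0; c < n_chan; ++c) {
    double x = ch_cagate[c] ? std::log10(ca_rest) : V[ch_comp[c]];
    int mt = ch_mtab[c];
    gm[c] = interp(tab_inf[mt], x, tisca[mt] ? lc0 : v0g, tisca[mt] ? dlc : dvg);
    if (ch_htab[c] >= 0) {
      int ht = ch_htab[c];
      gh[c] = interp(tab_inf[ht], V[ch_comp[c]], v0g, dvg);
    } else gh[c] = 1.0;
  }
  std::vector<double> sr(n_syn, 0.0), sF(n_syn, 1.0), sD1(n_syn, 1.0), sD2(n_syn, 1.0);
  std::vector<int> s_on_until(n_syn, -1), s_last(n_syn, -1000000000);
  std::vector<char> s_active(n_syn, 0);
  std::vector<double> ge(n_cell), gi(n_cell);
  for (int c = 0; c < n_cell; ++c) { ge[c] = ou_ge_mean[c]; gi[c] = ou_gi_mean[c]; }
  RNG rng(seed);
  const double e_oue = std::exp(-dt / ou_taue), s_oue = std::sqrt(1 - e_oue * e_oue);
  const double e_oui = std::exp(-dt / ou_taui), s_oui = std::sqrt(1 - e_oui * e_oui);
  const bool has_ou = true;

  std::vector<int> last_spike(n_cell, -1000000000);
  std::vector<int> spike_cell; std::vector<double> spike_t;

  // accumulators
  std::vector<double> G(n_comp), GE(n_comp), Iinj(n_comp), a(n_comp), b(n_comp);
  int n_lfp = lfp_bin > 0 ? n_steps / lfp_bin : 0;
  NumericVector lfp(n_lfp);
  double lfp_acc = 0.0;
  NumericMatrix ibin(rec_i && lfp_bin > 0 ? n_comp : 0, rec_i ? n_lfp : 0);
  std::vector<double> ib_acc(rec_i ? n_comp : 0, 0.0);
  const int n_recv = rec_v.size();
  NumericMatrix vtrace(n_recv, n_recv > 0 ? n_steps : 0);

  int ev_ptr = 0;
  const double dt_inv = 1.0 / dt;

  // STP recovery-then-jump on a delivered spike
  auto deliver = [&](int s, int step) {
    if (sy_stp[s] != 0) {
      double gap = (step - s_last[s]) * dt;
      if (s_last[s] > -1000000000 && !s_active[s]) {
        sF[s] = 1 + (sF[s] - 1) * std::exp(-gap / sy_tauF[s]);
        sD1[s] = 1 + (sD1[s] - 1) * std::exp(-gap / sy_taud1[s]);
        sD2[s] = 1 + (sD2[s] - 1) * std::exp(-gap / sy_taud2[s]);
      }
      sF[s] *= sy_f[s];
      sD1[s] *= sy_d1[s];
      sD2[s] *= sy_d2[s];
    }
    int until = step + sy_onsteps[s];
    if (until > s_on_until[s]) s_on_until[s] = until;
    s_active[s] = 1;
    s_last[s] = step;
  };

  for (int step = 0; step < n_steps; ++step) {
    // 1. event deliveries
    while (ev_ptr < n_ev && ev_step[ev_ptr] == step) {
      deliver(ev_syn[ev_ptr], step); ++ev_ptr;
    }
    std::vector<int>& slot = ring[step % (max_delay + 1)];
    for (size_t k = 0; k < slot.size(); ++k) deliver(slot[k], step);
    slot.clear();

    std::fill(G.begin(), G.end(), 0.0);
    std::fill(GE.begin(), GE.end(), 0.0);
    std::fill(Iinj.begin(), Iinj.end(), 0.0);

    // 2. synapses
    for (int s = 0; s < n_syn; ++s) {
      if (!s_active[s]) continue;
      bool on = step < s_on_until[s];
      if (on) sr[s] = sy_rinf[s] + (sr[s] - sy_rinf[s]) * sy_eon[s];
      else sr[s] *= sy_eoff[s];
      if (sy_stp[s] != 0) {
        sF[s] = 1 + (sF[s] - 1) * sy_eF[s];
        sD1[s] = 1 + (sD1[s] - 1) * sy_eD1[s];
        sD2[s] = 1 + (sD2[s] - 1) * sy_eD2[s];
        s_last[s] = step;
      }
      if (!on && sr[s] < 1e-10) { sr[s] = 0.0; s_active[s] = 0; continue; }
      double mult = sF[s] * sD1[s] * sD2[s];
      if (sy_stp[s] == 1 && mult > 1.0) mult = 1.0;
      int cp = sy_comp[s];
      double sfac = sy_mg[s] ? 1.0 / (1.0 + 0.33 * std::exp(-0.06 * V[cp])) : 1.0;
      double g = sy_g[s] * mult * sfac * sr[s];
      G[cp] += g;
      GE[cp] += g * sy_E[s];
    }

    // 3. channels: advance gates, accumulate conductances, track Ca influx
    std::vector<double> ica(n_comp, 0.0);
    for (int c = 0; c < n_chan; ++c) {
      int cp = ch_comp[c];
      double v = V[cp];
      int mt = ch_mtab[c];
      double x, x0, dx;
      if (ch_cagate[c]) {
        double ca = Ca[cp] < ca_floor ? ca_floor : Ca[cp];
        x = std::log10(ca); x0 = lc0; dx = dlc;
      } else { x = v; x0 = v0g; dx = dvg; }
      double minf = interp(tab_inf[mt], x, x0, dx);
      double mef = interp(tab_efac[mt], x, x0, dx);
      gm[c] = minf + (gm[c] - minf) * mef;
      double gate = powi(gm[c], ch_p[c]);
      if (ch_htab[c] >= 0) {
        int ht = ch_htab[c];
        double hinf = interp(tab_inf[ht], v, v0g, dvg);
        double hef = interp(tab_efac[ht], v, v0g, dvg);
        gh[c] = hinf + (gh[c] - hinf) * hef;
        gate *= powi(gh[c], ch_q[c]);
      }
      double g = ch_g[c] * gate;
      G[cp] += g;
      GE[cp] += g * ch_E[c];
      if (ch_cagain[c] != 0.0) ica[cp] += ch_cagain[c] * g * (v - ch_E[c]);
    }
    // 4. calcium pools
    for (int i = 0; i < n_comp; ++i) {
      if (ica[i] != 0.0 || Ca[i] != ca_rest) {
        Ca[i] += dt * (-ica[i] - (Ca[i] - ca_rest) / tau_ca);
        if (Ca[i] < ca_floor) Ca[i] = ca_floor;
      }
    }

    // 5. OU background at the soma
    if (has_ou) {
      for (int c = 0; c < n_cell; ++c) {
        if (ou_ge_sd[c] > 0 || ou_ge_mean[c] > 0) {
          ge[c] = ou_ge_mean[c] + (ge[c] - ou_ge_mean[c]) * e_oue +
                  ou_ge_sd[c] * s_oue * rng.norm();
          double g = ge[c] > 0 ? ge[c] : 0.0;
          int sp = cell_soma[c];
          G[sp] += g; GE[sp] += g * ou_Ee;
        }
        if (ou_gi_sd[c] > 0 || ou_gi_mean[c] > 0) {
          gi[c] = ou_gi_mean[c] + (gi[c] - ou_gi_mean[c]) * e_oui +
                  ou_gi_sd[c] * s_oui * rng.norm();
          double g = gi[c] > 0 ? gi[c] : 0.0;
          int sp = cell_soma[c];
          G[sp] += g; GE[sp] += g * ou_Ei;
        }
      }
    }

    // 6. injected currents
    for (int j = 0; j < n_inj; ++j)
      if (step >= inj_on[j] && step < inj_off[j]) Iinj[inj_comp[j]] += inj_amp[j];

    // 7. implicit voltage step on each cell tree (Hines elimination; the
    //    compartment list is ordered parent-before-child)
    for (int i = 0; i < n_comp; ++i) {
      a[i] = comp_C[i] * dt_inv + comp_gL[i] + G[i];
      b[i] = comp_C[i] * dt_inv * V[i] + comp_gL[i] * comp_EL[i] + GE[i] + Iinj[i];
    }
    for (int i = 0; i < n_comp; ++i) {
      int p = comp_parent[i];
      if (p >= 0) { a[i] += comp_gc[i]; a[p] += comp_gc[i]; }
    }
    for (int i = n_comp - 1; i >= 0; --i) {
      int p = comp_parent[i];
      if (p >= 0) {
        double f = comp_gc[i] / a[i];
        a[p] -= f * comp_gc[i];
        b[p] += f * b[i];
      }
    }
    for (int i = 0; i < n_comp; ++i) {
      int p = comp_parent[i];
      Vn[i] = p < 0 ? b[i] / a[i] : (b[i] + comp_gc[i] * Vn[p]) / a[i];
    }

    // 8. spike detection on somata + efferent delivery scheduling
    for (int c = 0; c < n_cell; ++c) {
      int sp = cell_soma[c];
      if (Vn[sp] >= thresh && V[sp] < thresh && step - last_spike[c] > refrac) {
        last_spike[c] = step;
        spike_cell.push_back(c + 1);
        spike_t.push_back((step + 1) * dt);
        for (int k = eff_ptr[c]; k < eff_ptr[c + 1]; ++k) {
          int s = eff_idx[k];
          ring[(step + sy_delay[s]) % (max_delay + 1)].push_back(s);
        }
      }
      if (Vn[sp] > 200.0 || Vn[sp] < -200.0 || !std::isfinite(Vn[sp]))
        stop("integration failure (|V| > 200 mV) in cell %d at t = %.2f ms",
             c + 1, (step + 1) * dt);
    }

    // 9. LFP and transmembrane-current recording
    if (lfp_bin > 0) {
      for (int i = 0; i < n_comp; ++i) {
        double itr = comp_C[i] * (Vn[i] - V[i]) * dt_inv +
                     (comp_gL[i] + G[i]) * Vn[i] -
                     (comp_gL[i] * comp_EL[i] + GE[i]);
        lfp_acc += comp_clfp[i] * itr;
        if (rec_i) ib_acc[i] += itr;
      }
      if ((step + 1) % lfp_bin == 0) {
        int bin = (step + 1) / lfp_bin - 1;
        if (bin < n_lfp) {
          lfp[bin] = lfp_acc / lfp_bin;
          if (rec_i) for (int i = 0; i < n_comp; ++i) ibin(i, bin) = ib_acc[i] / lfp_bin;
        }
        lfp_acc = 0.0;
        if (rec_i) std::fill(ib_acc.begin(), ib_acc.end(), 0.0);
      }
    }

    for (int k = 0; k < n_recv; ++k) vtrace(k, step) = Vn[rec_v[k]];
    std::swap(V, Vn);
  }

  return List::create(
    _["spike_cell"] = wrap(spike_cell),
    _["spike_time"] = wrap(spike_t),
    _["lfp"] = lfp,
    _["v"] = vtrace,
    _["i_binned"] = ibin,
    _["final_v"] = wrap(V));
}
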