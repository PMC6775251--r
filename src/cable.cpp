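// Cable-equation integrator for a reduced multicompartment conductance-based
// neuron. Semi-implicit theta-scheme (theta = 0.5, Crank-Nicolson-like) on the
// voltage with a Hines-ordered tree solve; Rush-Larsen exponential updates for
// Hodgkin-Huxley gates; exponential relaxation for the intracellular Ca2+ pool.
//
// Units: mV, ms, nA, uS, nF, mM. Channel densities arrive pre-multiplied by
// compartment area (total uS per compartment).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double VTAB_MIN = -130.0;
const double VTAB_MAX = 70.0;
const int VTAB_N = 8001; // 0.025 mV resolution

struct GateDef {
  int type;        // 0 = voltage gate, 1 = calcium gate
  double expn;     // gate exponent
  double vhalf, slope;
  int tau_shape;   // 0 constant, 1 gaussian bell, 2 sigmoid
  double tau_base, tau_amp, tau_vmax, tau_sigma;
  double ca_half, hill, ca_tau;
  double ca_rl;        // precomputed 1 - exp(-dt/ca_tau) for calcium gates
  bool hill_int;       // Hill exponent is a small integer
  // lookup tables on the voltage grid (voltage gates only)
  std::vector<double> inf_tab, rl_tab;
};

struct ChannelDef {
  std::vector<double> gbar;  // uS per compartment
  double erev;
  bool nernst_ca;
  bool is_ca;
  std::vector<int> gates;    // indices into gate list
  std::vector<int> comps;    // compartments with gbar > 0
};

inline double tau_of_v(const GateDef& g, double v) {
  double tau = g.tau_base;
  if (g.tau_shape == 1) {
    double z = (v - g.tau_vmax) / g.tau_sigma;
    tau += g.tau_amp * std::exp(-z * z);
  } else if (g.tau_shape == 2) {
    tau += g.tau_amp / (1.0 + std::exp((v - g.tau_vmax) / g.tau_sigma));
  }
  return tau > 1e-4 ? tau : 1e-4;
}

inline double vinf(const GateDef& g, double v) {
  return 1.0 / (1.0 + std::exp(-(v - g.vhalf) / g.slope));
}

void build_tables(GateDef& g, double dt) {
  if (g.type != 0) return;
  g.inf_tab.resize(VTAB_N);
  g.rl_tab.resize(VTAB_N);
  double step = (VTAB_MAX - VTAB_MIN) / (VTAB_N - 1);
  for (int i = 0; i < VTAB_N; ++i) {
    double v = VTAB_MIN + i * step;
    g.inf_tab[i] = vinf(g, v);
    g.rl_tab[i] = 1.0 - std::exp(-dt / tau_of_v(g, v));
  }
}

inline void table_lookup(const GateDef& g, double v, double& inf, double& rl) {
  double x = (v - VTAB_MIN) * ((VTAB_N - 1) / (VTAB_MAX - VTAB_MIN));
  if (x <= 0.0) { inf = g.inf_tab[0]; rl = g.rl_tab[0]; return; }
  if (x >= VTAB_N - 1) { inf = g.inf_tab[VTAB_N - 1]; rl = g.rl_tab[VTAB_N - 1]; return; }
  int i = (int)x;
  double f = x - i;
  inf = g.inf_tab[i] + f * (g.inf_tab[i + 1] - g.inf_tab[i]);
  rl = g.rl_tab[i] + f * (g.rl_tab[i + 1] - g.rl_tab[i]);
}

inline double ipow(double x, double n) {
  if (n == 1.0) return x;
  if (n == 2.0) return x * x;
  if (n == 3.0) return x * x * x;
  if (n == 4.0) { double y = x * x; return y * y; }
  return std::pow(x, n);
}

} // namespace

// [[Rcpp::export]]
List simulate_cable(List net, List chanlist, List calcium, NumericMatrix stim,
                    NumericMatrix syn_events, NumericMatrix syn_types,
                    double duration, double dt, IntegerVector record_idx,
                    int record_stride, double v_init, double theta) {
  IntegerVector parent = net["parent"];       // 0-based, root = -1, parent[i] < i
  NumericVector g_ax = net["g_axial"];        // uS to parent
  NumericVector cm = net["cm"];               // nF
  const int n = parent.size();

  // --- gates & channels -----------------------------------------------------
  std::vector<GateDef> gates;
  std::vector<ChannelDef> chans;
  for (int c = 0; c < chanlist.size(); ++c) {
    List ch = chanlist[c];
    ChannelDef cd;
    NumericVector gb = ch["gbar"];
    cd.gbar = std::vector<double>(gb.begin(), gb.end());
    cd.erev = as<double>(ch["erev"]);
    cd.nernst_ca = as<bool>(ch["nernst_ca"]);
    cd.is_ca = as<bool>(ch["is_ca"]);
    for (int i = 0; i < n; ++i) if (cd.gbar[i] > 0.0) cd.comps.push_back(i);
    List gl = ch["gates"];
    for (int k = 0; k < gl.size(); ++k) {
      List gk = gl[k];
      GateDef gd;
      gd.type = as<int>(gk["type"]);
      gd.expn = as<double>(gk["exponent"]);
      gd.vhalf = as<double>(gk["vhalf"]);
      gd.slope = as<double>(gk["slope"]);
      gd.tau_shape = as<int>(gk["tau_shape"]);
      gd.tau_base = as<double>(gk["tau_base"]);
      gd.tau_amp = as<double>(gk["tau_amp"]);
      gd.tau_vmax = as<double>(gk["tau_vmax"]);
      gd.tau_sigma = as<double>(gk["tau_sigma"]);
      gd.ca_half = as<double>(gk["ca_half"]);
      gd.hill = as<double>(gk["hill"]);
      gd.ca_tau = as<double>(gk["ca_tau"]);
      gd.ca_rl = 1.0 - std::exp(-dt / gd.ca_tau);
      gd.hill_int = (gd.hill == std::floor(gd.hill) && gd.hill <= 6.0);
      build_tables(gd, dt);
      cd.gates.push_back((int)gates.size());
      gates.push_back(gd);
    }
    chans.push_back(cd);
  }

  // --- calcium pool ---------------------------------------------------------
  double ca_gamma = as<double>(calcium["gamma"]);
  double ca_tau = as<double>(calcium["decay_tau"]);
  double ca_rest = as<double>(calcium["ca_rest"]);
  double ca_depth = as<double>(calcium["depth"]);
  double ca_out = as<double>(calcium["ca_out"]);
  NumericVector area = calcium["area"];          // cm^2, for current density
  LogicalVector has_ca = calcium["has_ca"];      // per compartment
  // dCa/dt (mM/ms) = -gamma * ICa(mA/cm^2) * 0.0518239 / depth_um
  double ca_flux = ca_gamma * 0.05182136 / ca_depth;
  double ca_decay_f = std::exp(-dt / ca_tau);

  // --- synapse receptor types ----------------------------------------------
  // syn_types rows: tau_rise, tau_decay, e_rev, mg_on, alpha_flag
  const int nrt = syn_types.nrow();
  std::vector<double> rt_fr(nrt), rt_fd(nrt), rt_norm(nrt), rt_erev(nrt);
  std::vector<int> rt_mg(nrt), rt_alpha(nrt);
  for (int r = 0; r < nrt; ++r) {
    double tr = syn_types(r, 0), td = syn_types(r, 1);
    rt_erev[r] = syn_types(r, 2);
    rt_mg[r] = (int)syn_types(r, 3);
    rt_alpha[r] = (int)syn_types(r, 4);
    if (rt_alpha[r]) {
      rt_fd[r] = std::exp(-dt / td);        // td holds the alpha tau
      rt_fr[r] = dt / td;
      rt_norm[r] = std::exp(1.0);           // impulse scale so peak = weight
    } else {
      rt_fd[r] = std::exp(-dt / td);
      rt_fr[r] = std::exp(-dt / tr);
      double tp = tr * td / (td - tr) * std::log(td / tr);
      rt_norm[r] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    }
  }
  // state per rtype per compartment
  std::vector<std::vector<double>> sA(nrt, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> sB(nrt, std::vector<double>(n, 0.0));
  const int nev = syn_events.nrow();  // cols: time, comp(0-based), rtype, weight(uS)
  int ev_ptr = 0;

  // --- state ----------------------------------------------------------------
  std::vector<double> V(n, v_init), Ca(n, ca_rest);
  std::vector<std::vector<double>> gstate(gates.size(), std::vector<double>(n));
  for (size_t c = 0; c < chans.size(); ++c)
    for (int gi : chans[c].gates) {
      GateDef& g = gates[gi];
      for (int i = 0; i < n; ++i)
        gstate[gi][i] = (g.type == 0) ? vinf(g, v_init)
                        : 1.0 / (1.0 + std::pow(g.ca_half / ca_rest, g.hill));
    }

  const int nsteps = (int)std::round(duration / dt);
  const int nrec = record_idx.size();
  const int nsamp = nsteps / record_stride + 1;
  NumericMatrix Vout(nsamp, nrec), Caout(nsamp, nrec);
  NumericVector tout(nsamp);
  int samp = 0;
  for (int r = 0; r < nrec; ++r) {
    Vout(0, r) = V[record_idx[r]];
    Caout(0, r) = Ca[record_idx[r]];
  }
  tout[0] = 0.0;
  samp = 1;

  std::vector<double> diag(n), rhs(n), Gtot(n), Snode(n);
  std::vector<double> Gca(n), Eca(n, 128.0);
  std::vector<double> up(n); // coupling to parent after theta weighting
  bool diverged = false;
  double t_diverge = NA_REAL;

  const double RTF2 = 13.3077; // RT/2F in mV at ~35.5 C

  for (int step = 1; step <= nsteps; ++step) {
    double t = step * dt;

    // synapse events scheduled within (t-dt, t] (each applied exactly once)
    while (ev_ptr < nev && syn_events(ev_ptr, 0) <= t + 1e-9) {
      int ic = (int)syn_events(ev_ptr, 1);
      int rt = (int)syn_events(ev_ptr, 2);
      double w = syn_events(ev_ptr, 3) * rt_norm[rt];
      sA[rt][ic] += w;
      if (!rt_alpha[rt]) sB[rt][ic] += w;
      ++ev_ptr;
    }
    // decay synaptic states
    for (int r = 0; r < nrt; ++r) {
      if (rt_alpha[r]) {
        for (int i = 0; i < n; ++i) {
          double a = sA[r][i], b = sB[r][i];
          if (a == 0.0 && b == 0.0) continue;
          sB[r][i] = rt_fd[r] * (b + a * rt_fr[r]);
          sA[r][i] = a * rt_fd[r];
        }
      } else {
        for (int i = 0; i < n; ++i) {
          sA[r][i] *= rt_fd[r];
          sB[r][i] *= rt_fr[r];
        }
      }
    }

    // Nernst Ca2+ reversal, one log per Ca2+-carrying compartment per step
    for (int i = 0; i < n; ++i) {
      if (!has_ca[i]) continue;
      double ca = Ca[i] > 1e-9 ? Ca[i] : 1e-9;
      Eca[i] = RTF2 * std::log(ca_out / ca);
    }

    // membrane conductances: update gates, accumulate G and G*E
    std::fill(Gtot.begin(), Gtot.end(), 0.0);
    std::fill(Snode.begin(), Snode.end(), 0.0);
    std::fill(Gca.begin(), Gca.end(), 0.0);
    for (size_t c = 0; c < chans.size(); ++c) {
      ChannelDef& cd = chans[c];
      for (int i : cd.comps) {
        double open = 1.0;
        for (int gi : cd.gates) {
          GateDef& g = gates[gi];
          double x = gstate[gi][i];
          if (g.type == 0) {
            // staggered update: gates live at half steps, advanced with V_n
            double inf, rl;
            table_lookup(g, V[i], inf, rl);
            x += (inf - x) * rl;
          } else {
            double ca = Ca[i] > 1e-9 ? Ca[i] : 1e-9;
            double r = g.ca_half / ca;
            double rh = g.hill_int ? ipow(r, g.hill) : std::pow(r, g.hill);
            double inf = 1.0 / (1.0 + rh);
            x += (inf - x) * g.ca_rl;
          }
          gstate[gi][i] = x;
          open *= ipow(x, g.expn);
        }
        double g_now = cd.gbar[i] * open;
        double e = cd.nernst_ca ? Eca[i] : cd.erev;
        Gtot[i] += g_now;
        Snode[i] += g_now * e;
        if (cd.is_ca) Gca[i] += g_now;
      }
    }
    // synaptic conductances (NMDA scaled by Mg block at previous V)
    for (int r = 0; r < nrt; ++r) {
      for (int i = 0; i < n; ++i) {
        double g_s = rt_alpha[r] ? sB[r][i] : (sA[r][i] - sB[r][i]);
        if (g_s <= 0.0) continue;
        if (rt_mg[r])
          g_s /= 1.0 + std::exp(-0.062 * V[i]) / 3.57; // Jahr-Stevens, 1 mM Mg
        Gtot[i] += g_s;
        Snode[i] += g_s * rt_erev[r];
      }
    }
    // injected currents
    for (int s = 0; s < stim.nrow(); ++s) {
      // cols: comp, kind(0 square/DC, 1 double-exp), onset, dur, amp, tau_r, tau_d
      double onset = stim(s, 2);
      if (t < onset) continue;
      int ic = (int)stim(s, 0);
      int kind = (int)stim(s, 1);
      if (kind == 0) {
        if (t <= onset + stim(s, 3)) Snode[ic] += stim(s, 4);
      } else {
        double tr = stim(s, 5), td = stim(s, 6);
        double tp = tr * td / (td - tr) * std::log(td / tr);
        double norm = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
        double dtau = t - onset;
        Snode[ic] += stim(s, 4) * norm *
          (std::exp(-dtau / td) - std::exp(-dtau / tr));
      }
    }

    // assemble theta-scheme tree system
    for (int i = 0; i < n; ++i) {
      double cdt = cm[i] / dt;
      diag[i] = cdt + theta * Gtot[i];
      // explicit part of membrane current at V_n
      rhs[i] = cdt * V[i] + Snode[i] - (1.0 - theta) * Gtot[i] * V[i];
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      double ga = g_ax[i];
      diag[i] += theta * ga;
      diag[p] += theta * ga;
      up[i] = -theta * ga;
      double iax = ga * (V[p] - V[i]); // explicit axial current into i
      rhs[i] += (1.0 - theta) * iax;
      rhs[p] -= (1.0 - theta) * iax;
    }
    // Hines elimination (children have larger indices than parents)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = up[i] / diag[i];
      diag[p] -= f * up[i];
      rhs[p] -= f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      V[i] = (rhs[i] - up[i] * V[p]) / diag[i];
    }

    // calcium update from the accumulated Ca2+-channel conductance at the
    // new voltage (reversal from the start of the step)
    for (int i = 0; i < n; ++i) {
      if (!has_ca[i] || Gca[i] == 0.0) {
        if (has_ca[i]) {
          double ca_inf = ca_rest;
          Ca[i] = ca_inf + (Ca[i] - ca_inf) * ca_decay_f;
        }
        continue;
      }
      double ica = Gca[i] * (V[i] - Eca[i]);         // nA
      double ica_dens = ica * 1e-6 / area[i];        // mA/cm^2 (neg inward)
      double influx = -ica_dens * ca_flux;           // mM/ms
      if (influx < 0.0) influx = 0.0;                // pump handles efflux
      double ca_inf = ca_rest + influx * ca_tau;
      Ca[i] = ca_inf + (Ca[i] - ca_inf) * ca_decay_f;
    }

    if (!std::isfinite(V[0]) || std::fabs(V[0]) > 400.0 ||
        !std::isfinite(V[n - 1]) || std::fabs(V[n - 1]) > 400.0) {
      diverged = true;
      t_diverge = t;
      break;
    }

    if (step % record_stride == 0 && samp < nsamp) {
      for (int r = 0; r < nrec; ++r) {
        Vout(samp, r) = V[record_idx[r]];
        Caout(samp, r) = Ca[record_idx[r]];
      }
      tout[samp] = t;
      ++samp;
    }
  }

  return List::create(_["time"] = tout, _["v"] = Vout, _["ca"] = Caout,
                      _["diverged"] = diverged, _["t_diverge"] = t_diverge,
                      _["n_samples"] = samp);
}
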