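// Implicit (theta-method) integrator for reduced compartmental cable models
// with Hodgkin-Huxley style channels defined by lookup tables.
//
// Unit conventions (fixed throughout the package):
//   voltage mV, time ms, capacitance nF, conductance uS, current nA,
//   channel densities S/cm^2, areas cm^2, synaptic amplitudes nS.
// With these, C[nF] * dV/dt [mV/ms] = I [nA] holds without scale factors.
//
// Gates advance by the exact exponential update
//   x <- xinf + (x - xinf) * exp(-dt / tau(V))
// using tables of xinf and exp(-dt/tau) sampled on a shared voltage grid;
// the membrane/cable equation is then solved implicitly (Hines elimination
// over the compartment tree) with conductances frozen across the step.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Gate {
  int power;
  std::vector<double> inf;   // on voltage grid
  std::vector<double> decay; // exp(-dt/tau) on voltage grid
  std::vector<double> state; // per active compartment
};

struct Channel {
  double erev;
  bool record;
  std::vector<int> comps;    // compartments with nonzero density
  std::vector<double> gabs;  // density * area * 1e6 -> uS per active comp
  std::vector<Gate> gates;
};

inline double interp(const std::vector<double>& tab, double u, int n) {
  if (u <= 0.0) return tab[0];
  if (u >= n - 1) return tab[n - 1];
  int i = (int)u;
  double f = u - i;
  return tab[i] + f * (tab[i + 1] - tab[i]);
}

} // namespace

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(List cable, List channels, List grid, List stim,
                  Nullable<List> syn_, double dt, double duration,
                  NumericVector v_init, double theta, double record_dt,
                  IntegerVector record_comps, double abort_v) {
  IntegerVector parent = cable["parent"];
  NumericVector area = cable["area"];
  NumericVector cm = cable["cm"];
  NumericVector g_ax = cable["g_axial"];
  const int ncomp = parent.size();

  const double v0 = as<double>(grid["v0"]);
  const double dv = as<double>(grid["dv"]);
  const int ngrid = as<int>(grid["n"]);

  // --- channels -> internal representation ------------------------------
  std::vector<Channel> ch;
  const int nch = channels.size();
  ch.reserve(nch);
  for (int c = 0; c < nch; ++c) {
    List cl = channels[c];
    Channel C;
    C.erev = as<double>(cl["erev"]);
    C.record = as<bool>(cl["record"]);
    NumericVector gbar = cl["gbar"];
    for (int i = 0; i < ncomp; ++i) {
      if (gbar[i] > 0.0) {
        C.comps.push_back(i);
        C.gabs.push_back(gbar[i] * area[i] * 1e6);
      }
    }
    List gates = cl["gates"];
    for (int g = 0; g < gates.size(); ++g) {
      List gl = gates[g];
      Gate G;
      G.power = as<int>(gl["power"]);
      NumericVector inf = gl["inf"], tau = gl["tau"];
      G.inf.assign(inf.begin(), inf.end());
      G.decay.resize(ngrid);
      for (int k = 0; k < ngrid; ++k) G.decay[k] = std::exp(-dt / tau[k]);
      G.state.assign(C.comps.size(), 0.0);
      C.gates.push_back(G);
    }
    ch.push_back(C);
  }

  // --- state ------------------------------------------------------------
  std::vector<double> V(ncomp);
  for (int i = 0; i < ncomp; ++i)
    V[i] = (v_init.size() == 1) ? v_init[0] : v_init[i];

  // gates start at steady state for the initial voltage
  for (auto& C : ch)
    for (auto& G : C.gates)
      for (size_t a = 0; a < C.comps.size(); ++a) {
        double u = (V[C.comps[a]] - v0) / dv;
        G.state[a] = interp(G.inf, u, ngrid);
      }

  std::vector<double> cap(ncomp);
  for (int i = 0; i < ncomp; ++i) cap[i] = cm[i] * area[i] * 1e3; // nF

  // --- stimulus ---------------------------------------------------------
  std::string mode = as<std::string>(stim["mode"]);
  NumericMatrix epochs = stim["epochs"]; // columns: value, duration
  const bool vclamp = (mode == "vclamp");
  double g_series = vclamp ? as<double>(stim["g_series"]) : 0.0;
  int stim_comp = stim.containsElementNamed("comp") ? as<int>(stim["comp"]) : 0;
  std::vector<double> ep_end(epochs.nrow());
  {
    double acc = 0.0;
    for (int e = 0; e < epochs.nrow(); ++e) {
      acc += epochs(e, 1);
      ep_end[e] = acc;
    }
    if (duration <= 0) duration = acc;
  }

  // --- synapses ---------------------------------------------------------
  bool has_syn = syn_.isNotNull();
  NumericVector sy_t, sy_amp;
  IntegerVector sy_kind, sy_comp;
  double e_rev_syn[2] = {0.0, -70.0};
  double rdec[2], ddec[2], fnorm[2];
  std::vector<double> A[2], B[2]; // per kind: rise/decay accumulators (nS)
  size_t ev = 0;
  if (has_syn) {
    List syn(syn_);
    sy_t = syn["time"];
    sy_amp = syn["amp"];
    sy_kind = syn["kind"];
    sy_comp = syn["comp"];
    NumericVector tr = syn["tau_rise"], td = syn["tau_decay"], er = syn["e_rev"];
    for (int k = 0; k < 2; ++k) {
      e_rev_syn[k] = er[k];
      rdec[k] = std::exp(-dt / tr[k]);
      ddec[k] = std::exp(-dt / td[k]);
      double tp = tr[k] * td[k] / (td[k] - tr[k]) * std::log(td[k] / tr[k]);
      fnorm[k] = 1.0 / (std::exp(-tp / td[k]) - std::exp(-tp / tr[k]));
      A[k].assign(ncomp, 0.0);
      B[k].assign(ncomp, 0.0);
    }
  }

  // --- recording --------------------------------------------------------
  const long nstep = (long)std::ceil(duration / dt - 1e-9);
  int every = record_dt > 0 ? std::max(1, (int)std::lround(record_dt / dt)) : 1;
  const long nrec = nstep / every + 1;
  NumericVector rt(nrec);
  NumericMatrix rV(nrec, record_comps.size());
  NumericVector rIclamp(vclamp ? nrec : 0);
  int nrecch = 0;
  for (auto& C : ch) nrecch += C.record ? 1 : 0;
  NumericMatrix rIch(nrec, nrecch);

  std::vector<double> diag(ncomp), off(ncomp), rhs(ncomp);
  bool diverged = false;
  long rk = 0;

  auto record_row = [&](long step, double t) {
    rt[rk] = t;
    for (int j = 0; j < record_comps.size(); ++j)
      rV(rk, j) = V[record_comps[j]];
    if (vclamp) {
      // command level at time t
      double cmd = epochs(epochs.nrow() - 1, 0);
      for (int e = 0; e < epochs.nrow(); ++e)
        if (t < ep_end[e] - 1e-9 || e == epochs.nrow() - 1) { cmd = epochs(e, 0); break; }
      // current injected by the electrode to hold the command; an outward
      // membrane current shows up as positive clamp current (nA)
      rIclamp[rk] = g_series * (cmd - V[stim_comp]);
    }
    int rc = 0;
    for (auto& C : ch) {
      if (!C.record) continue;
      double s = 0.0;
      for (size_t a = 0; a < C.comps.size(); ++a) {
        double gp = 1.0;
        for (auto& G : C.gates)
          for (int p = 0; p < G.power; ++p) gp *= G.state[a];
        s += C.gabs[a] * gp * (V[C.comps[a]] - C.erev);
      }
      rIch(rk, rc++) = s;
    }
    ++rk;
    (void)step;
  };
  record_row(0, 0.0);

  int cur_ep = 0;
  for (long step = 0; step < nstep && !diverged; ++step) {
    double t = step * dt;
    double tn = t + dt;
    while (cur_ep < epochs.nrow() - 1 && t >= ep_end[cur_ep] - 1e-9) ++cur_ep;
    double stim_val = epochs(cur_ep, 0);

    // synaptic events due in (t, tn]
    if (has_syn) {
      for (int k = 0; k < 2; ++k)
        for (int i = 0; i < ncomp; ++i) { A[k][i] *= rdec[k]; B[k][i] *= ddec[k]; }
      while (ev < (size_t)sy_t.size() && sy_t[ev] <= tn) {
        int k = sy_kind[ev], i = sy_comp[ev];
        A[k][i] += sy_amp[ev] * fnorm[k];
        B[k][i] += sy_amp[ev] * fnorm[k];
        ++ev;
      }
    }

    // advance gates with V(t), accumulate membrane conductance/driving terms
    std::fill(diag.begin(), diag.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    std::vector<double>& Gm = diag; // reuse: first accumulate G (uS) in diag
    std::vector<double>& Sm = rhs;  // and sum g*E (nA) in rhs
    for (auto& C : ch) {
      for (size_t a = 0; a < C.comps.size(); ++a) {
        int i = C.comps[a];
        double u = (V[i] - v0) / dv;
        double gp = 1.0;
        for (auto& G : C.gates) {
          double inf = interp(G.inf, u, ngrid);
          double dec = interp(G.decay, u, ngrid);
          double x = inf + (G.state[a] - inf) * dec;
          G.state[a] = x;
          for (int p = 0; p < G.power; ++p) gp *= x;
        }
        double g = C.gabs[a] * gp;
        Gm[i] += g;
        Sm[i] += g * C.erev;
      }
    }
    if (has_syn) {
      for (int k = 0; k < 2; ++k)
        for (int i = 0; i < ncomp; ++i) {
          double g = (B[k][i] - A[k][i]) * 1e-3; // nS -> uS
          if (g > 0.0) { Gm[i] += g; Sm[i] += g * e_rev_syn[k]; }
        }
    }
    if (vclamp) {
      Gm[stim_comp] += g_series;
      Sm[stim_comp] += g_series * stim_val;
    } else {
      Sm[stim_comp] += stim_val * 1e-3; // pA -> nA injected current
    }

    // assemble theta-method linear system (tree Hines solve)
    for (int i = 0; i < ncomp; ++i) {
      double G = Gm[i];
      double S = Sm[i];
      double a0 = cap[i] / dt;
      double d = a0 + theta * G;
      double b = a0 * V[i] + S - (1.0 - theta) * G * V[i];
      diag[i] = d;   // overwrite Gm storage
      rhs[i] = b;    // overwrite Sm storage
      off[i] = 0.0;
    }
    for (int i = 1; i < ncomp; ++i) {
      int p = parent[i];
      double ga = g_ax[i];
      if (ga <= 0.0) continue;
      double expl = (1.0 - theta) * ga * (V[p] - V[i]);
      rhs[i] += expl;
      rhs[p] -= expl;
      diag[i] += theta * ga;
      diag[p] += theta * ga;
      off[i] = -theta * ga;
    }
    for (int i = ncomp - 1; i >= 1; --i) {
      int p = parent[i];
      double f = off[i] / diag[i];
      diag[p] -= f * off[i];
      rhs[p] -= f * rhs[i];
    }
    V[0] = rhs[0] / diag[0];
    for (int i = 1; i < ncomp; ++i)
      V[i] = (rhs[i] - off[i] * V[parent[i]]) / diag[i];

    for (int i = 0; i < ncomp; ++i)
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > abort_v) diverged = true;

    if ((step + 1) % every == 0 && rk < nrec) record_row(step + 1, tn);
    if ((step & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
  }

  if (rk < nrec) { // divergence: truncate
    rt = rt[Range(0, std::max((long)1, rk) - 1)];
  }

  return List::create(_["time"] = rt, _["v"] = rV, _["i_clamp"] = rIclamp,
                      _["i_channel"] = rIch, _["diverged"] = diverged,
                      _["n_recorded"] = (double)rk);
}
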