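#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Branched-cable integrator.
//
// Solves C dV/dt = -g_L (V - E_L) - I_chan - I_syn + I_axial + I_bias + I_inj
// per compartment with a theta-rule (default Crank-Nicolson) implicit step and
// a Hines-ordered direct tree solve (parents precede children, one backward
// elimination pass plus one substitution pass per step, O(n)).
//
// Units: mV, ms, uS, nF, nA.  Conductances are held fixed over a step and
// evaluated from the previous step's voltages (staggered update): synaptic
// kinetic states are advanced analytically, the NMDA gating factor uses
// V from the previous step, and HH gating variables are advanced by one
// exponential update against the previous voltage.

static inline double nmda_gate(double v) {
  return 1.0 / (1.0 + 0.25 * std::exp(-0.08 * v));
}

// x/(exp(x/y)-1) with the removable singularity handled
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

struct HHRates {
  double am, bm, ah, bh, an, bn;
};

// Traub/Pospischil-style rates with spike-threshold parameter vt (ms^-1)
static inline HHRates hh_rates(double v, double vt) {
  HHRates r;
  double u = v - vt;
  r.am = 0.32 * vtrap(13.0 - u, 4.0);
  r.bm = 0.28 * vtrap(u - 40.0, 5.0);
  r.ah = 0.128 * std::exp(-(u - 17.0) / 18.0);
  r.bh = 4.0 / (1.0 + std::exp(-(u - 40.0) / 5.0));
  r.an = 0.032 * vtrap(15.0 - u, 5.0);
  r.bn = 0.5 * std::exp(-(u - 10.0) / 40.0);
  return r;
}

// slow non-inactivating K (M-like) steady state and time constant
static inline void ks_inf_tau(double v, double vhalf, double slope,
                              double taumax, double &pinf, double &ptau) {
  pinf = 1.0 / (1.0 + std::exp(-(v - vhalf) / slope));
  double x = (v - vhalf) / 20.0;
  ptau = taumax / (3.3 * std::exp(x) + std::exp(-x));
}

// [[Rcpp::export]]
List cpp_steady_gating(double v, double vt, double ks_vhalf, double ks_slope,
                       double ks_taumax) {
  HHRates r = hh_rates(v, vt);
  double pinf, ptau;
  ks_inf_tau(v, ks_vhalf, ks_slope, ks_taumax, pinf, ptau);
  return List::create(_["m"] = r.am / (r.am + r.bm),
                      _["h"] = r.ah / (r.ah + r.bh),
                      _["n"] = r.an / (r.an + r.bn),
                      _["p"] = pinf, _["p_tau"] = ptau);
}

// [[Rcpp::export]]
List cpp_integrate(int n,
                   IntegerVector parent,      // 0-based, -1 at root
                   NumericVector g_ax,        // uS, coupling to parent
                   NumericVector cap,         // nF
                   NumericVector g_leak,      // uS
                   NumericVector e_leak,      // mV
                   NumericVector i_bias,      // nA, constant balance current
                   NumericVector gna, NumericVector gkdr, NumericVector gks,
                   double ena, double ek, double vt,
                   double ks_vhalf, double ks_slope, double ks_taumax,
                   IntegerVector syn_comp,    // 0-based compartment per component
                   NumericVector syn_taur, NumericVector syn_taud,
                   NumericVector syn_erev, LogicalVector syn_is_nmda,
                   IntegerVector ev_syn,      // 0-based component index
                   IntegerVector ev_step,     // 1-based step of application
                   NumericVector ev_g,        // uS conductance increment (at peak)
                   bool ohmic, double ohmic_vm,
                   IntegerVector inj_comp, IntegerVector inj_from,
                   IntegerVector inj_to, NumericVector inj_amp,
                   int clamp_comp, double clamp_v,
                   double v0, double dt, int n_steps,
                   IntegerVector rec_idx, double theta) {

  const int ns = syn_comp.size();
  const int nev = ev_syn.size();
  const int ninj = inj_comp.size();
  const int nrec = rec_idx.size();

  std::vector<double> v(n, v0), vnew(n);
  if (clamp_comp >= 0) v[clamp_comp] = clamp_v;

  // synapse kinetic states: sA decays with tau_decay, sB with tau_rise
  std::vector<double> sA(ns, 0.0), sB(ns, 0.0);
  std::vector<double> decA(ns), decB(ns), norm(ns);
  std::vector<bool> dual(ns);
  for (int s = 0; s < ns; ++s) {
    double td = syn_taud[s], tr = syn_taur[s];
    decA[s] = std::exp(-dt / td);
    dual[s] = tr > 0.0;
    if (dual[s]) {
      decB[s] = std::exp(-dt / tr);
      double tp = std::log(td / tr) * td * tr / (td - tr);
      norm[s] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
    } else {
      decB[s] = 0.0;
      norm[s] = 1.0;
    }
  }

  // gating state, initialised at steady state for v0
  std::vector<bool> has_chan(n, false);
  std::vector<double> gm(n), gh(n), gn_(n), gp(n);
  for (int i = 0; i < n; ++i) {
    if (gna[i] > 0 || gkdr[i] > 0 || gks[i] > 0) {
      has_chan[i] = true;
      HHRates r = hh_rates(v[i], vt);
      gm[i] = r.am / (r.am + r.bm);
      gh[i] = r.ah / (r.ah + r.bh);
      gn_[i] = r.an / (r.an + r.bn);
      double pinf, ptau;
      ks_inf_tau(v[i], ks_vhalf, ks_slope, ks_taumax, pinf, ptau);
      gp[i] = pinf;
    }
  }

  NumericMatrix v_rec(n_steps + 1, nrec);
  NumericVector i_clamp(clamp_comp >= 0 ? n_steps + 1 : 0);
  for (int r = 0; r < nrec; ++r) v_rec(0, r) = v[rec_idx[r]];

  std::vector<double> gsum(n), gesum(n), d(n), rhs(n), offd(n);
  const double cdt = 1.0 / dt;

  int ev_ptr = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // --- synaptic states: decay, then apply this step's release events
    for (int s = 0; s < ns; ++s) {
      sA[s] *= decA[s];
      if (dual[s]) sB[s] *= decB[s];
    }
    while (ev_ptr < nev && ev_step[ev_ptr] == step) {
      int s = ev_syn[ev_ptr];
      double a = ev_g[ev_ptr] * norm[s];
      sA[s] += a;
      if (dual[s]) sB[s] += a;
      ++ev_ptr;
    }

    // --- per-compartment conductance/current accumulation
    for (int i = 0; i < n; ++i) { gsum[i] = 0.0; gesum[i] = 0.0; }
    for (int s = 0; s < ns; ++s) {
      double g = dual[s] ? (sA[s] - sB[s]) : sA[s];
      if (g <= 0.0) continue;
      int c = syn_comp[s];
      if (syn_is_nmda[s]) g *= nmda_gate(ohmic ? ohmic_vm : v[c]);
      gsum[c] += g;
      gesum[c] += g * syn_erev[s];
    }
    for (int i = 0; i < n; ++i) {
      if (!has_chan[i]) continue;
      HHRates r = hh_rates(v[i], vt);
      double tm = 1.0 / (r.am + r.bm), th = 1.0 / (r.ah + r.bh),
             tn = 1.0 / (r.an + r.bn);
      gm[i] += (r.am * tm - gm[i]) * (1.0 - std::exp(-dt / tm));
      gh[i] += (r.ah * th - gh[i]) * (1.0 - std::exp(-dt / th));
      gn_[i] += (r.an * tn - gn_[i]) * (1.0 - std::exp(-dt / tn));
      double pinf, ptau;
      ks_inf_tau(v[i], ks_vhalf, ks_slope, ks_taumax, pinf, ptau);
      gp[i] += (pinf - gp[i]) * (1.0 - std::exp(-dt / ptau));
      double gna_e = gna[i] * gm[i] * gm[i] * gm[i] * gh[i];
      double gk_e = gkdr[i] * gn_[i] * gn_[i] * gn_[i] * gn_[i] + gks[i] * gp[i];
      gsum[i] += gna_e + gk_e;
      gesum[i] += gna_e * ena + gk_e * ek;
    }

    // --- assemble theta-rule system
    for (int i = 0; i < n; ++i) {
      double gmemb = g_leak[i] + gsum[i];
      double be = g_leak[i] * e_leak[i] + gesum[i] + i_bias[i];
      d[i] = cap[i] * cdt + theta * gmemb;
      rhs[i] = cap[i] * cdt * v[i] - (1.0 - theta) * gmemb * v[i] + be;
      offd[i] = 0.0;
    }
    for (int k = 0; k < ninj; ++k) {
      if (step >= inj_from[k] && step <= inj_to[k]) rhs[inj_comp[k]] += inj_amp[k];
    }
    for (int i = 1; i < n; ++i) {
      int p = parent[i];
      double g = g_ax[i];
      d[i] += theta * g;
      d[p] += theta * g;
      offd[i] = -theta * g;
      double ax = (1.0 - theta) * g * (v[p] - v[i]);
      rhs[i] += ax;
      rhs[p] -= ax;
    }

    if (clamp_comp >= 0) {
      int c = clamp_comp;
      // transfer the known clamped voltage into neighbouring equations
      if (c > 0) {
        int p = parent[c];
        rhs[p] -= offd[c] * clamp_v;
        offd[c] = 0.0;
      }
      for (int i = c + 1; i < n; ++i) {
        if (parent[i] == c) {
          rhs[i] -= offd[i] * clamp_v;
          offd[i] = 0.0;
        }
      }
      d[c] = 1.0;
      rhs[c] = clamp_v;
    }

    // --- Hines elimination (leaves toward root) and back substitution
    for (int i = n - 1; i >= 1; --i) {
      if (offd[i] == 0.0) continue;
      int p = parent[i];
      double f = offd[i] / d[i];
      d[p] -= f * offd[i];
      rhs[p] -= f * rhs[i];
    }
    vnew[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) {
      vnew[i] = (rhs[i] - offd[i] * vnew[parent[i]]) / d[i];
    }

    if (clamp_comp >= 0) {
      int c = clamp_comp;
      double gmemb = g_leak[c] + gsum[c];
      double be = g_leak[c] * e_leak[c] + gesum[c] + i_bias[c];
      double iinj = 0.0;
      for (int k = 0; k < ninj; ++k)
        if (inj_comp[k] == c && step >= inj_from[k] && step <= inj_to[k])
          iinj += inj_amp[k];
      double ax = 0.0;
      if (c > 0) ax += g_ax[c] * (vnew[parent[c]] - clamp_v);
      for (int i = c + 1; i < n; ++i)
        if (parent[i] == c) ax += g_ax[i] * (vnew[i] - clamp_v);
      // electrode current required to hold the command voltage
      i_clamp[step] = gmemb * clamp_v - be - iinj - ax;
      vnew[c] = clamp_v;
    }

    bool bad = false;
    for (int i = 0; i < n; ++i) {
      v[i] = vnew[i];
      if (!std::isfinite(v[i])) bad = true;
    }
    if (bad) {
      stop("integration diverged (non-finite voltage) at t = %f ms",
           step * dt);
    }
    for (int r = 0; r < nrec; ++r) v_rec(step, r) = v[rec_idx[r]];
  }

  return List::create(_["v"] = v_rec, _["i_clamp"] = i_clamp);
}
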