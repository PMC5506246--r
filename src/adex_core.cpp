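#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// AdEx parameter vector layout (fixed order, see adex_param_vector() in R):
// 0:C[pF] 1:g_L[nS] 2:E_L[mV] 3:V_T[mV] 4:V_peak[mV] 5:eta[mV]
// 6:a[nS] 7:b[pA] 8:V_r[mV] 9:tau_q[ms]

// Forward-Euler update of (V, q). The exponential argument is clamped at
// (V_peak - V_T)/eta + 5: beyond that V has already crossed V_peak so the
// clamp cannot change any spike time, it only prevents overflow.
static inline void euler_step(double &V, double &q, double I, double dt,
                              double C, double gL, double EL, double VT,
                              double eta, double a, double tq,
                              double exp_clamp) {
  double arg = (V - VT) / eta;
  if (arg > exp_clamp) arg = exp_clamp;
  double dV = (-gL * (V - EL) + gL * eta * std::exp(arg) - q + I) / C;
  double dq = (a * (V - EL) - q) / tq;
  V += dt * dV;
  q += dt * dq;
}

// Integrate a single AdEx neuron for `horizon` ms at step `dt`.
// Drive is the sum of (a) an externally supplied current series I_ext
// (length n_steps, pA; may be length 0 for none) and (b) an excitatory
// conductance-based synapse receiving presynaptic spikes `pre_spikes` (ms)
// each incrementing g_exc by `w` (nS), decaying with tau_e and reversal E_e.
// A spike whose time falls in step k is delivered at the start of step k+1
// (one-step axonal delay, matching the network integrator).
// [[Rcpp::export]]
List adex_integrate_cpp(NumericVector p, double dt, double horizon,
                        NumericVector I_ext, NumericVector pre_spikes,
                        double w, double tau_e, double E_e,
                        bool record) {
  const double C = p[0], gL = p[1], EL = p[2], VT = p[3], Vpeak = p[4],
               eta = p[5], a = p[6], b = p[7], Vr = p[8], tq = p[9];
  const double exp_clamp = (Vpeak - VT) / eta + 5.0;
  const int n_steps = (int)std::lround(horizon / dt);
  const bool has_I = I_ext.size() > 0;
  const bool has_pre = pre_spikes.size() > 0;
  const double decay_e = std::exp(-dt / tau_e);

  // presynaptic increments bucketed by delivery step
  std::vector<double> incr;
  if (has_pre) {
    incr.assign(n_steps + 1, 0.0);
    for (int s = 0; s < pre_spikes.size(); ++s) {
      // delivered in the step starting at the first grid time >= spike time
      // (for a spike stamped on a step boundary this is the network's
      // one-step delay: it fired during the preceding step)
      int k = (int)std::ceil(pre_spikes[s] / dt - 1e-9);
      if (k >= 0 && k <= n_steps) incr[k] += w;
    }
  }

  double V = EL, q = 0.0, g = 0.0;
  std::vector<double> spikes;
  NumericVector Vtr, qtr, gtr;
  if (record) { Vtr = NumericVector(n_steps + 1); qtr = NumericVector(n_steps + 1);
                gtr = NumericVector(n_steps + 1);
                Vtr[0] = V; qtr[0] = q; gtr[0] = g; }

  for (int k = 0; k < n_steps; ++k) {
    if (has_pre && incr[k] > 0.0) g += incr[k];
    double I = 0.0;
    if (has_I) I += I_ext[k];
    if (has_pre) I += g * (E_e - V);
    euler_step(V, q, I, dt, C, gL, EL, VT, eta, a, tq, exp_clamp);
    if (V >= Vpeak) {                      // threshold test after the update
      V = Vr; q += b;
      spikes.push_back((k + 1) * dt);
    }
    if (has_pre) g *= decay_e;
    if (record) { Vtr[k + 1] = V; qtr[k + 1] = q; gtr[k + 1] = g; }
  }

  List out = List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()));
  if (record) {
    out["V"] = Vtr; out["q"] = qtr; out["g_exc"] = gtr;
    NumericVector tt(n_steps + 1);
    for (int k = 0; k <= n_steps; ++k) tt[k] = k * dt;
    out["time"] = tt;
  }
  return out;
}

// Full two-layer trial. FEF neurons receive the spatial-temporal external
// current I0 * exp(-(u_n-u_T)^2 / (2 sigma^2)) * t^gamma * exp(-beta t) and
// no synapses; SC neurons receive conductance-based input: one-to-one
// feedforward from their FEF partner (weight w_ff[n], nS) plus, if
// `lateral`, recurrent excitation/inhibition through W_exc / W_inh (nS,
// zero diagonal). Conductances decay exponentially (exact per-step factor)
// and jump instantly one step after each presynaptic spike.
// [[Rcpp::export]]
List network_sim_cpp(NumericVector u, double uT, NumericVector inp,
                     NumericVector fef_p, NumericVector sc_p,
                     NumericVector sc_tau_q, NumericVector w_ff,
                     NumericVector syn, NumericMatrix W_exc,
                     NumericMatrix W_inh, bool lateral,
                     double dt, double horizon, int guard) {
  const int N = u.size();
  const int n_steps = (int)std::lround(horizon / dt);
  const double I0 = inp[0], sigma = inp[1], beta = inp[2], gamma = inp[3];
  const double Ee = syn[0], Ei = syn[1], tau_e = syn[2], tau_i = syn[3];
  const double de = std::exp(-dt / tau_e), di = std::exp(-dt / tau_i);

  // FEF params
  const double fC = fef_p[0], fgL = fef_p[1], fEL = fef_p[2], fVT = fef_p[3],
               fVpk = fef_p[4], feta = fef_p[5], fa = fef_p[6], fb = fef_p[7],
               fVr = fef_p[8], ftq = fef_p[9];
  const double f_clamp = (fVpk - fVT) / feta + 5.0;
  // SC params (tau_q per neuron)
  const double sC = sc_p[0], sgL = sc_p[1], sEL = sc_p[2], sVT = sc_p[3],
               sVpk = sc_p[4], seta = sc_p[5], sa = sc_p[6], sb = sc_p[7],
               sVr = sc_p[8];
  const double s_clamp = (sVpk - sVT) / seta + 5.0;

  std::vector<double> spatial(N);
  for (int n = 0; n < N; ++n) {
    double d = u[n] - uT;
    spatial[n] = I0 * std::exp(-d * d / (2.0 * sigma * sigma));
  }

  std::vector<double> fV(N, fEL), fq(N, 0.0);
  std::vector<double> sV(N, sEL), sq(N, 0.0);
  std::vector<double> gE(N, 0.0), gI(N, 0.0);
  std::vector<int> fef_pending, sc_pending;  // spikes from the current step
  std::vector<std::vector<double> > fef_spk(N), sc_spk(N);
  std::vector<int> sc_count(N, 0);

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    const double temporal = (t > 0.0)
        ? std::pow(t, gamma) * std::exp(-beta * t) : 0.0;

    // deliver the previous step's spikes to the SC conductances before the
    // state update: one-step delay, the minimal causal convention
    for (size_t j = 0; j < fef_pending.size(); ++j) {
      int n = fef_pending[j];
      gE[n] += w_ff[n];
    }
    if (lateral) {
      for (size_t j = 0; j < sc_pending.size(); ++j) {
        int i = sc_pending[j];
        for (int n = 0; n < N; ++n) {
          gE[n] += W_exc(i, n);
          gI[n] += W_inh(i, n);
        }
      }
    }
    fef_pending.clear();
    sc_pending.clear();

    // FEF layer: external current only
    for (int n = 0; n < N; ++n) {
      double I = spatial[n] * temporal;
      euler_step(fV[n], fq[n], I, dt, fC, fgL, fEL, fVT, feta, fa, ftq, f_clamp);
      if (fV[n] >= fVpk) {
        fV[n] = fVr; fq[n] += fb;
        fef_spk[n].push_back((k + 1) * dt);
        fef_pending.push_back(n);
      }
    }

    // SC layer: conductance-based synaptic current
    for (int n = 0; n < N; ++n) {
      double I = gE[n] * (Ee - sV[n]) + gI[n] * (Ei - sV[n]);
      euler_step(sV[n], sq[n], I, dt, sC, sgL, sEL, sVT, seta, sa,
                 sc_tau_q[n], s_clamp);
      if (sV[n] >= sVpk) {
        sV[n] = sVr; sq[n] += sb;
        sc_spk[n].push_back((k + 1) * dt);
        sc_pending.push_back(n);
        if (++sc_count[n] > guard)
          stop("runaway activity: SC neuron %d exceeded %d spikes "
               "(unbalanced lateral weights?)", n + 1, guard);
      }
    }

    for (int n = 0; n < N; ++n) { gE[n] *= de; gI[n] *= di; }
  }

  List fef(N), sc(N);
  for (int n = 0; n < N; ++n) {
    fef[n] = NumericVector(fef_spk[n].begin(), fef_spk[n].end());
    sc[n] = NumericVector(sc_spk[n].begin(), sc_spk[n].end());
  }
  return List::create(_["fef"] = fef, _["sc"] = sc);
}
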