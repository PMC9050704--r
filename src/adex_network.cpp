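#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Column order of the per-neuron parameter matrices (one row per neuron).
// Kept in step with adex_param_matrix() on the R side.
enum ParCol {
  P_C = 0, P_GL, P_EL, P_VT, P_DT, P_A, P_B, P_TAUQ,
  P_VRESET, P_VCUT, P_TREF, P_EEXC, P_EINH, P_TSE, P_TSI, P_TFF,
  P_NCOL
};

struct Layer {
  int n;
  std::vector<double> V, q, gexc, ginh, gff, tlast;
  const NumericMatrix par;
  std::vector<double> dec_e, dec_i, dec_f; // per-step conductance decay factors

  Layer(const NumericMatrix& par_, double dt) : n(par_.nrow()), par(par_) {
    V.assign(n, 0.0); q.assign(n, 0.0);
    gexc.assign(n, 0.0); ginh.assign(n, 0.0); gff.assign(n, 0.0);
    tlast.assign(n, -1e18);
    dec_e.resize(n); dec_i.resize(n); dec_f.resize(n);
    for (int i = 0; i < n; ++i) {
      V[i] = par(i, P_EL);
      dec_e[i] = std::exp(-dt / par(i, P_TSE));
      dec_i[i] = std::exp(-dt / par(i, P_TSI));
      dec_f[i] = std::exp(-dt / par(i, P_TFF));
    }
  }

  // Advance neuron i by dt under external current Iext; returns true on spike.
  // Linearized exponential-Euler on V: the conductance/leak part is integrated
  // exactly over the step (unconditionally stable however large the synaptic
  // conductances get), the spike-initiation exponential is treated explicitly
  // with its argument clamped at +10 slope factors. Forward Euler on q. The
  // spike is stamped at the start time t of the step in which V crossed Vcut.
  bool step(int i, double t, double dt, double Iext, bool& bad) {
    const double C = par(i, P_C), gL = par(i, P_GL), EL = par(i, P_EL),
                 VT = par(i, P_VT), DT = par(i, P_DT), a = par(i, P_A),
                 tauq = par(i, P_TAUQ), tref = par(i, P_TREF);
    if (t - tlast[i] < tref - 1e-12) {
      // refractory clamp: V held at reset, adaptation keeps evolving
      V[i] = par(i, P_VRESET);
      q[i] += dt * (a * (V[i] - EL) - q[i]) / tauq;
      return false;
    }
    double expo = (V[i] - VT) / DT;
    if (expo > 10.0) expo = 10.0;
    const double G = gL + gexc[i] + ginh[i] + gff[i];
    const double A = gL * EL + gL * DT * std::exp(expo) +
                     (gexc[i] + gff[i]) * par(i, P_EEXC) +
                     ginh[i] * par(i, P_EINH) - q[i] + Iext;
    const double Vinf = A / G;
    const double dq = (a * (V[i] - EL) - q[i]) / tauq;
    V[i] = Vinf + (V[i] - Vinf) * std::exp(-G * dt / C);
    q[i] += dt * dq;
    if (!std::isfinite(V[i]) || !std::isfinite(q[i])) { bad = true; return false; }
    if (V[i] >= par(i, P_VCUT)) {
      V[i] = par(i, P_VRESET);
      q[i] += par(i, P_B);
      tlast[i] = t;
      return true;
    }
    return false;
  }

  void decay_conductances() {
    for (int i = 0; i < n; ++i) {
      gexc[i] *= dec_e[i]; ginh[i] *= dec_i[i]; gff[i] *= dec_f[i];
    }
  }
};

// Two-layer simulation. The input layer is driven by the separable external
// current (spatial profile x temporal profile), passed through a saturating
// sigmoid (rate cap); it has no recurrent synapses. Input spikes arrive on the
// SC layer through one-to-one feedforward conductances wFS onto a dedicated
// fast excitatory channel (decay P_TFF); SC spikes are broadcast through the
// routed lateral weight matrices (row = source neuron).
// All deliveries happen at the end of the step in which the spike occurred
// (zero axonal delay).
// [[Rcpp::export]]
List simulate_network_cpp(NumericMatrix par_input, NumericMatrix par_sc,
                          NumericVector spatial_pA, NumericVector temporal_unit,
                          double I_sat,
                          NumericVector wFS,
                          NumericMatrix W_exc_routed, NumericMatrix W_inh_routed,
                          double dt, IntegerVector monitor_sc) {
  const int n = par_input.nrow();
  const int n_steps = temporal_unit.size();
  if (par_sc.nrow() != n || spatial_pA.size() != n || wFS.size() != n ||
      W_exc_routed.nrow() != n || W_exc_routed.ncol() != n ||
      W_inh_routed.nrow() != n || W_inh_routed.ncol() != n)
    stop("simulate_network_cpp: inconsistent dimensions");

  Layer inp(par_input, dt), sc(par_sc, dt);

  std::vector<int> spk_in_id, spk_sc_id;
  std::vector<double> spk_in_t, spk_sc_t;
  std::vector<int> fired;
  fired.reserve(n);

  const int n_mon = monitor_sc.size();
  NumericMatrix Vmon(n_mon > 0 ? n_steps : 0, n_mon);

  bool bad = false;
  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    const double gt = temporal_unit[k];

    // input layer: external drive with saturating sigmoid cap
    fired.clear();
    for (int i = 0; i < n; ++i) {
      double drive = spatial_pA[i] * gt;
      if (I_sat > 0) drive = I_sat * std::tanh(drive / I_sat);
      if (inp.step(i, t, dt, drive, bad)) fired.push_back(i);
      if (bad) stop("simulate_network_cpp: non-finite state in input layer at t = %f ms", t);
    }

    // SC layer: synaptic drive only
    std::vector<int> sc_fired;
    for (int i = 0; i < n; ++i) {
      if (sc.step(i, t, dt, 0.0, bad)) sc_fired.push_back(i);
      if (bad) stop("simulate_network_cpp: non-finite state in SC layer at t = %f ms", t);
    }

    for (int m = 0; m < n_mon; ++m) Vmon(k, m) = sc.V[monitor_sc[m] - 1];

    // record + deliver input-layer spikes (one-to-one feedforward)
    for (int i : fired) {
      spk_in_id.push_back(i + 1); spk_in_t.push_back(t);
      sc.gff[i] += wFS[i];
    }
    // record + deliver SC spikes through the lateral matrices
    for (int i : sc_fired) {
      spk_sc_id.push_back(i + 1); spk_sc_t.push_back(t);
      for (int j = 0; j < n; ++j) {
        sc.gexc[j] += W_exc_routed(i, j);
        sc.ginh[j] += W_inh_routed(i, j);
      }
    }

    inp.decay_conductances();
    sc.decay_conductances();
  }

  List out = List::create(
    _["input_neuron"] = wrap(spk_in_id), _["input_t"] = wrap(spk_in_t),
    _["sc_neuron"] = wrap(spk_sc_id), _["sc_t"] = wrap(spk_sc_t));
  if (n_mon > 0) out["V_sc"] = Vmon;
  return out;
}
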