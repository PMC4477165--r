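#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All quantities SI: V, A, S, F, s, Hz.

// ---------------------------------------------------------------------------
// Ornstein-Uhlenbeck path, Euler-Maruyama.
// gbar/gs may be length 1 (stationary) or length n (per-step target moments,
// e.g. under sinusoidal rate modulation). noise: standard-normal draws.
// Returns the state after each of the n updates, starting from g0.
// [[Rcpp::export]]
NumericVector cpp_ou_path(NumericVector noise, double dt, NumericVector gbar,
                          NumericVector gs, double tau, double g0) {
  int n = noise.size();
  NumericVector out(n);
  bool mod = gbar.size() > 1;
  double g = g0;
  for (int i = 0; i < n; ++i) {
    double m = mod ? gbar[i] : gbar[0];
    double s = (gs.size() > 1) ? gs[i] : gs[0];
    double D = s * s / tau;
    g += dt * (m - g) / tau + std::sqrt(2.0 * D * dt) * noise[i];
    out[i] = g;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hodgkin-Huxley (1952 squid, rest ~ -65 mV) rate functions; V in mV, 1/ms.
static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) with the x -> 0 limit handled
  double e = x / y;
  if (std::fabs(e) < 1e-6) return y * (1.0 - e / 2.0);
  return x / (1.0 - std::exp(-e));
}

struct Gates { double m, h, n; };

static void hh_rates(double Vm, double *am, double *bm, double *ah, double *bh,
                     double *an, double *bn) {
  *am = 0.1 * vtrap(Vm + 40.0, 10.0);
  *bm = 4.0 * std::exp(-(Vm + 65.0) / 18.0);
  *ah = 0.07 * std::exp(-(Vm + 65.0) / 20.0);
  *bh = 1.0 / (1.0 + std::exp(-(Vm + 35.0) / 10.0));
  *an = 0.01 * vtrap(Vm + 55.0, 10.0);
  *bn = 0.125 * std::exp(-(Vm + 65.0) / 80.0);
}

// Reduced Traub-Miles (Ermentrout-Kopell form); V in mV, rates 1/ms.
static void rtm_rates(double Vm, double *am, double *bm, double *ah, double *bh,
                      double *an, double *bn) {
  *am = 0.32 * vtrap(Vm + 54.0, 4.0);
  *bm = 0.28 * vtrap(-(Vm + 27.0), 5.0);
  *ah = 0.128 * std::exp(-(Vm + 50.0) / 18.0);
  *bh = 4.0 / (1.0 + std::exp(-(Vm + 27.0) / 5.0));
  *an = 0.032 * vtrap(Vm + 52.0, 5.0);
  *bn = 0.5 * std::exp(-(Vm + 57.0) / 40.0);
}

static Gates steady_gates(double Vm, bool rtm) {
  double am, bm, ah, bh, an, bn;
  if (rtm) rtm_rates(Vm, &am, &bm, &ah, &bh, &an, &bn);
  else hh_rates(Vm, &am, &bm, &ah, &bh, &an, &bn);
  Gates g;
  g.m = am / (am + bm);
  g.h = ah / (ah + bh);
  g.n = an / (an + bn);
  return g;
}

// ---------------------------------------------------------------------------
// Fixed-step Euler simulation of one point or conductance-based neuron.
// kind: "lif", "qif", "aeif", "hh", "rtm", "passive".
// I_ext, Ge, Gi: length 0 or 1 (constant) or n (per step). Conductances are
// clipped to >= 0 at injection; the synaptic current uses the instantaneous V.
// Returns V trace (if record_v), 1-based spike step indices, final state.
// [[Rcpp::export]]
List cpp_simulate_neuron(std::string kind, List params, int n, double dt,
                         NumericVector I_ext, NumericVector Ge,
                         NumericVector Gi, double Ee, double Ei,
                         double V0, bool record_v) {
  double C  = as<double>(params["C"]);
  double gL = as<double>(params["g_L"]);
  double EL = as<double>(params["E_L"]);

  bool is_lif = kind == "lif", is_qif = kind == "qif", is_aeif = kind == "aeif";
  bool is_hh = kind == "hh", is_rtm = kind == "rtm", is_pass = kind == "passive";
  if (!(is_lif || is_qif || is_aeif || is_hh || is_rtm || is_pass))
    stop("unknown neuron kind '%s'", kind.c_str());

  double Vth = 0, Vreset = 0, tref = 0, DeltaT = 0, a = 0, b = 0, tauw = 1, Vc = 0;
  double gNa = 0, gK = 0, ENa = 0, EK = 0;
  if (is_lif || is_qif || is_aeif) {
    Vth = as<double>(params["V_thresh"]);
    Vreset = as<double>(params["V_reset"]);
    tref = as<double>(params["t_ref"]);
  }
  if (is_aeif) {
    DeltaT = as<double>(params["Delta_T"]);
    a = as<double>(params["a"]);
    b = as<double>(params["b"]);
    tauw = as<double>(params["tau_w"]);
  }
  if (is_qif) Vc = as<double>(params["V_crit"]);
  if (is_hh || is_rtm) {
    gNa = as<double>(params["g_Na"]);
    gK  = as<double>(params["g_K"]);
    ENa = as<double>(params["E_Na"]);
    EK  = as<double>(params["E_K"]);
  }

  double V = V0, w = 0;
  if (is_aeif && params.containsElementNamed("w0")) w = as<double>(params["w0"]);
  Gates g;
  if (is_hh || is_rtm) g = steady_gates(V0 * 1e3, is_rtm);

  NumericVector Vout(record_v ? n : 0);
  std::vector<int> spikes;
  int ref_steps = (int)std::floor(tref / dt + 0.5);
  int ref_left = 0;
  // conductance-model spike detector: upward crossing of 0 mV, 2 ms lockout
  int lockout_steps = (int)std::floor(0.002 / dt + 0.5), lockout = 0;
  double Vprev = V;
  // aEIF numerical spike threshold
  double Vspk = is_aeif ? Vth + 5.0 * DeltaT : Vth;

  bool Ie1 = I_ext.size() <= 1, Ge1 = Ge.size() <= 1, Gi1 = Gi.size() <= 1;
  double Ie0 = I_ext.size() ? I_ext[0] : 0.0;
  double Ge0 = Ge.size() ? Ge[0] : 0.0;
  double Gi0 = Gi.size() ? Gi[0] : 0.0;

  for (int i = 0; i < n; ++i) {
    double Iex = Ie1 ? Ie0 : I_ext[i];
    double ge = Ge1 ? Ge0 : Ge[i];
    double gi = Gi1 ? Gi0 : Gi[i];
    if (ge < 0) ge = 0;
    if (gi < 0) gi = 0;
    double Iin = Iex + ge * (Ee - V) + gi * (Ei - V);
    bool spiked = false;

    if (is_pass) {
      V += dt * (-gL * (V - EL) + Iin) / C;
    } else if (is_lif) {
      if (ref_left > 0) { --ref_left; V = Vreset; }
      else {
        V += dt * (-gL * (V - EL) + Iin) / C;
        if (V >= Vth) { spiked = true; V = Vreset; ref_left = ref_steps; }
      }
    } else if (is_qif) {
      if (ref_left > 0) { --ref_left; V = Vreset; }
      else {
        double drive = gL * (V - EL) * (V - Vc) / (Vc - EL);
        V += dt * (drive + Iin) / C;
        if (V >= Vth) { spiked = true; V = Vreset; ref_left = ref_steps; }
      }
    } else if (is_aeif) {
      double wprev = w;
      w += dt * (a * (V - EL) - wprev) / tauw;
      if (ref_left > 0) { --ref_left; V = Vreset; }
      else {
        double ex = (V - Vth) / DeltaT;
        if (ex > 10.0) ex = 10.0;  // bounded: spike fires before this matters
        V += dt * (-gL * (V - EL) + gL * DeltaT * std::exp(ex) - wprev + Iin) / C;
        if (V >= Vspk) {
          spiked = true; V = Vreset; w += b; ref_left = ref_steps;
        }
      }
    } else {  // hh / rtm
      double Vm = V * 1e3;
      double am, bm, ah, bh, an, bn;
      if (is_rtm) rtm_rates(Vm, &am, &bm, &ah, &bh, &an, &bn);
      else hh_rates(Vm, &am, &bm, &ah, &bh, &an, &bn);
      double dtms = dt * 1e3;
      g.m += dtms * (am * (1.0 - g.m) - bm * g.m);
      g.h += dtms * (ah * (1.0 - g.h) - bh * g.h);
      g.n += dtms * (an * (1.0 - g.n) - bn * g.n);
      if (g.m < -0.01 || g.m > 1.01 || g.h < -0.01 || g.h > 1.01 ||
          g.n < -0.01 || g.n > 1.01)
        stop("gating variable left [0,1] at step %d: integration unstable, reduce dt",
             i + 1);
      double INa = gNa * g.m * g.m * g.m * g.h * (V - ENa);
      double IK = gK * g.n * g.n * g.n * g.n * (V - EK);
      double IL = gL * (V - EL);
      V += dt * (-INa - IK - IL + Iin) / C;
      if (lockout > 0) --lockout;
      else if (Vprev < 0.0 && V >= 0.0) { spiked = true; lockout = lockout_steps; }
    }

    if (!std::isfinite(V) || (is_aeif && !std::isfinite(w)))
      stop("non-finite state in neuron at step %d", i + 1);
    if (spiked) spikes.push_back(i + 1);
    if (record_v) Vout[i] = V;
    Vprev = V;
  }

  List fin = List::create(_["V"] = V, _["w"] = w);
  if (is_hh || is_rtm)
    fin = List::create(_["V"] = V, _["m"] = g.m, _["h"] = g.h, _["n"] = g.n);
  return List::create(_["V"] = Vout, _["spike_steps"] = wrap(spikes),
                      _["final"] = fin);
}

// ---------------------------------------------------------------------------
// Spike-triggered PID firing-rate clamp closed loop on an aEIF neuron with
// OU background conductances. The rate estimate and the controller output
// update only at spike arrivals (sample-and-hold); between spikes I_ext is
// held constant. Gains map rate error (Hz) to current via out_scale (A per
// gain unit; nA convention => 1e-9).
// [[Rcpp::export]]
List cpp_firing_rate_clamp(List params, NumericVector Ge, NumericVector Gi,
                           double Ee, double Ei, double dt, double target,
                           double P, double I, double D, double tau_r,
                           double out_scale, double I0, double V0,
                           bool record) {
  int n = Ge.size();
  double C = as<double>(params["C"]), gL = as<double>(params["g_L"]);
  double EL = as<double>(params["E_L"]), Vth = as<double>(params["V_thresh"]);
  double Vreset = as<double>(params["V_reset"]), tref = as<double>(params["t_ref"]);
  double DeltaT = as<double>(params["Delta_T"]), a = as<double>(params["a"]);
  double b = as<double>(params["b"]), tauw = as<double>(params["tau_w"]);
  double Vspk = Vth + 5.0 * DeltaT;

  double V = V0, w = 0;
  double Iext = I0, r = 0, EI = 0, e_prev = 0;
  bool have_e_prev = false, have_last = false;
  double last_spike = 0;
  int ref_steps = (int)std::floor(tref / dt + 0.5), ref_left = 0;

  NumericVector Vout(record ? n : 0), Iout(record ? n : 0), rout(record ? n : 0);
  std::vector<int> spikes;

  for (int i = 0; i < n; ++i) {
    double ge = Ge[i] > 0 ? Ge[i] : 0.0;
    double gi = Gi[i] > 0 ? Gi[i] : 0.0;
    double Iin = Iext + ge * (Ee - V) + gi * (Ei - V);
    double wprev = w;
    w += dt * (a * (V - EL) - wprev) / tauw;
    bool spiked = false;
    if (ref_left > 0) { --ref_left; V = Vreset; }
    else {
      double ex = (V - Vth) / DeltaT;
      if (ex > 10.0) ex = 10.0;
      V += dt * (-gL * (V - EL) + gL * DeltaT * std::exp(ex) - wprev + Iin) / C;
      if (V >= Vspk) { spiked = true; V = Vreset; w += b; ref_left = ref_steps; }
    }
    if (!std::isfinite(V) || !std::isfinite(w))
      stop("non-finite state in firing-rate clamp at step %d", i + 1);

    if (spiked) {
      double t = (i + 1) * dt;
      spikes.push_back(i + 1);
      if (have_last) {
        double isi = t - last_spike;
        double wgt = std::exp(-isi / tau_r);
        r = r * wgt + (1.0 / isi) * (1.0 - wgt);
        double e = target - r;
        EI += e;
        double de = have_e_prev ? (e - e_prev) : 0.0;
        Iext = I0 + out_scale * (P * e + I * EI + D * de);
        e_prev = e;
        have_e_prev = true;
      }
      last_spike = t;
      have_last = true;
    }
    if (record) { Vout[i] = V; Iout[i] = Iext; rout[i] = r; }
  }
  return List::create(_["V"] = Vout, _["I_ext"] = Iout, _["rate_est"] = rout,
                      _["spike_steps"] = wrap(spikes),
                      _["final_rate_est"] = r, _["final_I_ext"] = Iext);
}

// ---------------------------------------------------------------------------
// Gated PI voltage hold on a passive membrane. Error in V; output current is
// out_scale * (P*err + I*EI) with EI accumulated in V*s while the gate is
// open; while gated closed both the output and the integral are frozen.
// [[Rcpp::export]]
List cpp_voltage_hold(double C, double gL, double EL, int n, double dt,
                      double V_target, NumericVector gate, double P, double I,
                      double out_scale, double V0, double I0) {
  double V = V0, Ih = I0, EI = 0;
  bool g1 = gate.size() <= 1;
  double g0 = gate.size() ? gate[0] : 1.0;
  NumericVector Vout(n), Iout(n);
  for (int i = 0; i < n; ++i) {
    bool open = (g1 ? g0 : gate[i]) > 0.5;
    if (open) {
      double err = V_target - V;
      EI += err * dt;
      Ih = out_scale * (P * err + I * EI);
    }
    V += dt * (-gL * (V - EL) + Ih) / C;
    if (!std::isfinite(V)) stop("non-finite state in voltage hold at step %d", i + 1);
    Vout[i] = V; Iout[i] = Ih;
  }
  return List::create(_["V"] = Vout, _["I_hold"] = Iout, _["EI"] = EI);
}

// ---------------------------------------------------------------------------
// Dynamic clamp through a simulated pipette electrode, with optional online
// active electrode compensation. Per step:
//   1. electrode voltage V_e relaxes toward Rs*I_prev (tau = Rs*Ce);
//   2. recorded potential V_rec = V_m + V_e;
//   3. compensated estimate V_hat = V_rec - sum_k K[k] * I[n-k];
//   4. injected current I_n = Ge(Ee - V*) + Gi(Ei - V*) + I_extra, with
//      V* = V_hat when AEC is on, else V_rec (one-step-delay feedback);
//   5. membrane advances under I_n.
// Divergence (non-finite or |V| > 1 V) is reported, not thrown, so callers
// can assert that the instability detector fired.
// [[Rcpp::export]]
List cpp_dynamic_clamp_aec(std::string kind, List params, NumericVector Ge,
                           NumericVector Gi, double Ee, double Ei,
                           double Rs, double Ce, NumericVector kernel,
                           bool aec_on, double dt, NumericVector I_extra,
                           double V0, bool record) {
  int n = Ge.size();
  double C = as<double>(params["C"]), gL = as<double>(params["g_L"]);
  double EL = as<double>(params["E_L"]);
  bool is_aeif = kind == "aeif";
  double Vth = 0, Vreset = 0, tref = 0, DeltaT = 0, a = 0, b = 0, tauw = 1;
  if (is_aeif) {
    Vth = as<double>(params["V_thresh"]); Vreset = as<double>(params["V_reset"]);
    tref = as<double>(params["t_ref"]); DeltaT = as<double>(params["Delta_T"]);
    a = as<double>(params["a"]); b = as<double>(params["b"]);
    tauw = as<double>(params["tau_w"]);
  }
  double Vspk = Vth + 5.0 * DeltaT;
  int ref_steps = is_aeif ? (int)std::floor(tref / dt + 0.5) : 0, ref_left = 0;

  int nk = kernel.size();
  std::vector<double> hist(nk > 0 ? nk : 1, 0.0);
  int head = 0;  // hist[head] = most recent current
  double V = V0, w = 0, Ve = 0, Iprev = 0;
  double tau_e = Rs * Ce;

  NumericVector Vtrue(record ? n : 0), Vrec_out(record ? n : 0),
      Vcomp_out(record ? n : 0), Iout(record ? n : 0);
  std::vector<int> spikes;
  bool ok = true; int bad_step = -1;
  bool Ix1 = I_extra.size() <= 1;
  double Ix0 = I_extra.size() ? I_extra[0] : 0.0;

  for (int i = 0; i < n; ++i) {
    if (Ce > 0) Ve += dt * (Rs * Iprev - Ve) / tau_e;
    else Ve = Rs * Iprev;
    double Vrec = V + Ve;
    double conv = 0;
    for (int k = 0; k < nk; ++k) conv += kernel[k] * hist[(head + k) % nk];
    double Vhat = Vrec - conv;
    double Vused = aec_on ? Vhat : Vrec;
    double ge = Ge[i] > 0 ? Ge[i] : 0.0;
    double gi = Gi[i] > 0 ? Gi[i] : 0.0;
    double Iin = ge * (Ee - Vused) + gi * (Ei - Vused) + (Ix1 ? Ix0 : I_extra[i]);

    bool spiked = false;
    if (is_aeif) {
      double wprev = w;
      w += dt * (a * (V - EL) - wprev) / tauw;
      if (ref_left > 0) { --ref_left; V = Vreset; }
      else {
        double ex = (V - Vth) / DeltaT;
        if (ex > 10.0) ex = 10.0;
        V += dt * (-gL * (V - EL) + gL * DeltaT * std::exp(ex) - wprev + Iin) / C;
        if (V >= Vspk) { spiked = true; V = Vreset; w += b; ref_left = ref_steps; }
      }
    } else {
      V += dt * (-gL * (V - EL) + Iin) / C;
    }

    if (!std::isfinite(V) || !std::isfinite(Iin) || std::fabs(V) > 1.0) {
      ok = false; bad_step = i + 1;
      break;
    }
    if (nk > 0) { head = (head - 1 + nk) % nk; hist[head] = Iin; }
    Iprev = Iin;
    if (spiked) spikes.push_back(i + 1);
    if (record) { Vtrue[i] = V; Vrec_out[i] = Vrec; Vcomp_out[i] = Vhat; Iout[i] = Iin; }
  }
  return List::create(_["V_true"] = Vtrue, _["V_rec"] = Vrec_out,
                      _["V_comp"] = Vcomp_out, _["I_inj"] = Iout,
                      _["spike_steps"] = wrap(spikes), _["ok"] = ok,
                      _["bad_step"] = bad_step);
}

// ---------------------------------------------------------------------------
// Electrode + passive membrane probe response (for kernel identification):
// the commanded current I reaches the membrane and the electrode in series,
// V_rec = V_m + V_e. Returns the recorded trace.
// [[Rcpp::export]]
NumericVector cpp_probe_response(NumericVector I, double dt, double Rs,
                                 double Ce, double Cm, double Rm, double EL) {
  int n = I.size();
  NumericVector Vrec(n);
  double Vm = EL, Ve = 0;
  double tau_e = Rs * Ce;
  for (int i = 0; i < n; ++i) {
    if (Ce > 0) Ve += dt * (Rs * I[i] - Ve) / tau_e;
    else Ve = Rs * I[i];
    if (Rm > 0) Vm += dt * (-(Vm - EL) / Rm + I[i]) / Cm;
    Vrec[i] = Vm + Ve;
  }
  return Vrec;
}
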