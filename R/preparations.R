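#' Point-neuron parameter set
#'
#' Parameters for the integrate-and-fire family (`"lif"`, `"qif"`, `"aeif"`)
#' and the passive membrane (`"passive"`). All values SI (F, S, V, s, A).
#' For the adaptive exponential model the canonical form is
#' `C dV/dt = -g_L (V - E_L) + g_L Delta_T exp((V - V_thresh)/Delta_T) - w + I`,
#' `tau_w dw/dt = a (V - E_L) - w`, with a numerical spike threshold at
#' `V_thresh + 5 Delta_T`, reset to `V_reset` and `w <- w + b` at each spike.
#'
#' @param model_kind one of `"lif"`, `"qif"`, `"aeif"`, `"passive"`.
#' @param C capacitance (F). @param g_L leak conductance (S).
#' @param E_L leak reversal (V). @param V_thresh spike threshold (V).
#' @param V_reset reset potential (V). @param t_ref absolute refractory (s).
#' @param Delta_T slope factor (V), aEIF only.
#' @param a subthreshold adaptation conductance (S), aEIF only.
#' @param b spike-triggered adaptation increment (A), aEIF only.
#' @param tau_w adaptation time constant (s), aEIF only.
#' @param V_crit critical voltage (V), QIF only.
#' @return list of class `"neuron_params"`.
#' @export
point_neuron_params <- function(model_kind = c("lif", "qif", "aeif", "passive"),
                                C = 200e-12, g_L = 10e-9, E_L = -70e-3,
                                V_thresh = -50e-3, V_reset = -60e-3,
                                t_ref = 2e-3, Delta_T = 2e-3, a = 2e-9,
                                b = 40e-12, tau_w = 144e-3, V_crit = -60e-3) {
  model_kind <- match.arg(model_kind)
  stopifnot(C > 0, g_L > 0, t_ref >= 0, tau_w > 0, V_reset < V_thresh)
  structure(list(model_kind = model_kind, C = C, g_L = g_L, E_L = E_L,
                 V_thresh = V_thresh, V_reset = V_reset, t_ref = t_ref,
                 Delta_T = Delta_T, a = a, b = b, tau_w = tau_w,
                 V_crit = V_crit),
            class = "neuron_params")
}

#' Conductance-based neuron parameter set
#'
#' Hodgkin-Huxley (1952 squid kinetics, resting near -65 mV) or the reduced
#' Traub-Miles model in the Ermentrout-Kopell form. Defaults correspond to a
#' patch of 2e-4 cm^2 (point-neuron scaling of the per-area constants).
#'
#' @param model_kind `"hh"` or `"rtm"`.
#' @param area membrane area in cm^2 used to scale the per-area defaults.
#' @param C,g_Na,g_K,g_L absolute capacitance (F) and conductances (S);
#'   defaults derived from `area`.
#' @param E_Na,E_K,E_L reversal potentials (V).
#' @return list of class `"neuron_params"`.
#' @export
conductance_neuron_params <- function(model_kind = c("hh", "rtm"),
                                      area = 2e-4,
                                      C = NULL, g_Na = NULL, g_K = NULL,
                                      g_L = NULL, E_Na = NULL, E_K = NULL,
                                      E_L = NULL) {
  model_kind <- match.arg(model_kind)
  per_area <- if (model_kind == "hh") {
    list(C = 1e-6, g_Na = 120e-3, g_K = 36e-3, g_L = 0.3e-3,
         E_Na = 50e-3, E_K = -77e-3, E_L = -54.4e-3)
  } else {
    list(C = 1e-6, g_Na = 100e-3, g_K = 80e-3, g_L = 0.1e-3,
         E_Na = 50e-3, E_K = -100e-3, E_L = -67e-3)
  }
  p <- list(model_kind = model_kind,
            C = C %||% (per_area$C * area),
            g_Na = g_Na %||% (per_area$g_Na * area),
            g_K = g_K %||% (per_area$g_K * area),
            g_L = g_L %||% (per_area$g_L * area),
            E_Na = E_Na %||% per_area$E_Na,
            E_K = E_K %||% per_area$E_K,
            E_L = E_L %||% per_area$E_L)
  stopifnot(p$g_Na >= 0, p$g_K >= 0, p$g_L >= 0, p$E_K < p$E_L, p$E_L < p$E_Na)
  structure(p, class = "neuron_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The calibrated default preparation
#'
#' An adaptive exponential integrate-and-fire cell calibrated to a layer-5
#' pyramidal phenotype: resting input conductance 10 nS (input resistance
#' 100 MOhm), rest at -70 mV, rheobase threshold near -50 mV, membrane time
#' constant 20 ms. With this cell the conventional rule of setting unitary
#' synaptic conductances to 2% (excitatory) and 6% (inhibitory) of the
#' resting input conductance yields g_e = 0.2 nS and g_i = 0.6 nS.
#'
#' @param ... overrides forwarded to [point_neuron_params()].
#' @return list of class `"neuron_params"`.
#' @export
default_preparation <- function(...) {
  point_neuron_params(model_kind = "aeif", C = 200e-12, g_L = 10e-9,
                      E_L = -70e-3, V_thresh = -50e-3, V_reset = -60e-3,
                      t_ref = 2e-3, Delta_T = 2e-3, a = 2e-9, b = 40e-12,
                      tau_w = 144e-3, ...)
}

#' Initialize the state of a neuron model
#'
#' @param params a `"neuron_params"` object.
#' @param V0 initial membrane potential (V); defaults to `E_L`.
#' @return named list holding the model state.
#' @export
init_neuron_state <- function(params, V0 = params$E_L) {
  st <- list(V = V0, ref_left = 0L, last_spike_time = NA_real_)
  if (params$model_kind == "aeif") st$w <- 0
  if (params$model_kind %in% c("hh", "rtm")) {
    g <- gating_steady_state(params$model_kind, V0)
    st$m <- g$m; st$h <- g$h; st$n <- g$n
    st$lockout <- 0L
  }
  st
}

gating_steady_state <- function(kind, V) {
  r <- gating_rates(kind, V * 1e3)
  list(m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
       n = r$an / (r$an + r$bn))
}

vtrap_r <- function(x, y) {
  e <- x / y
  ifelse(abs(e) < 1e-6, y * (1 - e / 2), x / (1 - exp(-e)))
}

# V in mV, rates in 1/ms
gating_rates <- function(kind, Vm) {
  if (kind == "hh") {
    list(am = 0.1 * vtrap_r(Vm + 40, 10), bm = 4 * exp(-(Vm + 65) / 18),
         ah = 0.07 * exp(-(Vm + 65) / 20), bh = 1 / (1 + exp(-(Vm + 35) / 10)),
         an = 0.01 * vtrap_r(Vm + 55, 10), bn = 0.125 * exp(-(Vm + 65) / 80))
  } else {
    list(am = 0.32 * vtrap_r(Vm + 54, 4), bm = 0.28 * vtrap_r(-(Vm + 27), 5),
         ah = 0.128 * exp(-(Vm + 50) / 18), bh = 4 / (1 + exp(-(Vm + 27) / 5)),
         an = 0.032 * vtrap_r(Vm + 52, 5), bn = 0.5 * exp(-(Vm + 57) / 40))
  }
}

#' Advance a point-neuron model by one explicit-Euler step
#'
#' Reference per-step implementation used by the block engine and as the
#' oracle route against the compiled simulator. Refractoriness is implemented
#' by clamping the potential at `V_reset`.
#'
#' @param params a `"neuron_params"` object (`lif`, `qif`, `aeif`, `passive`).
#' @param state state list from [init_neuron_state()].
#' @param I_in total input current (A).
#' @param dt time step (s).
#' @param t current time (s), used to stamp `last_spike_time`.
#' @return `list(state =, spike = logical)`.
#' @export
step_point_neuron <- function(params, state, I_in, dt, t = NA_real_) {
  stopifnot(dt > 0)
  kind <- params$model_kind
  V <- state$V
  spike <- FALSE
  wprev <- if (kind == "aeif") state$w else 0
  if (kind == "aeif") {
    state$w <- wprev + dt * (params$a * (V - params$E_L) - wprev) / params$tau_w
  }
  if (kind != "passive" && state$ref_left > 0L) {
    state$ref_left <- state$ref_left - 1L
    state$V <- params$V_reset
  } else {
    dV <- switch(kind,
      passive = -params$g_L * (V - params$E_L) + I_in,
      lif = -params$g_L * (V - params$E_L) + I_in,
      qif = params$g_L * (V - params$E_L) * (V - params$V_crit) /
              (params$V_crit - params$E_L) + I_in,
      aeif = {
        ex <- min((V - params$V_thresh) / params$Delta_T, 10)
        -params$g_L * (V - params$E_L) +
          params$g_L * params$Delta_T * exp(ex) - wprev + I_in
      })
    V <- V + dt * dV / params$C
    thr <- if (kind == "aeif") params$V_thresh + 5 * params$Delta_T
           else params$V_thresh
    if (kind != "passive" && V >= thr) {
      spike <- TRUE
      V <- params$V_reset
      state$ref_left <- as.integer(floor(params$t_ref / dt + 0.5))
      if (kind == "aeif") state$w <- state$w + params$b
      state$last_spike_time <- t
    }
    state$V <- V
  }
  if (!is.finite(state$V)) stop("non-finite membrane potential")
  list(state = state, spike = spike)
}

#' Advance a conductance-based neuron by one explicit-Euler step
#'
#' @inheritParams step_point_neuron
#' @return `list(state =, spike = logical)`; a spike is an upward crossing of
#'   0 mV with a 2 ms lockout.
#' @export
step_conductance_neuron <- function(params, state, I_in, dt, t = NA_real_) {
  stopifnot(dt > 0, dt <= 25e-6)
  r <- gating_rates(params$model_kind, state$V * 1e3)
  dtms <- dt * 1e3
  state$m <- state$m + dtms * (r$am * (1 - state$m) - r$bm * state$m)
  state$h <- state$h + dtms * (r$ah * (1 - state$h) - r$bh * state$h)
  state$n <- state$n + dtms * (r$an * (1 - state$n) - r$bn * state$n)
  gv <- c(state$m, state$h, state$n)
  if (any(gv < -0.01 | gv > 1.01))
    stop("gating variable left [0,1]: integration unstable, reduce dt")
  Vprev <- state$V
  I_ion <- params$g_Na * state$m^3 * state$h * (Vprev - params$E_Na) +
    params$g_K * state$n^4 * (Vprev - params$E_K) +
    params$g_L * (Vprev - params$E_L)
  state$V <- Vprev + dt * (-I_ion + I_in) / params$C
  spike <- FALSE
  if (state$lockout > 0L) {
    state$lockout <- state$lockout - 1L
  } else if (Vprev < 0 && state$V >= 0) {
    spike <- TRUE
    state$lockout <- as.integer(floor(2e-3 / dt + 0.5))
    state$last_spike_time <- t
  }
  if (!is.finite(state$V)) stop("non-finite membrane potential")
  list(state = state, spike = spike)
}

#' Simulate a neuron model over many steps (compiled loop)
#'
#' Vectorized counterpart of the per-step functions; the two routes agree
#' step-for-step.
#'
#' @param params a `"neuron_params"` object.
#' @param duration run length (s). @param dt step (s).
#' @param I_ext external current (A): scalar or per-step vector.
#' @param G_e,G_i synaptic conductance waveforms (S): scalar or per-step;
#'   negative excursions are clipped to zero at injection.
#' @param E_e,E_i synaptic reversal potentials (V).
#' @param V0 initial potential; defaults to `E_L`.
#' @param record_v keep the full voltage trace.
#' @return list with `V` ([trace()] or NULL), `spike_times` (s), `final` state.
#' @export
simulate_neuron <- function(params, duration, dt, I_ext = 0,
                            G_e = numeric(0), G_i = numeric(0),
                            E_e = 0, E_i = -80e-3, V0 = params$E_L,
                            record_v = TRUE) {
  stopifnot(inherits(params, "neuron_params"), duration > 0, dt > 0)
  if (params$model_kind %in% c("hh", "rtm") && dt > 25e-6)
    stop("conductance-based models require dt <= 25 us for stability")
  n <- n_steps(duration, dt)
  res <- cpp_simulate_neuron(params$model_kind, unclass(params), n, dt,
                             as.numeric(I_ext), as.numeric(G_e),
                             as.numeric(G_i), E_e, E_i, V0, record_v)
  list(V = if (record_v) trace(res$V, dt = dt, unit = "V", t0 = dt) else NULL,
       spike_times = res$spike_steps * dt,
       final = res$final)
}

#' Tsodyks-Markram synapse parameter set
#'
#' Short-term depression and facilitation. `tau_facil = 0` disables
#' facilitation (utilization pinned at `U`).
#'
#' @param U release probability increment (0,1].
#' @param tau_rec recovery time constant (s).
#' @param tau_facil facilitation time constant (s); 0 disables.
#' @param A absolute efficacy: peak conductance (S) or current (A) at full
#'   resources and utilization 1.
#' @param tau_syn postsynaptic decay time constant (s).
#' @return list of class `"tm_synapse_params"`.
#' @export
tm_synapse_params <- function(U = 0.5, tau_rec = 0.5, tau_facil = 0,
                              A = 1e-9, tau_syn = 5e-3) {
  stopifnot(U > 0, U <= 1, tau_rec > 0, tau_syn > 0, tau_facil >= 0)
  structure(list(U = U, tau_rec = tau_rec, tau_facil = tau_facil, A = A,
                 tau_syn = tau_syn),
            class = "tm_synapse_params")
}

#' Initialize Tsodyks-Markram synapse state
#' @param params a `"tm_synapse_params"` object.
#' @return list with resources `x` (fraction, starts 1), utilization `u`,
#'   postsynaptic output `g` (same unit as `A`) and the last event amplitude.
#' @export
init_tm_state <- function(params) {
  list(x = 1, u = if (params$tau_facil > 0) 0 else params$U, g = 0,
       last_amplitude = 0)
}

#' Advance a Tsodyks-Markram synapse by one step
#'
#' Between presynaptic spikes resources recover with `tau_rec`, utilization
#' decays with `tau_facil` and the postsynaptic output decays with `tau_syn`.
#' On a presynaptic spike the utilization increments (facilitation), the
#' output jumps by `A * u * x`, and that fraction of resources is consumed.
#' Between events the dynamics are linear, so the update uses the exact
#' exponential discretization (no integration error in dt).
#'
#' @param params a `"tm_synapse_params"` object.
#' @param state state from [init_tm_state()].
#' @param presyn_spike logical: presynaptic event in this step.
#' @param dt step (s).
#' @return `list(state =, output =)`, `output` in the unit of `A`.
#' @export
step_tm_synapse <- function(params, state, presyn_spike, dt) {
  stopifnot(dt > 0)
  # between events the dynamics are linear: exact exponential updates
  state$x <- 1 - (1 - state$x) * exp(-dt / params$tau_rec)
  if (params$tau_facil > 0) {
    state$u <- state$u * exp(-dt / params$tau_facil)
  }
  state$g <- state$g * exp(-dt / params$tau_syn)
  if (isTRUE(presyn_spike)) {
    if (params$tau_facil > 0) {
      state$u <- state$u + params$U * (1 - state$u)
    } else {
      state$u <- params$U
    }
    amp <- params$A * state$u * state$x
    state$x <- state$x - state$u * state$x
    state$g <- state$g + amp
    state$last_amplitude <- amp
  }
  state$x <- min(max(state$x, 0), 1)
  list(state = state, output = state$g)
}

#' Closed-form steady-state release amplitude of a depressing TM synapse
#'
#' For a regular presynaptic train of period `T` with facilitation disabled,
#' the resource fraction seen by each spike converges to
#' `x* = (1 - exp(-T/tau_rec)) / (1 - (1 - U) exp(-T/tau_rec))` and the
#' steady-state amplitude is `A * U * x*`.
#'
#' @param params a `"tm_synapse_params"` with `tau_facil = 0`.
#' @param period interspike period of the regular train (s).
#' @return steady-state event amplitude, unit of `A`.
#' @export
tm_depression_fixed_point <- function(params, period) {
  stopifnot(params$tau_facil == 0)
  e <- exp(-period / params$tau_rec)
  xstar <- (1 - e) / (1 - (1 - params$U) * e)
  params$A * params$U * xstar
}

#' Pipette electrode circuit parameters
#'
#' Series resistance with a parallel capacitance to ground: the electrode
#' voltage drop relaxes toward `R_s * I` with time constant `R_s * C_e`
#' (pure resistor when `C_e = 0`).
#'
#' @param R_s series resistance (Ohm). @param C_e electrode capacitance (F).
#' @return list of class `"electrode_params"`.
#' @export
electrode_params <- function(R_s = 20e6, C_e = 20e-12) {
  stopifnot(R_s > 0, C_e >= 0)
  structure(list(R_s = R_s, C_e = C_e), class = "electrode_params")
}

#' Advance the electrode circuit one step and return the recorded potential
#'
#' @param params an `"electrode_params"` object.
#' @param state list with element `V_e` (electrode voltage drop, V).
#' @param I_pipette current through the pipette (A).
#' @param V_membrane true membrane potential (V).
#' @param dt step (s).
#' @return `list(state =, V_recorded =)` with
#'   `V_recorded = V_membrane + V_e`.
#' @export
step_electrode <- function(params, state, I_pipette, V_membrane, dt) {
  stopifnot(dt > 0)
  if (params$C_e > 0) {
    tau_e <- params$R_s * params$C_e
    state$V_e <- state$V_e + dt * (params$R_s * I_pipette - state$V_e) / tau_e
  } else {
    state$V_e <- params$R_s * I_pipette
  }
  list(state = state, V_recorded = V_membrane + state$V_e)
}

#' Closed-form LIF interspike interval under constant current
#'
#' For `I > I_rh = g_L (V_thresh - E_L)` the interspike interval is
#' `t_ref + tau_m * log((I - g_L (V_reset - E_L)) / (I - I_rh))` with
#' `tau_m = C / g_L`; the firing rate is its inverse.
#'
#' @param params an LIF `"neuron_params"` object.
#' @param I constant input current (A).
#' @return firing rate (Hz); 0 below rheobase.
#' @export
lif_rate_closed_form <- function(params, I) {
  tau_m <- params$C / params$g_L
  I_rh <- params$g_L * (params$V_thresh - params$E_L)
  ifelse(I <= I_rh, 0,
         1 / (params$t_ref + tau_m *
                log((I - params$g_L * (params$V_reset - params$E_L)) /
                      (I - I_rh))))
}
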