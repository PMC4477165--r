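# Closed-loop regulation blocks: spike detection, spike-triggered rate
# estimation, PID firing-rate clamp, gated PI voltage hold, sliding
# response-probability estimation, PI stimulus-intensity control, and PSP
# amplitude measurement. All controllers are sample-and-hold: outputs update
# only on discrete events (spikes, stimuli) and are exactly constant between
# events.

#' Detect spikes as upward threshold crossings in a voltage trace
#'
#' @param V a [trace()] (V).
#' @param threshold detection threshold (V).
#' @param refractory minimum separation between events (s).
#' @param window optional `c(start, end)` times restricting detection.
#' @return numeric spike times (s).
#' @export
detect_spikes <- function(V, threshold = -20e-3, refractory = 2e-3,
                          window = NULL) {
  stopifnot(inherits(V, "trace"), length(V) > 0, refractory >= 0)
  v <- V$values
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- V$t0 + (up - 1L) * V$dt
  if (!is.null(window)) times <- times[times >= window[1] & times <= window[2]]
  if (!length(times)) return(numeric(0))
  keep <- times[1]
  for (tt in times[-1]) {
    if (tt - keep[length(keep)] >= refractory) keep <- c(keep, tt)
  }
  keep
}

#' Spike-triggered firing-rate estimator state
#'
#' @param tau_r averaging timescale (s).
#' @param r0 initial rate estimate (Hz).
#' @return list of class `"rate_estimator"`.
#' @export
rate_estimator <- function(tau_r = 1, r0 = 0) {
  stopifnot(tau_r > 0, r0 >= 0)
  structure(list(r = r0, last_spike_time = NA_real_, tau_r = tau_r),
            class = "rate_estimator")
}

#' Update the firing-rate estimate at a spike arrival
#'
#' Event-triggered exponential weighting between the previous history and
#' the inverse of the last interspike interval:
#' `r <- r * exp(-isi/tau_r) + (1/isi) * (1 - exp(-isi/tau_r))`. No updates
#' occur between spikes. The first spike only initializes the interval
#' clock.
#'
#' @param state a [rate_estimator()].
#' @param spike_time time of the new spike (s), beyond the previous one.
#' @return updated state.
#' @export
update_rate_estimate <- function(state, spike_time) {
  if (is.na(state$last_spike_time)) {
    state$last_spike_time <- spike_time
    return(state)
  }
  isi <- spike_time - state$last_spike_time
  stopifnot(isi > 0)
  w <- exp(-isi / state$tau_r)
  state$r <- state$r * w + (1 / isi) * (1 - w)
  state$last_spike_time <- spike_time
  state
}

#' PID controller parameters
#' @param P,I,D gains mapping error to output.
#' @param output_limits optional `c(lo, hi)` clamp on the output.
#' @return list of class `"pid_params"`.
#' @export
pid_params <- function(P, I = 0, D = 0, output_limits = NULL) {
  if (!is.null(output_limits)) stopifnot(output_limits[1] <= output_limits[2])
  structure(list(P = P, I = I, D = D, output_limits = output_limits),
            class = "pid_params")
}

#' Spike-triggered PID firing-rate clamp: one event update
#'
#' Discrete PID on the rate error with per-event accumulation (no dt
#' scaling), consistent with sample-and-hold semantics: the returned current
#' is held until the next spike. Gains follow the convention of rate error
#' in Hz and output in nA (`out_scale = 1e-9` A per unit).
#'
#' @param pid a [pid_params()].
#' @param target_rate setpoint (Hz). @param estimate current estimate (Hz).
#' @param ctrl controller accumulator list (`EI`, `e_prev`); pass the value
#'   returned by the previous call, or `list(EI = 0, e_prev = NA)` to start.
#' @param out_scale output scale (A per gain unit).
#' @return `list(I_ext = <held current, A>, ctrl =, saturated = logical)`.
#' @export
firing_rate_clamp_step <- function(pid, target_rate, estimate,
                                   ctrl = list(EI = 0, e_prev = NA_real_),
                                   out_scale = 1e-9) {
  e <- target_rate - estimate
  ctrl$EI <- ctrl$EI + e
  de <- if (is.na(ctrl$e_prev)) 0 else e - ctrl$e_prev
  ctrl$e_prev <- e
  out <- out_scale * (pid$P * e + pid$I * ctrl$EI + pid$D * de)
  saturated <- FALSE
  if (!is.null(pid$output_limits)) {
    lim <- pid$output_limits
    if (out < lim[1] || out > lim[2]) saturated <- TRUE
    out <- min(max(out, lim[1]), lim[2])
  }
  list(I_ext = out, ctrl = ctrl, saturated = saturated)
}

#' Run the closed-loop firing-rate clamp on the default preparation
#'
#' Spike-triggered PID regulation of the external current into an adaptive
#' exponential IF cell receiving OU background conductances (compiled loop).
#'
#' @param params `"aeif"` neuron parameters.
#' @param pid a [pid_params()] (rate error in Hz, output in nA).
#' @param target_rate setpoint (Hz).
#' @param G_e,G_i background conductance traces (S).
#' @param E_e,E_i reversals (V).
#' @param tau_r rate-estimator timescale (s).
#' @param I0 constant current offset (A): the held output is
#'   `I0 + PID(...)`, mirroring the constant offset of the
#'   stimulus-intensity law. Defaults to the cell's quiescent rheobase
#'   `g_L (V_thresh - E_L)` so the spike-triggered controller receives
#'   events from the outset.
#' @param record keep full traces.
#' @return list with `spike_times`, traces `V`, `I_ext`, `rate_est` (if
#'   recorded) and the final estimator/controller values.
#' @export
run_firing_rate_clamp <- function(params, pid, target_rate, G_e, G_i,
                                  E_e = 0, E_i = -80e-3, tau_r = 1,
                                  I0 = params$g_L *
                                    (params$V_thresh - params$E_L),
                                  record = TRUE) {
  stopifnot(params$model_kind == "aeif", inherits(pid, "pid_params"))
  dt <- G_e$dt
  res <- cpp_firing_rate_clamp(unclass(params), G_e$values, G_i$values,
                               E_e, E_i, dt, target_rate, pid$P, pid$I,
                               pid$D, tau_r, 1e-9, I0, params$E_L, record)
  out <- list(spike_times = res$spike_steps * dt,
              final_rate_est = res$final_rate_est,
              final_I_ext = res$final_I_ext)
  if (record) {
    out$V <- trace(res$V, dt, "V", t0 = dt)
    out$I_ext <- trace(res$I_ext, dt, "A", t0 = dt)
    out$rate_est <- trace(res$rate_est, dt, "Hz", t0 = dt)
  }
  out
}

#' Gated PI voltage hold: one step
#'
#' PI update on the voltage error while the gate is open; while the gate is
#' closed the output is frozen at its last value and the integral
#' accumulator does not advance (so control resumes without windup).
#'
#' @param pid a [pid_params()] (P, I used).
#' @param V_target,V_measured potentials (V).
#' @param gate_open logical.
#' @param state list with `EI` (V s) and `I_hold` (A); start from
#'   `list(EI = 0, I_hold = 0)`.
#' @param dt step (s).
#' @param out_scale output scale (A per gain unit), default 1e-9 (nA).
#' @return `list(I_hold =, state =)`.
#' @export
voltage_hold_step <- function(pid, V_target, V_measured, gate_open, state,
                              dt, out_scale = 1e-9) {
  if (isTRUE(gate_open)) {
    err <- V_target - V_measured
    state$EI <- state$EI + err * dt
    state$I_hold <- out_scale * (pid$P * err + pid$I * state$EI)
  }
  list(I_hold = state$I_hold, state = state)
}

#' Run the gated PI voltage hold on a passive membrane (compiled loop)
#'
#' @param params neuron parameters (the passive `C`, `g_L`, `E_L` are used).
#' @param pid a [pid_params()].
#' @param V_target hold target (V).
#' @param duration,dt run length and step (s).
#' @param gate scalar or per-step 0/1 gate signal.
#' @param out_scale A per gain unit (default nA convention).
#' @param I0 initial held current (A).
#' @return list with traces `V` and `I_hold`.
#' @export
run_voltage_hold <- function(params, pid, V_target, duration, dt,
                             gate = 1, out_scale = 1e-9, I0 = 0) {
  n <- n_steps(duration, dt)
  res <- cpp_voltage_hold(params$C, params$g_L, params$E_L, n, dt, V_target,
                          as.numeric(gate), pid$P, pid$I, out_scale,
                          params$E_L, I0)
  list(V = trace(res$V, dt, "V", t0 = dt),
       I_hold = trace(res$I_hold, dt, "A", t0 = dt))
}

#' Sliding response-probability estimator state
#'
#' @param p0 initial probability estimate.
#' @param tau averaging time (s). @param ISI inter-stimulation interval (s).
#' @return list of class `"probability_state"`.
#' @export
probability_state <- function(p0, tau = 600, ISI = 4) {
  stopifnot(p0 >= 0, p0 <= 1, tau > 0, ISI > 0)
  structure(list(p = p0, tau = tau, ISI = ISI), class = "probability_state")
}

#' Update the sliding response-probability estimate after a stimulus
#'
#' `p <- p * exp(-ISI/tau) + F * (1 - exp(-ISI/tau))` with `F = 1` if the
#' stimulus evoked a response (a spike in the logging window) and 0
#' otherwise. A convex combination, so `p` stays in `[0, 1]`. The same
#' update with `F` set to a measured PSP amplitude gives the sliding
#' amplitude average of the EPSP-size clamp.
#'
#' @param state a [probability_state()].
#' @param responded logical, or a numeric `F` value (amplitude variant).
#' @return updated state.
#' @export
update_response_probability <- function(state, responded) {
  f <- if (is.logical(responded)) as.numeric(responded) else responded
  w <- exp(-state$ISI / state$tau)
  state$p <- state$p * w + f * (1 - w)
  state
}

#' Stimulus-intensity PI controller state
#'
#' @param S_1 initial/offset intensity (stimulator units).
#' @param G gain. @param P_pid,I_pid PI coefficients.
#' @param target target response probability (or PSP amplitude, in the
#'   controller's error unit).
#' @param bounds stimulator output bounds `c(lo, hi)`.
#' @return list of class `"stimulus_controller"`.
#' @export
stimulus_controller <- function(S_1, G, P_pid, I_pid, target,
                                bounds = c(0, Inf)) {
  structure(list(S_1 = S_1, G = G, P_pid = P_pid, I_pid = I_pid,
                 EI = 0, target = target, bounds = bounds),
            class = "stimulus_controller")
}

#' Next stimulus intensity from the PI law
#'
#' Per-stimulus (event-rate) update with dimensionless accumulation:
#' `EP = target - measured`; `EI <- EI + EP`;
#' `S_next = S_1 + G (P_pid EP + I_pid EI)`. Out-of-bounds commands are
#' clipped and reported.
#'
#' @param state a [stimulus_controller()].
#' @param measured measured probability (or amplitude in the error unit).
#' @return `list(S_next =, state =, clipped = logical)`.
#' @export
next_stimulus_intensity <- function(state, measured) {
  EP <- state$target - measured
  state$EI <- state$EI + EP
  S <- state$S_1 + state$G * (state$P_pid * EP + state$I_pid * state$EI)
  clipped <- FALSE
  if (S < state$bounds[1] || S > state$bounds[2]) {
    clipped <- TRUE
    S <- min(max(S, state$bounds[1]), state$bounds[2])
  }
  list(S_next = S, state = state, clipped = clipped)
}

#' Charge-balanced biphasic pulse specification
#'
#' Symmetric current-controlled pulse, positive phase first by default, each
#' phase lasting `phase_width` (200 us in the stimulation convention
#' emulated here).
#'
#' @param amplitude phase amplitude (A). @param phase_width per-phase
#'   duration (s). @param positive_first polarity order.
#' @return list of class `"biphasic_pulse"`.
#' @export
biphasic_pulse <- function(amplitude, phase_width = 200e-6,
                           positive_first = TRUE) {
  stopifnot(phase_width > 0)
  structure(list(amplitude = amplitude, phase_width = phase_width,
                 positive_first = positive_first),
            class = "biphasic_pulse")
}

#' Compile a biphasic pulse to a waveform trace
#' @param pulse a [biphasic_pulse()]. @param dt sampling interval (s).
#' @return a [trace()] in A; the two phases carry equal and opposite charge.
#' @export
compile_biphasic_pulse <- function(pulse, dt) {
  n_phase <- max(1L, as.integer(round(pulse$phase_width / dt)))
  s <- if (pulse$positive_first) 1 else -1
  trace(c(rep(s * pulse$amplitude, n_phase),
          rep(-s * pulse$amplitude, n_phase)),
        dt = dt, unit = "A", t0 = 0)
}

#' Measure a PSP amplitude in a triggered segment
#'
#' Amplitude is the extremum inside the search window minus the mean over
#' the baseline window, signed by polarity (a positive value means a
#' deflection in the requested direction).
#'
#' @param segment a [triggered_segment()] whose first trace is the voltage.
#' @param baseline_window duration (s) ending at the trigger used for the
#'   baseline mean.
#' @param search_window duration (s) after the trigger searched for the
#'   extremum.
#' @param polarity `"positive"` or `"negative"`.
#' @param channel name or index of the voltage trace in the segment.
#' @return amplitude (V).
#' @export
measure_psp_amplitude <- function(segment, baseline_window = 10e-3,
                                  search_window = 100e-3,
                                  polarity = c("positive", "negative"),
                                  channel = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(segment, "triggered_segment"))
  if (baseline_window > segment$pre_window ||
      search_window > segment$post_window)
    stop("measurement windows extend outside the segment")
  v <- segment$traces[[channel]]
  tt <- trace_times(v)
  rel <- tt - segment$trigger_time
  base <- v$values[rel >= -baseline_window & rel <= 0]
  srch <- v$values[rel > 0 & rel <= search_window]
  b <- mean(base)
  if (polarity == "positive") max(srch) - b else b - min(srch)
}
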