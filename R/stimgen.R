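#' Diffusion-approximation moments of a background synaptic conductance
#'
#' Under the point-conductance diffusion approximation, a Poisson barrage of
#' unitary events of conductance `g`, decay `tau` and total presynaptic rate
#' `R` is replaced by a Gauss-distributed, exponentially correlated process
#' with stationary mean `G_bar = g * tau * R` and standard deviation
#' `G_S = sqrt(g^2 * tau * R / 2)`.
#'
#' @param g unitary conductance (S). @param tau correlation/decay time (s).
#' @param R presynaptic activation rate (Hz). Any argument may be a vector
#'   (e.g. a time-varying rate).
#' @return list with `G_bar` and `G_S` (S).
#' @examples
#' diffusion_moments(1e-9, 10e-3, 1000)  # 10 nS mean, 2.236 nS sd
#' @export
diffusion_moments <- function(g, tau, R) {
  stopifnot(all(g >= 0), all(tau >= 0), all(R >= 0))
  list(G_bar = g * tau * R, G_S = sqrt(g^2 * tau * R / 2))
}

#' Ornstein-Uhlenbeck process parameters
#'
#' @param G_bar stationary mean (S). @param G_S stationary sd (S).
#' @param tau correlation time (s).
#' @return list of class `"ou_params"`; the diffusion coefficient
#'   `D = G_S^2 / tau` is derived on construction.
#' @export
ou_params <- function(G_bar, G_S, tau) {
  stopifnot(tau > 0, G_S >= 0)
  structure(list(G_bar = G_bar, G_S = G_S, tau = tau, D = G_S^2 / tau),
            class = "ou_params")
}

#' One Euler-Maruyama step of an Ornstein-Uhlenbeck process
#'
#' `G' = G + dt (G_bar - G)/tau + sqrt(2 D dt) * xi`, with `xi` a standard
#' normal draw. Negative excursions are passed through here; clipping to zero
#' happens only at the injection point.
#'
#' @param params an [ou_params()] object.
#' @param G current value (S). @param dt step (s).
#' @param noise_draw standard-normal draw.
#' @return updated value (S).
#' @export
ou_step <- function(params, G, dt, noise_draw) {
  stopifnot(dt > 0)
  G + dt * (params$G_bar - G) / params$tau +
    sqrt(2 * params$D * dt) * noise_draw
}

#' Generate an Ornstein-Uhlenbeck path
#'
#' @param params an [ou_params()] object, or a list with per-step vectors
#'   `G_bar`, `G_S` and scalar `tau` for a non-stationary (rate-modulated)
#'   process.
#' @param duration run length (s). @param dt step (s).
#' @param seed integer seed. @param name stream name used to derive the child
#'   seed (see [child_seed()]).
#' @param G0 initial value; defaults to the (first) mean.
#' @return a [trace()] in S.
#' @export
ou_path <- function(params, duration, dt, seed, name = "ou", G0 = NULL) {
  n <- n_steps(duration, dt)
  noise <- child_normals(seed, name, n)
  g0 <- G0 %||% params$G_bar[[1]]
  vals <- cpp_ou_path(noise, dt, as.numeric(params$G_bar),
                      as.numeric(params$G_S), params$tau, g0)
  trace(vals, dt = dt, unit = "S", t0 = dt)
}

#' Sinusoidally modulated presynaptic rate
#'
#' `R(t) = R0 + R1 * sin(omega * t + phase)`; with `R0 >= R1` the rate never
#' goes negative over the cycle.
#'
#' @param R0 offset rate (Hz). @param R1 peak modulation (Hz).
#' @param omega angular frequency (rad/s). @param t time(s) (s).
#' @param phase phase offset (rad), default 0.
#' @return rate(s) in Hz.
#' @export
modulated_rate <- function(R0, R1, omega, t, phase = 0) {
  stopifnot(R0 >= R1, R1 >= 0)
  R0 + R1 * sin(omega * t + phase)
}

#' The dynamic-clamp current law
#'
#' The injected current recomputed each step from the instantaneous
#' (compensated) membrane potential:
#' `I_syn = G_e (E_e - V) + G_i (E_i - V)`.
#'
#' @param G_e,G_i excitatory/inhibitory conductances (S), clipped at 0.
#' @param V membrane potential (V).
#' @param E_e,E_i reversal potentials (V).
#' @return current (A).
#' @export
conductance_to_current <- function(G_e, G_i, V, E_e = 0, E_i = -80e-3) {
  pmax(G_e, 0) * (E_e - V) + pmax(G_i, 0) * (E_i - V)
}

#' Inhibitory rate balancing the mean injected current at a voltage
#'
#' Solves `0 = <G_e>(E_e - V_b) + <G_i>(E_i - V_b)` for the inhibitory
#' presynaptic rate, with the means taken from [diffusion_moments()]:
#' `R_i = g_e tau_e R_e (E_e - V_b) / (g_i tau_i (V_b - E_i))`.
#'
#' @param R_e excitatory rate (Hz).
#' @param g_e,tau_e,g_i,tau_i unitary conductances (S) and correlation
#'   times (s) of the two channels.
#' @param E_e,E_i reversal potentials (V).
#' @param V_b balance voltage (V), strictly between `E_i` and `E_e`
#'   (typically set 1-2 mV below the firing threshold).
#' @return inhibitory rate `R_i` (Hz).
#' @export
balance_inhibitory_rate <- function(R_e, g_e = 0.2e-9, tau_e = 5e-3,
                                    g_i = 0.6e-9, tau_i = 10e-3,
                                    E_e = 0, E_i = -80e-3, V_b = -51.85e-3) {
  if (V_b <= E_i || V_b > E_e)
    stop("V_b must lie in (E_i, E_e]: no balancing rate exists")
  stopifnot(R_e >= 0)
  g_e * tau_e * R_e * (E_e - V_b) / (g_i * tau_i * (V_b - E_i))
}

#' Balanced excitatory/inhibitory OU background at a multiple of the
#' reference condition
#'
#' Convenience wrapper producing the paired conductance processes of the
#' high-conductance-state background: excitatory rate `scale * 7000` Hz with
#' the inhibitory rate solved to balance the mean current at `V_b`.
#'
#' @param scale background multiplier (0, 1, 2, 3, ...).
#' @param duration,dt,seed as in [ou_path()].
#' @param g_e,tau_e,g_i,tau_i,E_e,E_i,V_b channel constants, defaults as in
#'   [balance_inhibitory_rate()].
#' @param R_e_1x reference excitatory rate (Hz) at scale 1.
#' @return list with traces `G_e`, `G_i` and the rates `R_e`, `R_i` used.
#' @export
background_conductances <- function(scale, duration, dt, seed,
                                    g_e = 0.2e-9, tau_e = 5e-3,
                                    g_i = 0.6e-9, tau_i = 10e-3,
                                    E_e = 0, E_i = -80e-3, V_b = -51.85e-3,
                                    R_e_1x = 7000) {
  R_e <- scale * R_e_1x
  R_i <- if (R_e > 0) {
    balance_inhibitory_rate(R_e, g_e, tau_e, g_i, tau_i, E_e, E_i, V_b)
  } else 0
  me <- diffusion_moments(g_e, tau_e, R_e)
  mi <- diffusion_moments(g_i, tau_i, R_i)
  list(G_e = ou_path(ou_params(me$G_bar, me$G_S, tau_e), duration, dt, seed,
                     name = "bg_exc"),
       G_i = ou_path(ou_params(mi$G_bar, mi$G_S, tau_i), duration, dt, seed,
                     name = "bg_inh"),
       R_e = R_e, R_i = R_i)
}

# --- waveform synthesis ------------------------------------------------------

#' Declarative stimulus waveform specification
#'
#' A waveform is an ordered list of segments, each
#' `list(kind =, duration =, ...)` with kinds `"constant"` (`value`),
#' `"pulse"` (`amplitude`, `width`, `delay`, `baseline`), `"ramp"` (`from`,
#' `to`), `"sinusoid"` (`offset`, `amplitude`, `freq_hz`, `phase`) and
#' `"ou"` (`mean`, `sd`, `tau`). Segments are concatenated in order.
#'
#' @param segments list of segment definitions.
#' @param unit unit tag of the compiled trace.
#' @return list of class `"waveform_spec"`.
#' @export
waveform_spec <- function(segments, unit = "A") {
  stopifnot(is.list(segments), length(segments) > 0)
  for (s in segments) {
    stopifnot(!is.null(s$kind), !is.null(s$duration), s$duration > 0)
  }
  structure(list(segments = segments, unit = unit), class = "waveform_spec")
}

compile_segment <- function(seg, dt, seed, idx) {
  n <- n_steps(seg$duration, dt)
  t <- (seq_len(n) - 1L) * dt
  switch(seg$kind,
    constant = rep(seg$value, n),
    pulse = {
      base <- seg$baseline %||% 0
      delay <- seg$delay %||% 0
      v <- rep(base, n)
      on <- t >= delay & t < delay + seg$width
      v[on] <- base + seg$amplitude
      v
    },
    ramp = seg$from + (seg$to - seg$from) * (seq_len(n) - 1L) / max(n - 1L, 1L),
    sinusoid = (seg$offset %||% 0) +
      seg$amplitude * sin(2 * pi * seg$freq_hz * t + (seg$phase %||% 0)),
    ou = {
      p <- ou_params(seg$mean, seg$sd, seg$tau)
      as.numeric(ou_path(p, seg$duration, dt, seed,
                         name = paste0("wf_seg_", idx))$values)
    },
    stop("unknown waveform segment kind '", seg$kind, "'"))
}

#' Compile a waveform specification into a trace
#'
#' Deterministic given `(spec, dt, seed)`; segment lengths are
#' `floor(duration/dt)` samples and concatenation lengths sum exactly.
#'
#' @param spec a [waveform_spec()].
#' @param dt sampling interval (s).
#' @param seed integer seed for stochastic segments.
#' @return a [trace()].
#' @export
compile_waveform <- function(spec, dt, seed = 0L) {
  stopifnot(inherits(spec, "waveform_spec"), dt > 0)
  vals <- unlist(lapply(seq_along(spec$segments), function(i) {
    compile_segment(spec$segments[[i]], dt, seed, i)
  }))
  trace(vals, dt = dt, unit = spec$unit, t0 = 0)
}

#' Sample-wise algebraic combination of aligned traces
#'
#' @param a,b traces sharing `dt` and length.
#' @param op `"sum"` or `"scale"`; for `"scale"`, `b` may be a scalar.
#' @return a [trace()].
#' @export
combine_traces <- function(a, b, op = c("sum", "scale")) {
  op <- match.arg(op)
  if (op == "scale") {
    stopifnot(is.numeric(b), length(b) == 1L)
    return(trace(a$values * b, dt = a$dt, unit = a$unit, t0 = a$t0))
  }
  if (!isTRUE(all.equal(a$dt, b$dt)) || length(a) != length(b))
    stop("combined traces must share dt and length")
  trace(a$values + b$values, dt = a$dt, unit = a$unit, t0 = a$t0)
}

#' Write a waveform trace to a two-column text file
#'
#' @param x a [trace()]. @param file path.
#' @return `file`, invisibly.
#' @export
write_waveform <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt = %.12g unit = %s", x$dt, x$unit), con)
  utils::write.table(data.frame(time = trace_times(x), value = x$values),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
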