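# Executable desk-scale demonstrators: each protocol wires preparations,
# stimulus generation and controllers into a reproducible run against a
# simulated preparation and returns logs plus an analysis summary.

#' Synthetic excitability drift model
#'
#' Stand-in preparation for the response-probing protocols: the
#' stimulus-response threshold of the cell performs a slow
#' Ornstein-Uhlenbeck walk, and a stimulus of intensity S evokes a spike
#' with probability `plogis((S - theta)/k)` (sigmoidal recruitment). The
#' drift parameters are fixture parameters, not biological claims.
#'
#' @param theta0 mean threshold (stimulator units).
#' @param k recruitment-curve width (stimulator units); the dynamic range of
#'   the curve is roughly `6 k`.
#' @param tau_drift drift correlation time (s).
#' @param sd_frac drift standard deviation as a fraction of the dynamic
#'   range.
#' @return list of class `"drift_model"`.
#' @export
drift_model <- function(theta0 = 300, k = 50, tau_drift = 120,
                        sd_frac = 0.10) {
  stopifnot(k > 0, tau_drift > 0, sd_frac >= 0)
  structure(list(theta0 = theta0, k = k, tau_drift = tau_drift,
                 sd = sd_frac * 6 * k),
            class = "drift_model")
}

# Exact OU update of the threshold over one inter-stimulus interval
# (event-driven; no dt-level integration is needed between stimuli).
drift_advance <- function(model, theta, isi, z) {
  rho <- exp(-isi / model$tau_drift)
  model$theta0 + (theta - model$theta0) * rho +
    model$sd * sqrt(1 - rho^2) * z
}

#' Spike-response probability of the drift preparation at intensity S
#' @param model a [drift_model()]. @param S stimulus intensity.
#' @param theta current threshold.
#' @return probability in (0, 1).
#' @export
drift_response_probability <- function(model, S, theta) {
  stats::plogis((S - theta) / model$k)
}

# Event-driven Tsodyks-Markram release: advance recovery over one ISI, then
# release on the event. Returns the released fraction u*x in (0, U].
tm_release_event <- function(params, state, isi) {
  state$x <- 1 - (1 - state$x) * exp(-isi / params$tau_rec)
  if (params$tau_facil > 0) {
    state$u <- state$u * exp(-isi / params$tau_facil)
    state$u <- state$u + params$U * (1 - state$u)
  } else {
    state$u <- params$U
  }
  rel <- state$u * state$x
  state$x <- state$x - rel
  list(state = state, release = rel)
}

#' Protocol configuration
#'
#' @param protocol registered protocol name (see [run_protocol()]).
#' @param duration run length (s). @param dt step (s). @param seed integer.
#' @param preparation optional `"neuron_params"` override.
#' @param out_dir optional directory for log files.
#' @param ... protocol-specific settings (documented per protocol).
#' @return list of class `"protocol_config"`.
#' @export
protocol_config <- function(protocol, duration = 10, dt = 5e-5, seed = 1L,
                            preparation = NULL, out_dir = NULL, ...) {
  stopifnot(duration > 0, dt > 0)
  structure(c(list(protocol = protocol, duration = duration, dt = dt,
                   seed = as.integer(seed), preparation = preparation,
                   out_dir = out_dir), list(...)),
            class = "protocol_config")
}

#' Read a protocol configuration from a YAML file
#'
#' Accepts the conventional electrophysiology units at the boundary: keys
#' may be suffixed `_mV`, `_pA`, `_nA`, `_nS`, `_ms` and are converted to SI
#' with the suffix stripped.
#'
#' @param file path to a YAML config.
#' @return a [protocol_config()].
#' @export
read_protocol_config <- function(file) {
  raw <- yaml::read_yaml(file)
  if (is.null(raw$protocol)) stop("config must name a protocol")
  conv <- list()
  for (nm in names(raw)) {
    m <- regmatches(nm, regexec("^(.*)_(mV|pA|nA|nS|ms)$", nm))[[1]]
    if (length(m) == 3) {
      conv[[m[2]]] <- si(raw[[nm]], m[3])
    } else {
      conv[[nm]] <- raw[[nm]]
    }
  }
  do.call(protocol_config, conv)
}

protocol_registry <- function() {
  c("arbitrary_stream_and_record", "conductance_clamp",
    "sine_modulated_background", "firing_rate_clamp", "voltage_hold",
    "response_probability_clamp", "epsp_size_clamp")
}

#' Run a registered demonstrator protocol
#'
#' The registry covers open-loop current injection and recording
#' (`arbitrary_stream_and_record`), conductance clamp with OU background
#' (`conductance_clamp`), sinusoidally rate-modulated background with or
#' without synaptic filtering (`sine_modulated_background`), the
#' spike-triggered PID firing-rate clamp (`firing_rate_clamp`), the gated PI
#' voltage hold (`voltage_hold`), and the two extracellular response-probing
#' clamps against the synthetic drift preparation
#' (`response_probability_clamp`, `epsp_size_clamp`). Each returns its logs
#' and an analysis summary; with `out_dir` set, logs are also written as
#' tabular text.
#'
#' @param config a [protocol_config()].
#' @return list of run artifacts (protocol-specific; always contains
#'   `protocol`, `seed` and `summary`).
#' @export
run_protocol <- function(config) {
  stopifnot(inherits(config, "protocol_config"))
  if (!config$protocol %in% protocol_registry())
    stop("unknown protocol '", config$protocol, "'; registered: ",
         paste(protocol_registry(), collapse = ", "))
  res <- switch(config$protocol,
    arbitrary_stream_and_record = proto_arbitrary_stream(config),
    conductance_clamp = proto_conductance_clamp(config),
    sine_modulated_background = proto_sine_modulated(config),
    firing_rate_clamp = proto_firing_rate_clamp(config),
    voltage_hold = proto_voltage_hold(config),
    response_probability_clamp = proto_response_clamp(config),
    epsp_size_clamp = proto_epsp_clamp(config))
  res$protocol <- config$protocol
  res$seed <- config$seed
  if (!is.null(config$out_dir) && !is.null(res$logs)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_log_store(res$logs,
                    file.path(config$out_dir,
                              paste0(config$protocol, "_log.tsv")),
                    seed = config$seed)
  }
  res
}

proto_arbitrary_stream <- function(cfg) {
  prep <- cfg$preparation %||% default_preparation()
  I <- if (!is.null(cfg$waveform)) {
    compile_waveform(cfg$waveform, cfg$dt, cfg$seed)$values
  } else 0
  sim <- simulate_neuron(prep, cfg$duration, cfg$dt, I_ext = I)
  list(logs = list(V = sim$V,
                   I_ext = trace(rep_len(I, length(sim$V)), cfg$dt, "A",
                                 t0 = cfg$dt)),
       spike_times = sim$spike_times,
       summary = list(mean_V = mean(sim$V$values),
                      n_spikes = length(sim$spike_times)))
}

proto_conductance_clamp <- function(cfg) {
  prep <- cfg$preparation %||% default_preparation()
  scale <- cfg$scale %||% 1
  bg <- background_conductances(scale, cfg$duration, cfg$dt, cfg$seed)
  sim <- simulate_neuron(prep, cfg$duration, cfg$dt,
                         I_ext = cfg$I_ext %||% 0,
                         G_e = bg$G_e$values, G_i = bg$G_i$values)
  keep <- trace_times(sim$V) > 0.5
  st <- sim$spike_times
  summ <- list(mean_V = mean(sim$V$values[keep]),
               sd_V = stats::sd(sim$V$values[keep]),
               rate = sum(st > 0.5) / (cfg$duration - 0.5),
               R_e = bg$R_e, R_i = bg$R_i)
  if (length(st) > 10) summ$isi_cv <- isi_stats(st)$cv
  list(logs = list(V = sim$V, G_e = bg$G_e, G_i = bg$G_i),
       spike_times = st, summary = summ)
}

proto_sine_modulated <- function(cfg) {
  prep <- cfg$preparation %||% default_preparation()
  f_mod <- cfg$f_mod %||% 100
  depth <- cfg$mod_depth %||% 0.1         # R1 as a fraction of R0
  filtering <- cfg$synaptic_filtering %||% TRUE
  scale <- cfg$scale %||% 1
  g_e <- 0.2e-9; tau_e <- 5e-3; g_i <- 0.6e-9; tau_i <- 10e-3
  R_e0 <- scale * 7000
  R_i0 <- balance_inhibitory_rate(R_e0)
  n <- n_steps(cfg$duration, cfg$dt)
  t <- (seq_len(n) - 1L) * cfg$dt
  omega <- 2 * pi * f_mod
  Re_t <- modulated_rate(R_e0, depth * R_e0, omega, t)
  me <- diffusion_moments(g_e, tau_e, Re_t)
  mi <- diffusion_moments(g_i, tau_i, R_i0)
  if (filtering) {
    # modulation enters the OU targets and is low-passed by tau_e
    Ge <- cpp_ou_path(child_normals(cfg$seed, "bg_exc", n), cfg$dt,
                      me$G_bar, me$G_S, tau_e, me$G_bar[[1]])
  } else {
    # modulated mean added directly; only the fluctuation is low-passed
    m0 <- diffusion_moments(g_e, tau_e, R_e0)
    flux <- cpp_ou_path(child_normals(cfg$seed, "bg_exc", n), cfg$dt,
                        0, m0$G_S, tau_e, 0)
    Ge <- me$G_bar + flux
  }
  Gi <- cpp_ou_path(child_normals(cfg$seed, "bg_inh", n), cfg$dt,
                    mi$G_bar, mi$G_S, tau_i, mi$G_bar)
  sim <- simulate_neuron(prep, cfg$duration, cfg$dt,
                         I_ext = cfg$I_ext %||% 0.3e-9,
                         G_e = Ge, G_i = Gi)
  st <- sim$spike_times[sim$spike_times > 0.5]
  hist <- cycle_histogram(st - 0.5, period = 1 / f_mod,
                          n_bins = cfg$n_bins %||% 32L,
                          total_time = cfg$duration - 0.5)
  fit <- fit_rate_sinusoid(hist)
  list(logs = list(V = sim$V,
                   G_e = trace(Ge, cfg$dt, "S", t0 = cfg$dt)),
       spike_times = sim$spike_times, histogram = hist, fit = fit,
       summary = list(r0 = fit$r0, r1 = fit$r1, phi = fit$phi,
                      n_spikes = length(st)))
}

proto_firing_rate_clamp <- function(cfg) {
  prep <- cfg$preparation %||% default_preparation()
  target <- cfg$target_rate %||% 17
  pid <- pid_params(cfg$P %||% 0.0045, cfg$I %||% 0.0023, cfg$D %||% 0)
  bg <- background_conductances(cfg$scale %||% 1, cfg$duration, cfg$dt,
                                cfg$seed)
  run <- run_firing_rate_clamp(prep, pid, target, bg$G_e, bg$G_i,
                               tau_r = cfg$tau_r %||% 1)
  final_window <- cfg$final_window %||% min(20, cfg$duration / 2)
  t1 <- cfg$duration - final_window
  mean_rate <- sum(run$spike_times > t1) / final_window
  list(logs = list(V = run$V, I_ext = run$I_ext, rate_est = run$rate_est),
       spike_times = run$spike_times,
       summary = list(target = target, mean_rate_final = mean_rate,
                      final_window = final_window,
                      R_e = bg$R_e, R_i = bg$R_i))
}

proto_voltage_hold <- function(cfg) {
  prep <- cfg$preparation %||% default_preparation()
  pid <- pid_params(cfg$P %||% 10, cfg$I %||% 100)
  target <- cfg$V_target %||% -60e-3
  run <- run_voltage_hold(prep, pid, target, cfg$duration, cfg$dt,
                          gate = cfg$gate %||% 1)
  tail_keep <- trace_times(run$V) > cfg$duration - 0.5
  list(logs = run,
       summary = list(V_target = target,
                      settled_mean = mean(run$V$values[tail_keep]),
                      settle_error = abs(mean(run$V$values[tail_keep]) -
                                           target)))
}

proto_response_clamp <- function(cfg) {
  model <- cfg$model %||% drift_model()
  n_stim <- cfg$n_stimuli %||% 300L
  ISI <- cfg$ISI %||% 4
  p_target <- cfg$p_target %||% 0.5
  tau <- cfg$tau %||% 600
  ctrl <- stimulus_controller(S_1 = cfg$S_1 %||% model$theta0,
                              G = cfg$G %||% 700,
                              P_pid = cfg$P_pid %||% 1,
                              I_pid = cfg$I_pid %||% 0.3,
                              target = p_target, bounds = c(0, 1e4))
  pst <- probability_state(p0 = cfg$p0 %||% p_target, tau = tau, ISI = ISI)
  zs <- child_normals(cfg$seed, "drift_theta", n_stim)
  us <- child_uniforms(cfg$seed, "response_draw", n_stim)
  theta <- model$theta0
  S <- ctrl$S_1
  out <- data.frame(stimulus = seq_len(n_stim), S = NA_real_,
                    theta = NA_real_, responded = NA, p = NA_real_)
  for (i in seq_len(n_stim)) {
    theta <- drift_advance(model, theta, ISI, zs[[i]])
    responded <- us[[i]] < drift_response_probability(model, S, theta)
    pst <- update_response_probability(pst, responded)
    out$S[i] <- S; out$theta[i] <- theta
    out$responded[i] <- responded; out$p[i] <- pst$p
    nx <- next_stimulus_intensity(ctrl, pst$p)
    ctrl <- nx$state
    S <- nx$S_next
  }
  discard <- cfg$discard %||% 50L
  post <- out$p[(discard + 1L):n_stim]
  list(events = out, model = model,
       summary = list(p_target = p_target,
                      mean_abs_rel_dev = mean(abs(post - p_target)) /
                        p_target,
                      p_variance = stats::var(post),
                      response_rate = mean(out$responded)))
}

proto_epsp_clamp <- function(cfg) {
  model <- cfg$model %||% drift_model(sd_frac = 0)     # threshold fixed;
  n_stim <- cfg$n_stimuli %||% 300L                    # efficacy drifts
  ISI <- cfg$ISI %||% 4
  target_mV <- (cfg$target_amplitude %||% 0.5e-3) * 1e3
  tau <- cfg$tau %||% 300
  syn <- cfg$synapse %||% tm_synapse_params(U = 0.5, tau_rec = 0.5,
                                            tau_facil = 0, A = 1)
  A_max_mV <- cfg$A_max_mV %||% 2      # peak PSP at full recruitment (mV)
  drift_tau <- cfg$drift_tau %||% 120
  drift_sd <- cfg$drift_sd %||% 0.15   # fractional efficacy drift
  noise_mV <- cfg$measurement_noise_mV %||% 0.05
  ctrl <- stimulus_controller(S_1 = cfg$S_1 %||% model$theta0,
                              G = cfg$G %||% 1600,
                              P_pid = cfg$P_pid %||% 1,
                              I_pid = cfg$I_pid %||% 0.3,
                              target = target_mV, bounds = c(0, 1e4))
  ast <- probability_state(p0 = 0, tau = tau, ISI = ISI)
  ast$p <- target_mV                      # sliding amplitude average (mV)
  zs <- child_normals(cfg$seed, "efficacy_drift", n_stim)
  ms <- child_normals(cfg$seed, "psp_measurement", n_stim)
  tm <- init_tm_state(syn)
  eff <- 1
  S <- ctrl$S_1
  out <- data.frame(stimulus = seq_len(n_stim), S = NA_real_,
                    amplitude_mV = NA_real_, A_est_mV = NA_real_,
                    efficacy = NA_real_)
  rho <- exp(-ISI / drift_tau)
  for (i in seq_len(n_stim)) {
    eff <- 1 + (eff - 1) * rho + drift_sd * sqrt(1 - rho^2) * zs[[i]]
    eff <- max(eff, 0.1)
    rel <- tm_release_event(syn, tm, ISI)
    tm <- rel$state
    recruit <- drift_response_probability(model, S, model$theta0)
    amp <- A_max_mV * recruit * eff * rel$release + noise_mV * ms[[i]]
    ast <- update_response_probability(ast, amp)
    out$S[i] <- S; out$amplitude_mV[i] <- amp
    out$A_est_mV[i] <- ast$p; out$efficacy[i] <- eff
    nx <- next_stimulus_intensity(ctrl, ast$p)
    ctrl <- nx$state
    S <- nx$S_next
  }
  discard <- cfg$discard %||% 50L
  post <- out$A_est_mV[(discard + 1L):n_stim]
  list(events = out, model = model,
       summary = list(target_mV = target_mV,
                      mean_abs_rel_dev = mean(abs(post - target_mV)) /
                        target_mV,
                      mean_amplitude_mV = mean(
                        out$amplitude_mV[(discard + 1L):n_stim])))
}

#' Replay a recorded stimulus sequence in open loop
#'
#' Delivers the stimulus intensities recorded during a closed-loop
#' response-clamp run against a fresh realization of the excitability drift
#' (same drift statistics, new seed) without any feedback, and reports the
#' probability-estimate trajectory for comparison with the closed-loop one.
#'
#' @param recorded_S stimulus intensities from a prior closed-loop run (the
#'   `events$S` column), or a path to an event file written by
#'   [write_event_file()].
#' @param config the [protocol_config()] of the closed-loop run; `seed`
#'   here controls the fresh drift realization.
#' @return list with `events` and `summary` as in the closed-loop protocol.
#' @export
replay_open_loop <- function(recorded_S, config) {
  if (is.character(recorded_S)) recorded_S <- read_event_file(recorded_S)$S
  if (!length(recorded_S)) {
    return(list(events = data.frame(), summary = list(p_variance = NA_real_,
                                                      n_stimuli = 0L)))
  }
  model <- config$model %||% drift_model()
  ISI <- config$ISI %||% 4
  p_target <- config$p_target %||% 0.5
  tau <- config$tau %||% 600
  n_stim <- length(recorded_S)
  pst <- probability_state(p0 = config$p0 %||% p_target, tau = tau,
                           ISI = ISI)
  zs <- child_normals(config$seed, "drift_theta", n_stim)
  us <- child_uniforms(config$seed, "response_draw", n_stim)
  theta <- model$theta0
  out <- data.frame(stimulus = seq_len(n_stim), S = recorded_S,
                    responded = NA, p = NA_real_)
  for (i in seq_len(n_stim)) {
    theta <- drift_advance(model, theta, ISI, zs[[i]])
    responded <- us[[i]] < drift_response_probability(model, recorded_S[i],
                                                      theta)
    pst <- update_response_probability(pst, responded)
    out$responded[i] <- responded
    out$p[i] <- pst$p
  }
  discard <- config$discard %||% 50L
  post <- out$p[(discard + 1L):n_stim]
  list(events = out,
       summary = list(p_variance = stats::var(post), n_stimuli = n_stim))
}

#' Write stimulation events to a text event file
#' @param events data frame with at least columns `stimulus` and `S`.
#' @param file path.
#' @export
write_event_file <- function(events, file) {
  utils::write.table(events, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read a stimulation event file
#' @param file path.
#' @return data frame of events.
#' @export
read_event_file <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")
}

#' Generate deterministic test fixtures
#'
#' Writes small plain-text fixture files with a YAML manifest of the true
#' generating parameters. Kinds: `"probe_circuit"` (paired probe current and
#' recorded voltage with known electrode/membrane constants),
#' `"drift_neuron"` (threshold trajectory of the drift preparation),
#' `"poisson_modulated_spikes"` (spike times from a sinusoidally modulated
#' Poisson process), `"psp_segments"` (alpha-function PSP bumps on noisy
#' baselines).
#'
#' @param kind fixture kind.
#' @param params named list of overrides (kind-specific).
#' @param seed integer seed.
#' @param dir output directory.
#' @return list with the fixture data and the manifest (also written to
#'   `dir`).
#' @export
make_fixture <- function(kind = c("probe_circuit", "drift_neuron",
                                  "poisson_modulated_spikes",
                                  "psp_segments"),
                         params = list(), seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- params
  fx <- switch(kind,
    probe_circuit = {
      R_s <- p$R_s %||% 10e6; C_e <- p$C_e %||% 20e-12
      R_m <- p$R_m %||% 100e6; tau_m <- p$tau_m %||% 20e-3
      dt <- p$dt %||% 5e-5; duration <- p$duration %||% 2
      I <- generate_probe_current(p$amplitude %||% 100e-12, duration, dt,
                                  seed)
      V <- simulate_probe_recording(I, electrode_params(R_s, C_e), R_m,
                                    tau_m)
      write_log_store(list(I_probe = I, V_rec = V),
                      file.path(dir, "probe_circuit.tsv"), seed = seed)
      list(I_probe = I, V_rec = V,
           manifest = list(kind = kind, R_s = R_s, C_e = C_e, R_m = R_m,
                           tau_m = tau_m, dt = dt, seed = seed))
    },
    drift_neuron = {
      model <- drift_model(theta0 = p$theta0 %||% 300, k = p$k %||% 50,
                           tau_drift = p$tau_drift %||% 120,
                           sd_frac = p$sd_frac %||% 0.10)
      n <- p$n %||% 300L; ISI <- p$ISI %||% 4
      zs <- child_normals(seed, "drift_theta", n)
      theta <- numeric(n); th <- model$theta0
      for (i in seq_len(n)) {
        th <- drift_advance(model, th, ISI, zs[[i]])
        theta[i] <- th
      }
      utils::write.table(data.frame(stimulus = seq_len(n), theta = theta),
                         file.path(dir, "drift_neuron.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      list(theta = theta,
           manifest = list(kind = kind, theta0 = model$theta0, k = model$k,
                           tau_drift = model$tau_drift, sd = model$sd,
                           ISI = ISI, seed = seed))
    },
    poisson_modulated_spikes = {
      r0 <- p$r0 %||% 10; r1 <- p$r1 %||% 3; f <- p$f %||% 100
      phi <- p$phi %||% 0.5; n_cycles <- p$n_cycles %||% 1e4
      duration <- n_cycles / f
      st <- generate_modulated_poisson(r0, r1, 2 * pi * f, phi, duration,
                                       child_seed(seed, "poisson_spikes"))
      utils::write.table(data.frame(spike_time = st),
                         file.path(dir, "poisson_spikes.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      list(spike_times = st,
           manifest = list(kind = kind, r0 = r0, r1 = r1, f = f, phi = phi,
                           n_cycles = n_cycles, seed = seed))
    },
    psp_segments = {
      dt <- p$dt %||% 1e-4; peak <- p$peak %||% 0.5e-3
      tau_alpha <- p$tau_alpha %||% 5e-3
      n_seg <- p$n_seg %||% 5
      pre <- 10e-3; post <- 500e-3
      nn <- as.integer(round((pre + post) / dt)) + 1L
      rel <- (seq_len(nn) - 1L) * dt - pre
      segs <- lapply(seq_len(n_seg), function(i) {
        bump <- ifelse(rel > 0,
                       peak * (rel / tau_alpha) * exp(1 - rel / tau_alpha),
                       0)
        v <- -70e-3 + bump
        triggered_segment(1 + (i - 1) * 4, pre, post,
                          list(V = trace(v, dt, "V", t0 = 1 + (i - 1) * 4 -
                                           pre)))
      })
      write_segments(segs, file.path(dir, "psp_segments"))
      list(segments = segs,
           manifest = list(kind = kind, peak = peak, tau_alpha = tau_alpha,
                           dt = dt, seed = seed))
    })
  yaml::write_yaml(fx$manifest, file.path(dir, paste0(kind, "_manifest.yml")))
  fx
}

#' Paired open- versus closed-loop comparison of probability variance
#'
#' Runs the response-probability clamp and the open-loop replay of its
#' recorded stimulus sequence against fresh drift realizations, over
#' `n_pairs` paired seeds, and reports the post-lock-in variance of the
#' probability estimate for each arm.
#'
#' @param n_pairs number of paired repetitions.
#' @param n_stimuli stimuli per run.
#' @param seed base integer seed.
#' @param ... forwarded to [protocol_config()] for both arms.
#' @return data frame with columns `closed_var` and `replay_var`.
#' @export
compare_open_closed_loop <- function(n_pairs = 20L, n_stimuli = 300L,
                                     seed = 1L, ...) {
  res <- lapply(seq_len(n_pairs), function(r) {
    cfg <- protocol_config("response_probability_clamp",
                           n_stimuli = n_stimuli,
                           seed = seed + 7L * r, ...)
    closed <- run_protocol(cfg)
    cfg_replay <- cfg
    cfg_replay$seed <- cfg$seed + 5000L     # fresh drift realization
    replay <- replay_open_loop(closed$events$S, cfg_replay)
    c(closed_var = closed$summary$p_variance,
      replay_var = replay$summary$p_variance)
  })
  as.data.frame(do.call(rbind, res))
}
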