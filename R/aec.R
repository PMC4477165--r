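# Active Electrode Compensation: identify the pipette-electrode impulse
# response from a uniform-noise current probe, separate it from the passive
# membrane component, and subtract online the convolution of the injected
# current with the electrode kernel from the recorded potential.

#' Lag-indexed impulse-response kernel
#'
#' Taps are in Ohm per tap (volts per ampere per step): the voltage predicted
#' from a current history is `sum_k taps[k] * I[n-k]`.
#'
#' @param taps numeric coefficients, lag 0 first.
#' @param dt sampling interval (s).
#' @return list of class `"aec_kernel"`.
#' @export
aec_kernel <- function(taps, dt) {
  stopifnot(length(taps) >= 1, dt > 0, all(is.finite(taps)))
  structure(list(taps = as.numeric(taps), dt = dt, n_taps = length(taps)),
            class = "aec_kernel")
}

#' @export
print.aec_kernel <- function(x, ...) {
  cat(sprintf("<aec_kernel> %d taps @ dt = %g s, total resistance %.3g MOhm\n",
              x$n_taps, x$dt, sum(x$taps) / 1e6))
  invisible(x)
}

#' Total resistance of a kernel (sum of taps)
#' @param kernel an [aec_kernel()].
#' @return resistance (Ohm).
#' @export
kernel_resistance <- function(kernel) sum(kernel$taps)

#' Uniformly distributed probe current for kernel identification
#'
#' I.i.d. samples uniform over `[-amplitude, amplitude]`: zero mean by
#' construction of the symmetric range.
#'
#' @param amplitude half-range (A). @param duration length (s).
#' @param dt sampling interval (s). @param seed integer seed.
#' @return a [trace()] in A.
#' @export
generate_probe_current <- function(amplitude, duration, dt, seed) {
  stopifnot(duration > 0, dt > 0, amplitude >= 0)
  n <- n_steps(duration, dt)
  vals <- child_uniforms(seed, "aec_probe", n, min = -amplitude,
                         max = amplitude)
  trace(vals, dt = dt, unit = "A", t0 = 0)
}

#' Record the probe response of a simulated electrode + passive membrane
#'
#' Ground-truth circuit for compensation tests: series pipette (R_s, C_e)
#' plus a passive membrane (R_m, C_m = tau_m / R_m); the recorded potential
#' is the sum of the membrane and electrode voltages. `R_m = 0` detaches the
#' membrane (electrode only).
#'
#' @param I_probe probe current [trace()].
#' @param electrode an [electrode_params()].
#' @param R_m membrane resistance (Ohm); 0 for electrode only.
#' @param tau_m membrane time constant (s).
#' @param E_L resting potential (V).
#' @return recorded voltage [trace()].
#' @export
simulate_probe_recording <- function(I_probe, electrode, R_m = 100e6,
                                     tau_m = 20e-3, E_L = -70e-3) {
  Cm <- if (R_m > 0) tau_m / R_m else 1
  v <- cpp_probe_response(I_probe$values, I_probe$dt, electrode$R_s,
                          electrode$C_e, Cm, R_m, if (R_m > 0) E_L else 0)
  trace(v, dt = I_probe$dt, unit = "V", t0 = I_probe$t0)
}

#' Estimate the combined electrode + membrane kernel by least squares
#'
#' Solves `V_rec ~ mean(V) + K * I_probe` over `n_taps` lags, optionally
#' ridge-regularized. The probe must carry variance at all lags (a constant
#' probe gives a rank-deficient design and is rejected).
#'
#' @param I_probe,V_rec aligned traces with the same `dt`.
#' @param n_taps number of kernel lags.
#' @param ridge regularizer (>= 0) added to the normal-equation diagonal,
#'   scaled by the mean diagonal.
#' @return an [aec_kernel()].
#' @export
estimate_full_kernel <- function(I_probe, V_rec, n_taps, ridge = 0) {
  stopifnot(inherits(I_probe, "trace"), inherits(V_rec, "trace"),
            isTRUE(all.equal(I_probe$dt, V_rec$dt)),
            length(I_probe) == length(V_rec), ridge >= 0)
  n <- length(I_probe)
  if (n < 4L * n_taps)
    stop("probe too short: need length well beyond n_taps (", n_taps, ")")
  s <- stats::sd(I_probe$values)
  if (!is.finite(s) || s == 0)
    stop("rank-deficient design (constant probe?)")
  # scale the current columns to unit variance so the intercept column is
  # commensurate with the lag regressors
  X <- cbind(1, stats::embed(I_probe$values / s, n_taps))
  y <- V_rec$values[n_taps:n]
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  if (ridge > 0) {
    d <- diag(XtX)
    diag(XtX) <- d + ridge * mean(d[-1]) * c(0, rep(1, n_taps))
  }
  beta <- tryCatch(drop(solve(XtX, Xty)),
                   error = function(e) stop(
                     "rank-deficient design (constant probe?): ",
                     conditionMessage(e)))
  aec_kernel(beta[-1] / s, I_probe$dt)
}

#' Split the full kernel into electrode and membrane components
#'
#' Fits an exponential `(R_m dt / tau_m) exp(-lag dt / tau_m)` to the tail of
#' the full kernel (lags beyond `membrane_tail_start`, where the electrode
#' has settled), then removes the fitted membrane component from every lag.
#' The electrode kernel is truncated where the membrane tail begins. In the
#' simulated ladder circuit the commanded current reaches the membrane
#' unfiltered, so the membrane component subtracts directly with no
#' electrode-filtering correction.
#'
#' @param K_full kernel from [estimate_full_kernel()].
#' @param membrane_tail_start lag time (s) beyond the electrode's timescale.
#' @return list with `K_electrode` ([aec_kernel()]), `R_m` (Ohm),
#'   `tau_m` (s).
#' @export
split_electrode_kernel <- function(K_full, membrane_tail_start = 3e-3) {
  dt <- K_full$dt
  k0 <- as.integer(ceiling(membrane_tail_start / dt))
  if (k0 >= K_full$n_taps - 4L)
    stop("kernel too short to contain a membrane tail beyond ",
         membrane_tail_start, " s; use a longer kernel or earlier tail start")
  lag <- (k0:(K_full$n_taps - 1L))
  tail_taps <- K_full$taps[lag + 1L]
  if (mean(tail_taps <= 0) > 0.5 ||
      sum(tail_taps[seq_len(length(tail_taps) %/% 2)]) <=
      sum(tail_taps[-seq_len(length(tail_taps) %/% 2)]))
    stop("kernel tail does not decay; use a longer probe or later tail start")
  # log-linear fit on the positive part of the tail
  ok <- tail_taps > 0
  fit <- stats::lm.fit(cbind(1, lag[ok] * dt), log(tail_taps[ok]))
  tau_m <- -1 / fit$coefficients[[2]]
  if (!is.finite(tau_m) || tau_m <= 0)
    stop("membrane tail fit failed (non-decaying); longer probe or later tail start")
  amp0 <- exp(fit$coefficients[[1]])             # tap at lag 0
  R_m <- amp0 * tau_m / dt
  lags_all <- 0:(K_full$n_taps - 1L)
  membrane <- amp0 * exp(-lags_all * dt / tau_m)
  e_taps <- (K_full$taps - membrane)[seq_len(k0)]
  list(K_electrode = aec_kernel(e_taps, dt), R_m = R_m, tau_m = tau_m)
}

#' Online compensation state
#'
#' Ring buffer of the last `n_taps` injected-current samples plus the
#' electrode kernel; when disabled the recorded voltage passes through
#' unchanged.
#'
#' @param kernel an [aec_kernel()]. @param enabled logical switch.
#' @return list of class `"aec_state"`.
#' @export
aec_state <- function(kernel, enabled = TRUE) {
  structure(list(kernel = kernel, history = rep(0, kernel$n_taps),
                 enabled = isTRUE(enabled)),
            class = "aec_state")
}

#' Compensate one recorded sample online
#'
#' Pushes the injected-current sample into the history and returns
#' `V_rec - sum_k taps[k] * I[n-k]`; when disabled, returns `V_rec`.
#'
#' @param state an [aec_state()].
#' @param V_rec_sample recorded potential (V).
#' @param I_injected_sample current injected this step (A).
#' @return `list(state =, V_membrane_estimate =)`.
#' @export
compensate_online <- function(state, V_rec_sample, I_injected_sample) {
  state$history <- c(I_injected_sample,
                     state$history[-length(state$history)])
  v <- if (state$enabled) {
    V_rec_sample - sum(state$kernel$taps * state$history)
  } else V_rec_sample
  list(state = state, V_membrane_estimate = v)
}

#' Closed-loop dynamic clamp through a simulated electrode with AEC
#'
#' Runs the full loop: OU background conductances converted to current from
#' the compensated potential estimate, injected through the electrode into
#' the simulated cell. Divergence (the positive-feedback hazard of an
#' over-estimated kernel) is reported via `ok`/`bad_step` rather than thrown.
#'
#' @param params neuron parameters (`"aeif"` or `"passive"` kinds).
#' @param electrode an [electrode_params()].
#' @param kernel compensation [aec_kernel()] (the estimated electrode
#'   kernel).
#' @param G_e,G_i conductance traces (S).
#' @param E_e,E_i reversal potentials (V).
#' @param aec_on logical: compensate before computing the current.
#' @param I_extra additional current (A), scalar or per-step.
#' @param record keep full traces.
#' @return list with traces `V_true`, `V_rec`, `V_comp`, `I_inj`,
#'   `spike_times`, and `ok`/`bad_step` divergence report.
#' @export
dynamic_clamp_aec <- function(params, electrode, kernel, G_e, G_i,
                              E_e = 0, E_i = -80e-3, aec_on = TRUE,
                              I_extra = 0, record = TRUE) {
  stopifnot(inherits(params, "neuron_params"))
  kind <- if (params$model_kind == "aeif") "aeif" else "passive"
  dt <- G_e$dt
  res <- cpp_dynamic_clamp_aec(kind, unclass(params), G_e$values, G_i$values,
                               E_e, E_i, electrode$R_s, electrode$C_e,
                               kernel$taps, aec_on, dt, as.numeric(I_extra),
                               params$E_L, record)
  out <- list(spike_times = res$spike_steps * dt, ok = res$ok,
              bad_step = res$bad_step)
  if (record) {
    out$V_true <- trace(res$V_true, dt, "V", t0 = dt)
    out$V_rec <- trace(res$V_rec, dt, "V", t0 = dt)
    out$V_comp <- trace(res$V_comp, dt, "V", t0 = dt)
    out$I_inj <- trace(res$I_inj, dt, "A", t0 = dt)
  }
  out
}

#' Write a kernel to a two-column text file (lag s, tap Ohm)
#' @param kernel an [aec_kernel()]. @param file path.
#' @export
write_kernel <- function(kernel, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt = %.12g", kernel$dt), con)
  utils::write.table(
    data.frame(lag = (seq_len(kernel$n_taps) - 1L) * kernel$dt,
               tap = kernel$taps),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a kernel written by [write_kernel()]
#' @param file path.
#' @return an [aec_kernel()].
#' @export
read_kernel <- function(file) {
  hdr <- readLines(file, n = 1L)
  dt <- as.numeric(sub("# dt = ", "", hdr, fixed = TRUE))
  df <- utils::read.table(file, header = FALSE, comment.char = "#")
  aec_kernel(df[[2]], dt)
}
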