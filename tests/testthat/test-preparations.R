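# Simulated preparations: neuron models against closed-form and limit-case
# oracles, synapse fixed points, electrode circuit responses, and agreement
# between the per-step R route and the compiled route.

test_that("LIF at rest with zero input is a fixed point", {
  p <- point_neuron_params("lif")
  sim <- simulate_neuron(p, 0.2, 1e-4, I_ext = 0)
  expect_true(all(sim$V$values == p$E_L))
  expect_length(sim$spike_times, 0)
})

test_that("LIF firing rate matches the closed-form f-I expression within 2%", {
  p <- point_neuron_params("lif")
  for (I in c(0.25e-9, 0.3e-9, 0.5e-9)) {
    sim <- simulate_neuron(p, 5, 1e-5, I_ext = I, record_v = FALSE)
    r_sim <- sum(sim$spike_times > 1) / 4
    r_cf <- lif_rate_closed_form(p, I)
    expect_lt(abs(r_sim - r_cf) / r_cf, 0.02)
  }
})

test_that("adaptive exponential IF with a = b = 0 reduces to the exponential IF oracle", {
  p <- point_neuron_params("aeif", a = 0, b = 0, t_ref = 0)
  dt <- 1e-5
  n <- 20000L
  st <- init_neuron_state(p)
  V_oracle <- p$E_L
  V_model <- V_orac <- numeric(n)
  sp_model <- sp_orac <- logical(n)
  for (i in seq_len(n)) {
    I <- 0.35e-9
    r <- step_point_neuron(p, st, I, dt, i * dt)
    st <- r$state
    o <- eif_oracle_step(p, V_oracle, I, dt)
    V_oracle <- o$V
    V_model[i] <- st$V
    V_orac[i] <- V_oracle
    sp_model[i] <- r$spike
    sp_orac[i] <- o$spike
  }
  expect_identical(V_model, V_orac)
  expect_identical(sp_model, sp_orac)
})

test_that("per-step R route and compiled route agree step-for-step", {
  set.seed(SUITE_SEED)
  dt <- 5e-5
  n <- 3000L
  I <- stats::rnorm(n, 0.25e-9, 0.05e-9)
  for (kind in c("lif", "qif", "aeif")) {
    p <- point_neuron_params(kind)
    st <- init_neuron_state(p)
    V <- numeric(n)
    sp <- integer(0)
    for (i in seq_len(n)) {
      r <- step_point_neuron(p, st, I[i], dt, i * dt)
      st <- r$state
      V[i] <- st$V
      if (r$spike) sp <- c(sp, i)
    }
    cc <- simulate_neuron(p, n * dt, dt, I_ext = I)
    expect_identical(V, cc$V$values, label = kind)
    expect_identical(sp * dt, cc$spike_times, label = kind)
  }
  hh <- conductance_neuron_params("hh")
  st <- init_neuron_state(hh, -65e-3)
  dt <- 1e-5
  n <- 2000L
  V <- numeric(n)
  for (i in seq_len(n)) {
    r <- step_conductance_neuron(hh, st, 5e-9, dt, i * dt)
    st <- r$state
    V[i] <- st$V
  }
  cc <- simulate_neuron(hh, n * dt, dt, I_ext = 5e-9, V0 = -65e-3)
  expect_equal(V, cc$V$values, tolerance = 1e-12)
})

test_that("conductance-based models rest stably and fire monotonically with current", {
  for (kind in c("hh", "rtm")) {
    p <- conductance_neuron_params(kind)
    V0 <- if (kind == "hh") -65e-3 else -67e-3
    sim <- simulate_neuron(p, 1, 1e-5, I_ext = 0, V0 = V0)
    expect_lt(max(abs(sim$V$values - V0)), 1e-3)   # within 1 mV of rest
    levels <- if (kind == "hh") c(2e-9, 4e-9, 8e-9) else c(0.5e-9, 1e-9, 2e-9)
    rates <- vapply(levels, function(I) {
      length(simulate_neuron(p, 1, 1e-5, I_ext = I, V0 = V0,
                             record_v = FALSE)$spike_times)
    }, 0)
    expect_true(all(diff(rates) > 0))
  }
})

test_that("halving dt changes the conductance-model trajectory RMS by < 1%", {
  p <- conductance_neuron_params("hh")
  a <- simulate_neuron(p, 1, 2e-5, I_ext = 1e-9, V0 = -65e-3)
  b <- simulate_neuron(p, 1, 1e-5, I_ext = 1e-9, V0 = -65e-3)
  expect_lt(abs(rms(a$V$values) - rms(b$V$values)) / rms(b$V$values), 0.01)
})

test_that("f-I curves are non-decreasing in current for every model", {
  currents <- seq(0.1e-9, 0.6e-9, by = 0.1e-9)
  for (kind in c("lif", "qif", "aeif")) {
    p <- point_neuron_params(kind)
    rates <- vapply(currents, function(I) {
      length(simulate_neuron(p, 2, 5e-5, I_ext = I,
                             record_v = FALSE)$spike_times)
    }, 0)
    expect_true(all(diff(rates) >= 0), label = kind)
  }
})

test_that("refractoriness caps the LIF rate at 1/t_ref", {
  p <- point_neuron_params("lif", t_ref = 5e-3)
  sim <- simulate_neuron(p, 2, 1e-5, I_ext = 5e-9, record_v = FALSE)
  expect_lte(length(sim$spike_times) / 2, 1 / 5e-3 + 1)
})

test_that("TM synapse decays, releases A*U from rest, and hits the depression fixed point", {
  syn <- tm_synapse_params(U = 0.5, tau_rec = 0.5, tau_facil = 0, A = 1e-9,
                           tau_syn = 5e-3)
  st <- init_tm_state(syn)
  # no spikes: pure exponential decay of the output with tau_syn
  st$g <- 1e-9
  r <- step_tm_synapse(syn, st, FALSE, 5e-3)
  expect_equal(r$output, 1e-9 * exp(-1))
  # first spike from full recovery releases A * U
  st <- init_tm_state(syn)
  r <- step_tm_synapse(syn, st, TRUE, 1e-4)
  expect_equal(r$state$last_amplitude, syn$A * syn$U, tolerance = 1e-3)
  # regular 20 Hz train settles on the closed-form fixed point
  st <- init_tm_state(syn)
  dt <- 1e-4
  for (ev in 1:400) {
    for (k in 1:500) {
      r <- step_tm_synapse(syn, st, k == 500L, dt)
      st <- r$state
    }
  }
  cf <- tm_depression_fixed_point(syn, 0.05)
  expect_lt(abs(st$last_amplitude - cf) / cf, 1e-6)
})

test_that("TM resources stay in [0,1] for arbitrary spike trains", {
  set.seed(SUITE_SEED)
  for (rep in 1:5) {
    syn <- tm_synapse_params(U = stats::runif(1, 0.05, 1),
                             tau_rec = stats::runif(1, 0.05, 1),
                             tau_facil = sample(c(0, 0.2), 1))
    st <- init_tm_state(syn)
    spikes <- stats::runif(2000) < 0.05
    xs <- numeric(length(spikes))
    for (i in seq_along(spikes)) {
      r <- step_tm_synapse(syn, st, spikes[i], 1e-3)
      st <- r$state
      xs[i] <- st$x
    }
    expect_gte(min(xs), 0)
    expect_lte(max(xs), 1)
  }
})

test_that("electrode circuit: identity at zero current, Ohm offset, RC step response", {
  # zero pipette current leaves the recording equal to the membrane
  el <- electrode_params(R_s = 10e6, C_e = 5e-12)
  r <- step_electrode(el, list(V_e = 0), 0, -70e-3, 1e-5)
  expect_equal(r$V_recorded, -70e-3)
  # pure resistor: 100 pA through 10 MOhm offsets by exactly 1 mV
  el0 <- electrode_params(R_s = 10e6, C_e = 0)
  r <- step_electrode(el0, list(V_e = 0), 100e-12, -70e-3, 1e-5)
  expect_equal(r$V_recorded, -70e-3 + 1e-3)
  # RC electrode: step settles to R_s*I with time constant R_s*C_e
  el <- electrode_params(R_s = 10e6, C_e = 100e-12)   # tau 1 ms
  dt <- 1e-6
  st <- list(V_e = 0)
  n <- 10000L
  ve <- numeric(n)
  for (i in seq_len(n)) {
    r <- step_electrode(el, st, 100e-12, 0, dt)
    st <- r$state
    ve[i] <- r$V_recorded
  }
  expect_lt(abs(ve[n] - 1e-3) / 1e-3, 0.01)
  # fitted time constant within 1%
  tfit <- (seq_len(n) - 1L) * dt
  fit <- stats::lm.fit(cbind(1, tfit), log(1e-3 - ve + 1e-15))
  expect_lt(abs(-1 / fit$coefficients[[2]] - 1e-3) / 1e-3, 0.01)
})

test_that("the calibrated default preparation matches its stated passive properties", {
  p <- default_preparation()
  expect_equal(p$g_L, 10e-9)       # 2% / 6% rule gives 0.2 / 0.6 nS
  expect_equal(p$E_L, -70e-3)
  expect_equal(p$V_thresh, -50e-3)
  expect_equal(0.02 * p$g_L, 0.2e-9)
  expect_equal(0.06 * p$g_L, 0.6e-9)
})
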