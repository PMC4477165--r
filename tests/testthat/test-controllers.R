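# Closed-loop regulation blocks: spike detection, event-triggered rate
# estimation, the sample-and-hold PID clamps, the sliding probability
# estimator and the PI stimulus-intensity law, and PSP measurement.

test_that("spike detection finds upward crossings with refractoriness and windows", {
  flat <- trace(rep(-70e-3, 1000), 1e-4, "V")
  expect_length(detect_spikes(flat, threshold = -20e-3), 0)

  # three constructed crossings 50 ms apart
  v <- rep(-70e-3, 2000)
  for (i0 in c(500, 1000, 1500)) v[i0 + 0:5] <- 0
  tr <- trace(v, 1e-4, "V", t0 = 0)
  st <- detect_spikes(tr, threshold = -20e-3, refractory = 2e-3)
  expect_length(st, 3)
  expect_equal(st, (c(500, 1000, 1500) - 1) * 1e-4, tolerance = 1e-9)

  # 100 Hz sinusoid crossing threshold each cycle: 100 events per second
  t <- seq(0, 1 - 1e-4, by = 1e-4)
  sine <- trace(-50e-3 + 40e-3 * sin(2 * pi * 100 * t), 1e-4, "V")
  expect_length(detect_spikes(sine, threshold = -20e-3, refractory = 2e-3),
                100)

  # detection window restriction
  expect_length(detect_spikes(sine, threshold = -20e-3, refractory = 2e-3,
                              window = c(0, 0.1)), 10)
})

test_that("the rate estimator has 1/isi fixed points and converges geometrically", {
  # already at the fixed point: unchanged
  st <- rate_estimator(tau_r = 1, r0 = 10)
  st$last_spike_time <- 0
  st <- update_rate_estimate(st, 0.1)
  expect_equal(st$r, 10)

  # constant 100 ms intervals from r = 0: within 1% of 10 Hz after 5 s
  st <- rate_estimator(tau_r = 1, r0 = 0)
  for (k in 0:50) st <- update_rate_estimate(st, k * 0.1)
  expect_lt(abs(st$r - 10) / 10, 0.01)
  # and the approach is monotone
  st <- rate_estimator(tau_r = 1, r0 = 0)
  rs <- c()
  for (k in 0:50) {
    st <- update_rate_estimate(st, k * 0.1)
    rs <- c(rs, st$r)
  }
  expect_true(all(diff(rs) >= 0))

  # isi >> tau_r: memory washed out, estimate ~ 1/isi
  st <- rate_estimator(tau_r = 1, r0 = 50)
  st$last_spike_time <- 0
  st <- update_rate_estimate(st, 20)
  expect_equal(st$r, 1 / 20, tolerance = 1e-5)
})

test_that("the firing-rate PID updates only on events and by the stated law", {
  pid <- pid_params(P = 0.0045, I = 0, D = 0)
  # zero error: output constant at zero correction
  r <- firing_rate_clamp_step(pid, 17, 17)
  expect_equal(r$I_ext, 0)
  # P-only: a single event with error e increments by P*e (nA convention)
  r <- firing_rate_clamp_step(pid, 17, 12)
  expect_equal(r$I_ext, 1e-9 * 0.0045 * 5)
  # output limits saturate with a report, not an error
  pidl <- pid_params(P = 1, output_limits = c(-1e-12, 1e-12))
  r <- firing_rate_clamp_step(pidl, 17, 0)
  expect_true(r$saturated)
  expect_equal(r$I_ext, 1e-12)
})

test_that("the closed-loop clamp output is exactly constant between spikes", {
  prep <- default_preparation()
  bg <- background_conductances(1, 5, 5e-5, seed = SUITE_SEED)
  run <- run_firing_rate_clamp(prep, pid_params(0.0045, 0.0023, 0), 17,
                               bg$G_e, bg$G_i)
  iv <- run$I_ext$values
  changes <- which(diff(iv) != 0) + 1L
  spikes <- as.integer(round(run$spike_times / 5e-5))
  expect_true(all(changes %in% spikes))
})

test_that("the gated voltage hold settles and freezes correctly", {
  prep <- default_preparation()
  pid <- pid_params(P = 10, I = 100)
  run <- run_voltage_hold(prep, pid, -60e-3, duration = 3, dt = 5e-5)
  t <- trace_times(run$V)
  # settles within 0.5 mV of the target in under 2 s
  expect_true(all(abs(run$V$values[t > 2] + 60e-3) < 0.5e-3))
  idx <- which(abs(run$V$values + 60e-3) < 0.5e-3)[1]
  expect_lt(t[idx], 2)

  # gate closed for the whole run: output frozen at the initial value
  frozen <- run_voltage_hold(prep, pid, -60e-3, duration = 0.5, dt = 5e-5,
                             gate = 0)
  expect_true(all(frozen$I_hold$values == 0))
  expect_true(all(abs(frozen$V$values - prep$E_L) < 1e-9))

  # per-step law: measured at target leaves the output unchanged
  st <- list(EI = 0, I_hold = 42e-12)
  r <- voltage_hold_step(pid, -60e-3, -60e-3, TRUE, st, 5e-5)
  expect_equal(r$I_hold, 0)      # P and I terms are both zero
  r <- voltage_hold_step(pid, -60e-3, -70e-3, FALSE, st, 5e-5)
  expect_equal(r$I_hold, 42e-12) # gated: frozen at the held value
})

test_that("the sliding probability estimator follows the stated update and stays in [0,1]", {
  # F equal to the current p is a fixed point
  st <- probability_state(p0 = 0.37, tau = 600, ISI = 3)
  st2 <- update_response_probability(st, 0.37)
  expect_equal(st2$p, 0.37)

  # first update from p0 = 0 with a response, ISI 3 s, tau 600 s
  st <- probability_state(p0 = 0, tau = 600, ISI = 3)
  st <- update_response_probability(st, TRUE)
  expect_equal(st$p, 1 - exp(-0.005))
  expect_equal(st$p, 0.0049875, tolerance = 1e-5)

  # all responses: monotone to 1; all failures: monotone to 0
  st <- probability_state(p0 = 0.2, tau = 10, ISI = 4)
  ps <- c()
  for (i in 1:60) {
    st <- update_response_probability(st, TRUE)
    ps <- c(ps, st$p)
  }
  expect_true(all(diff(ps) > 0))
  expect_gt(ps[60], 0.99)
  for (i in 1:120) st <- update_response_probability(st, FALSE)
  expect_lt(st$p, 0.01)

  # convex combination: p in [0,1] for arbitrary response sequences
  set.seed(SUITE_SEED)
  st <- probability_state(p0 = 0.5, tau = 2, ISI = 1)
  ps2 <- vapply(stats::runif(500) < 0.5, function(f) {
    st <<- update_response_probability(st, f)
    st$p
  }, 0)
  expect_gte(min(ps2), 0)
  expect_lte(max(ps2), 1)
})

test_that("constant-F sequences converge geometrically at rate exp(-ISI/tau)", {
  st <- probability_state(p0 = 0, tau = 600, ISI = 4)
  w <- exp(-4 / 600)
  ps <- vapply(1:100, function(n) {
    st <<- update_response_probability(st, 0.8)
    st$p
  }, 0)
  # closed form: p_n = 0.8 (1 - w^n), i.e. geometric approach at rate w
  expect_equal(ps, 0.8 * (1 - w^(1:100)), tolerance = 1e-12)
  expect_equal(0.8 - ps[-1], (0.8 - ps[-100]) * w, tolerance = 1e-12)
})

test_that("the PI stimulus-intensity law reproduces its closed-form updates", {
  ctrl <- stimulus_controller(S_1 = 100, G = 700, P_pid = 1, I_pid = 0.3,
                              target = 0.5)
  # zero error with empty integral: stays at S_1
  r <- next_stimulus_intensity(ctrl, 0.5)
  expect_equal(r$S_next, 100)

  # EP = 0.1 with prior EI = 0: S_1 + 700*(0.1 + 0.03) = S_1 + 91
  ctrl <- stimulus_controller(S_1 = 100, G = 700, P_pid = 1, I_pid = 0.3,
                              target = 0.5)
  r <- next_stimulus_intensity(ctrl, 0.4)
  expect_equal(r$S_next, 100 + 91)

  # measured equal to target on every stimulus: S constant at
  # S_1 + G * I_pid * EI0
  ctrl <- r$state
  s_prev <- NULL
  for (i in 1:5) {
    r <- next_stimulus_intensity(ctrl, 0.5)
    ctrl <- r$state
    if (!is.null(s_prev)) expect_equal(r$S_next, s_prev)
    s_prev <- r$S_next
  }
  expect_equal(s_prev, 100 + 700 * 0.3 * 0.1)

  # bound clipping is reported
  ctrl <- stimulus_controller(S_1 = 100, G = 700, P_pid = 1, I_pid = 0.3,
                              target = 1, bounds = c(0, 150))
  r <- next_stimulus_intensity(ctrl, 0)
  expect_true(r$clipped)
  expect_equal(r$S_next, 150)
})

test_that("biphasic pulses are charge balanced and positive-first", {
  p <- biphasic_pulse(50e-6, phase_width = 200e-6)
  tr <- compile_biphasic_pulse(p, dt = 2e-5)
  expect_equal(sum(tr$values), 0)                 # charge balance
  expect_length(tr, 20L)                          # 2 x 200 us at 20 us
  expect_true(all(tr$values[1:10] > 0))
  expect_true(all(tr$values[11:20] < 0))
})

test_that("PSP amplitude measurement handles flat, clean and drifting baselines", {
  dt <- 1e-4
  pre <- 10e-3
  post <- 500e-3
  nn <- as.integer(round((pre + post) / dt)) + 1L
  rel <- (seq_len(nn) - 1L) * dt - pre
  mk_seg <- function(v) triggered_segment(1, pre, post,
                                          list(V = trace(v, dt, "V",
                                                         t0 = 1 - pre)))
  # flat segment: zero amplitude
  expect_equal(measure_psp_amplitude(mk_seg(rep(-70e-3, nn))), 0)

  # alpha-function bump of 0.5 mV peak on a flat baseline, within 1%
  tau_a <- 5e-3
  bump <- ifelse(rel > 0, 0.5e-3 * (rel / tau_a) * exp(1 - rel / tau_a), 0)
  amp <- measure_psp_amplitude(mk_seg(-70e-3 + bump))
  expect_lt(abs(amp - 0.5e-3) / 0.5e-3, 0.01)

  # the same bump on a 1 mV/s linear drift with a 10 ms baseline: under 5%
  drift <- 1e-3 * (rel + pre)
  amp <- measure_psp_amplitude(mk_seg(-70e-3 + bump + drift),
                               search_window = 50e-3)
  expect_lt(abs(amp - 0.5e-3) / 0.5e-3, 0.05)

  # windows outside the segment are rejected
  expect_error(measure_psp_amplitude(mk_seg(rep(0, nn)),
                                     baseline_window = 20e-3),
               "outside")
})
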