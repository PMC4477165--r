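# Stimulus synthesis: diffusion-approximation moments, OU process
# statistics, rate modulation, the dynamic-clamp current law, the balance
# solver, and waveform compilation.

test_that("diffusion moments follow G_bar = g tau R, G_S = sqrt(g^2 tau R / 2)", {
  expect_equal(diffusion_moments(1e-9, 10e-3, 0), list(G_bar = 0, G_S = 0))
  m <- diffusion_moments(1e-9, 10e-3, 1000)
  expect_equal(m$G_bar, 10e-9)
  expect_equal(m$G_S, sqrt(1e-18 * 10e-3 * 1000 / 2))
  expect_equal(m$G_S, 2.236068e-9, tolerance = 1e-6)
  # the reference excitatory condition of the calibrated preparation
  m1 <- diffusion_moments(0.2e-9, 5e-3, 7000)
  expect_equal(m1$G_bar, 7e-9)
})

test_that("single OU steps behave deterministically", {
  p <- ou_params(G_bar = 5e-9, G_S = 0, tau = 10e-3)
  expect_equal(ou_step(p, 5e-9, 1e-4, 0.7), 5e-9)   # zero-sd fixed point
  p2 <- ou_params(G_bar = 5e-9, G_S = 1e-9, tau = 10e-3)
  expect_equal(ou_step(p2, 0, 1e-4, 0), 1e-4 * 5e-9 / 10e-3)
})

test_that("a long OU run reproduces the stationary moments and correlation time", {
  m <- diffusion_moments(1e-9, 10e-3, 1000)
  p <- ou_params(m$G_bar, m$G_S, 10e-3)
  path <- ou_path(p, 100, 5e-5, seed = SUITE_SEED)
  v <- path$values
  expect_lt(abs(mean(v) - m$G_bar) / m$G_bar, 0.01)
  expect_lt(abs(stats::sd(v) - m$G_S) / m$G_S, 0.03)
  expect_lt(abs(tau_from_acf(v, 5e-5) - 10e-3) / 10e-3, 0.05)
})

test_that("OU paths are reproducible per stream and independent across streams", {
  p <- ou_params(5e-9, 1e-9, 10e-3)
  a <- ou_path(p, 1, 1e-3, seed = 3, name = "x")
  b <- ou_path(p, 1, 1e-3, seed = 3, name = "x")
  expect_identical(a, b)
  c2 <- ou_path(p, 1, 1e-3, seed = 3, name = "y")
  expect_false(identical(a$values, c2$values))
  expect_lt(abs(stats::cor(a$values, c2$values)), 0.3)
})

test_that("sinusoidal rate modulation evaluates the rate law", {
  expect_equal(modulated_rate(7000, 700, 2 * pi * 100, 0), 7000)
  expect_equal(modulated_rate(7000, 0, 2 * pi * 100, 0.123), 7000)
  # at the peak of the cycle with 10% modulation depth
  omega <- 2 * pi * 100
  t_peak <- (pi / 2) / omega
  expect_equal(modulated_rate(7000, 700, omega, t_peak), 7700)
  expect_error(modulated_rate(500, 700, omega, 0))   # rate would go negative
})

test_that("the dynamic-clamp law evaluates and clips at reversal potentials", {
  expect_equal(conductance_to_current(0, 0, -60e-3), 0)
  expect_equal(conductance_to_current(5e-9, 0, V = 0, E_e = 0), 0)
  I <- conductance_to_current(7e-9, 10e-9, V = -60e-3, E_e = 0, E_i = -80e-3)
  expect_equal(I, 0.42e-9 - 0.2e-9)
  # negative conductance excursions are clipped at injection
  expect_equal(conductance_to_current(-5e-9, 0, -60e-3), 0)
})

test_that("the balance solver reproduces the printed rate pair and zeroes the mean current", {
  expect_equal(balance_inhibitory_rate(0), 0)
  expect_equal(balance_inhibitory_rate(7000, V_b = 0), 0)   # V_b at E_e
  R_i <- balance_inhibitory_rate(7000)
  expect_equal(R_i, 2149, tolerance = 1e-3)
  # substituting back: mean current below 1e-15 A in magnitude
  V_b <- -51.85e-3
  Ge <- diffusion_moments(0.2e-9, 5e-3, 7000)$G_bar
  Gi <- diffusion_moments(0.6e-9, 10e-3, R_i)$G_bar
  expect_lt(abs(Ge * (0 - V_b) + Gi * (-80e-3 - V_b)), 1e-15)
  expect_error(balance_inhibitory_rate(7000, V_b = -90e-3), "balancing")
})

test_that("slow rate modulation keeps OU moments tracking the instantaneous targets", {
  # quasi-stationary check: 0.2 Hz modulation, tau = 5 ms
  dt <- 1e-4
  dur <- 40
  n <- as.integer(dur / dt)
  t <- (seq_len(n) - 1L) * dt
  R_t <- modulated_rate(7000, 700, 2 * pi * 0.2, t)
  m <- diffusion_moments(0.2e-9, 5e-3, R_t)
  g <- clamploop:::cpp_ou_path(clamploop:::child_normals(SUITE_SEED, "m", n),
                               dt, m$G_bar, m$G_S, 5e-3, m$G_bar[1])
  # compare windowed means at the crest and trough of the cycle
  crest <- abs((t %% 5) - 1.25) < 0.4     # around sin = +1
  trough <- abs((t %% 5) - 3.75) < 0.4    # around sin = -1
  expect_lt(abs(mean(g[crest]) - diffusion_moments(0.2e-9, 5e-3, 7700)$G_bar) /
              7.7e-9, 0.03)
  expect_lt(abs(mean(g[trough]) - diffusion_moments(0.2e-9, 5e-3, 6300)$G_bar) /
              6.3e-9, 0.03)
})

test_that("waveform compilation is exact for deterministic segments", {
  w <- waveform_spec(list(list(kind = "constant", duration = 1,
                               value = 100e-12)))
  tr <- compile_waveform(w, 1e-3)
  expect_length(tr, 1000L)
  expect_true(all(tr$values == 1e-10))

  w <- waveform_spec(list(list(kind = "ramp", duration = 1, from = 0,
                               to = 100e-12)))
  tr <- compile_waveform(w, 1e-3)
  expect_equal(tr$values[1], 0)
  expect_equal(tr$values[1000], 1e-10)
  expect_true(all(diff(tr$values) > 0))

  # concatenation lengths sum exactly
  w <- waveform_spec(list(list(kind = "constant", duration = 0.3, value = 1),
                          list(kind = "pulse", duration = 0.2,
                               amplitude = 2, width = 0.05, delay = 0.1),
                          list(kind = "sinusoid", duration = 0.5,
                               amplitude = 1, freq_hz = 10)))
  expect_length(compile_waveform(w, 1e-3), 300L + 200L + 500L)
})

test_that("summing two sinusoids equals sample-wise addition of compiled traces", {
  s1 <- waveform_spec(list(list(kind = "sinusoid", duration = 1,
                                amplitude = 2, freq_hz = 5)))
  s2 <- waveform_spec(list(list(kind = "sinusoid", duration = 1,
                                amplitude = 1, freq_hz = 11, phase = 0.3)))
  a <- compile_waveform(s1, 1e-3)
  b <- compile_waveform(s2, 1e-3)
  expect_equal(combine_traces(a, b)$values, a$values + b$values)
})

test_that("waveform files round-trip through the two-column text format", {
  w <- waveform_spec(list(list(kind = "ramp", duration = 0.1, from = 0,
                               to = 1e-9)))
  tr <- compile_waveform(w, 1e-3)
  f <- tempfile(fileext = ".dat")
  write_waveform(tr, f)
  back <- read_waveform(f)
  expect_equal(back$values, tr$values, tolerance = 1e-9)
  expect_equal(back$dt, tr$dt)
})

test_that("unit conversion helpers map boundary units to SI", {
  expect_equal(si(10, "mV"), 0.01)
  expect_equal(si(100, "pA"), 1e-10)
  expect_equal(si(0.2, "nS"), 0.2e-9)
  expect_equal(si(20, "MOhm"), 2e7)
  expect_equal(si(5, "ms"), 5e-3)
  expect_equal(si(3, "V"), 3)
  expect_error(si(1, "furlong"))
})
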