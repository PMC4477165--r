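# Shared oracles and small utilities for the suite.

rms <- function(x) sqrt(mean(x^2))

# Independent exponential integrate-and-fire stepper (no adaptation), used
# as the limit-case oracle for the adaptive exponential model with a = b = 0.
eif_oracle_step <- function(p, V, I, dt) {
  ex <- min((V - p$V_thresh) / p$Delta_T, 10)
  dV <- -p$g_L * (V - p$E_L) + p$g_L * p$Delta_T * exp(ex) + I
  V <- V + dt * dV / p$C
  spike <- V >= p$V_thresh + 5 * p$Delta_T
  if (spike) V <- p$V_reset
  list(V = V, spike = spike)
}

# Autocorrelation-time estimate: log-linear fit of the empirical ACF over
# the lags where it exceeds 1/e.
tau_from_acf <- function(x, dt, lag_max = 400L) {
  ac <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  k <- which(ac > exp(-1)) - 1L
  fit <- stats::lm.fit(cbind(1, k * dt), log(ac[k + 1L]))
  -1 / fit$coefficients[[2]]
}

# Base seed for every stochastic check in the suite (fixed a priori).
SUITE_SEED <- 1L
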