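# Offline analyses of logged runs: cycle histograms and sinusoidal transfer
# fits, F-I curves and gain modulation, interspike-interval statistics.

#' Fold spike times into a cycle histogram
#'
#' Spike times are folded modulo the stimulus period and binned; bin rates
#' are `counts / (n_cycles * bin_width)` so a homogeneous train of rate r
#' gives bins near r. Counts are conserved: their sum equals the number of
#' spikes falling within whole cycles.
#'
#' @param spikes spike times (s).
#' @param period modulation period (s).
#' @param n_bins number of bins (>= 4).
#' @param total_time observation length (s), >= one period; only whole
#'   cycles are accumulated.
#' @return list of class `"cycle_histogram"` with `bin_rates` (Hz),
#'   `counts`, `bin_centers` (s within the cycle), `n_cycles`, `period`.
#' @export
cycle_histogram <- function(spikes, period, n_bins = 32L, total_time) {
  stopifnot(period > 0, n_bins >= 4L, total_time >= period)
  n_cycles <- floor(total_time / period)
  spikes <- spikes[spikes < n_cycles * period]
  phase <- spikes %% period
  breaks <- seq(0, period, length.out = n_bins + 1L)
  counts <- as.integer(table(cut(phase, breaks, include.lowest = TRUE,
                                 labels = FALSE, right = FALSE)))
  cnt <- integer(n_bins)
  idx <- as.integer(names(table(cut(phase, breaks, include.lowest = TRUE,
                                    labels = FALSE, right = FALSE))))
  cnt[idx] <- counts
  bin_width <- period / n_bins
  structure(list(bin_rates = cnt / (n_cycles * bin_width), counts = cnt,
                 bin_centers = breaks[-1] - bin_width / 2,
                 n_cycles = n_cycles, period = period, n_bins = n_bins),
            class = "cycle_histogram")
}

#' Fit a sinusoid to a cycle histogram
#'
#' Least-squares fit of `r(t) = r0 + r1 sin(omega t + phi)` to the bin
#' rates, linear in `(r0, a, b)` with `a = r1 cos(phi)`, `b = r1 sin(phi)`.
#' The amplitude is reported nonnegative with the phase wrapped into
#' `(-pi, pi]`. A flat histogram yields `r1 = 0` and `phi = 0` with the
#' `degenerate` flag set.
#'
#' @param hist a [cycle_histogram()].
#' @param omega angular frequency (rad/s), consistent with the histogram
#'   period (`omega = 2 pi / period`).
#' @return list of class `"sinusoid_fit"`: `r0`, `r1` (Hz), `phi` (rad),
#'   `rss` residual sum of squares, `degenerate` flag.
#' @export
fit_rate_sinusoid <- function(hist, omega = 2 * pi / hist$period) {
  stopifnot(inherits(hist, "cycle_histogram"))
  if (abs(omega * hist$period - 2 * pi) > 1e-6)
    stop("omega inconsistent with the histogram period")
  t <- hist$bin_centers
  X <- cbind(1, sin(omega * t), cos(omega * t))
  fit <- stats::lm.fit(X, hist$bin_rates)
  cf <- fit$coefficients
  r0 <- cf[[1]]
  a <- cf[[2]]   # coefficient of sin
  b <- cf[[3]]   # coefficient of cos
  r1 <- sqrt(a^2 + b^2)
  degenerate <- r1 < 1e-12 * max(abs(r0), 1)
  # r0 + a sin + b cos = r0 + r1 sin(wt + phi), phi = atan2(b, a)
  phi <- if (degenerate) 0 else atan2(b, a)
  structure(list(r0 = r0, r1 = if (degenerate) 0 else r1, phi = phi,
                 rss = sum(fit$residuals^2), degenerate = degenerate),
            class = "sinusoid_fit")
}

#' Generate an inhomogeneous Poisson spike train by thinning
#'
#' Oracle generator for transfer-function tests: spikes at rate
#' `r(t) = r0 + r1 sin(omega t + phi)`.
#'
#' @param r0,r1 offset and modulation amplitude (Hz), `r0 >= r1 >= 0`.
#' @param omega angular frequency (rad/s). @param phi phase (rad).
#' @param duration length (s). @param seed integer seed.
#' @return numeric spike times (s).
#' @export
generate_modulated_poisson <- function(r0, r1, omega, phi = 0, duration,
                                       seed) {
  stopifnot(r0 >= r1, r1 >= 0, duration > 0)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rmax <- r0 + r1
  n_cand <- stats::rpois(1, rmax * duration)
  cand <- sort(stats::runif(n_cand, 0, duration))
  keep <- stats::runif(n_cand) < (r0 + r1 * sin(omega * cand + phi)) / rmax
  cand[keep]
}

#' Stationary firing rate per current level and the suprathreshold slope
#'
#' Computes the mean rate for each constant-current run (after discarding
#' the onset transient) and fits the slope of the frequency-current relation
#' by least squares over the levels above rheobase (nonzero rate).
#'
#' @param spike_times_per_level list of spike-time vectors, one per level.
#' @param currents the current levels (A), strictly increasing.
#' @param duration run length per level (s).
#' @param discard onset transient to drop (s).
#' @return list of class `"fi_curve"`: `currents`, `rates` (Hz), `slope`
#'   (Hz/A, NA with a flag if fewer than 2 suprathreshold levels).
#' @export
fi_curve <- function(spike_times_per_level, currents, duration,
                     discard = 0.5) {
  stopifnot(length(spike_times_per_level) == length(currents),
            length(currents) >= 3, all(diff(currents) > 0),
            duration > discard)
  rates <- vapply(spike_times_per_level, function(st) {
    sum(st > discard) / (duration - discard)
  }, 0)
  supra <- rates > 0
  if (sum(supra) >= 2) {
    cf <- stats::lm.fit(cbind(1, currents[supra]), rates[supra])$coefficients
    slope <- cf[[2]]
    flagged <- FALSE
  } else {
    slope <- NA_real_
    flagged <- TRUE
  }
  structure(list(currents = currents, rates = rates, slope = slope,
                 no_suprathreshold = flagged),
            class = "fi_curve")
}

#' Frequency-current curve of a preparation under background conductances
#'
#' Runs the simulated cell at each current level on top of a balanced OU
#' background at the given scale and summarizes with [fi_curve()].
#'
#' @param params neuron parameters.
#' @param currents constant current levels (A), strictly increasing.
#' @param scale background multiplier (0 disables the background).
#' @param duration per-level run length (s). @param dt step (s).
#' @param seed integer seed (per-level child streams).
#' @param discard onset transient (s).
#' @param ... forwarded to [background_conductances()].
#' @return a [fi_curve()] with the background scale attached.
#' @export
measure_fi_curve <- function(params, currents, scale = 0, duration = 5,
                             dt = 5e-5, seed = 1, discard = 0.5, ...) {
  spikes <- lapply(seq_along(currents), function(i) {
    if (scale > 0) {
      bg <- background_conductances(scale, duration, dt,
                                    seed = seed + 1000L * i, ...)
      sim <- simulate_neuron(params, duration, dt, I_ext = currents[i],
                             G_e = bg$G_e$values, G_i = bg$G_i$values,
                             record_v = FALSE)
    } else {
      sim <- simulate_neuron(params, duration, dt, I_ext = currents[i],
                             record_v = FALSE)
    }
    sim$spike_times
  })
  out <- fi_curve(spikes, currents, duration, discard)
  out$background_scale <- scale
  out
}

#' Interspike-interval statistics
#'
#' @param spikes spike times (s), at least 2.
#' @param n_bins histogram bins (log-spaced).
#' @return list with `isi` (s), `mean`, `cv` (sd/mean) and a log-binned
#'   histogram (`breaks`, `counts`).
#' @export
isi_stats <- function(spikes, n_bins = 30L) {
  stopifnot(length(spikes) >= 2)
  isi <- diff(sort(spikes))
  m <- mean(isi)
  cv <- stats::sd(isi) / m
  pos <- isi[isi > 0]
  breaks <- exp(seq(log(min(pos)), log(max(pos)), length.out = n_bins + 1L))
  breaks[1] <- breaks[1] * (1 - 1e-9)
  breaks[length(breaks)] <- breaks[length(breaks)] * (1 + 1e-9)
  counts <- as.integer(table(cut(pos, breaks, labels = FALSE)))
  h_counts <- integer(n_bins)
  idx <- as.integer(names(table(cut(pos, breaks, labels = FALSE))))
  h_counts[idx] <- counts
  list(isi = isi, mean = m, cv = cv,
       histogram = list(breaks = breaks, counts = h_counts))
}
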