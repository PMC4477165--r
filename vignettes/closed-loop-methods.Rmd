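---
title: "Simulated closed-loop electrophysiology: models, controllers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated closed-loop electrophysiology: models, controllers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamploop)
```

`clamploop` emulates a reconfigurable block library for closed-loop
cellular electrophysiology, with every protocol running against simulated
preparations. This vignette is the package's own account of the models it
integrates, the controllers it implements, the parameters that matter, and
the choices made where the design was genuinely open.

## The execution model

Protocols are compositions of blocks advanced at a fixed step. Within a
step, blocks fire in a topological order over the forward wires; any loop
must be closed by a wire explicitly flagged as *feedback*, which carries a
one-step delay register with a declared initial value. This mirrors how a
sample-and-hold acquisition loop actually behaves — the current computed at
step $n$ is based on the potential recorded at step $n$, and reaches the
cell during step $n+1$ — and deliberately rules out algebraic-loop solving:
a mis-declared loop is an error, never a silently inserted delay.

Model time is derived as $t = n\,\Delta t$ from the step index, never
accumulated by repeated addition. The default step is
$\Delta t = 50\,\mu\mathrm{s}$ (20 kHz), in the range of typical
acquisition rates for these protocols (15–50 kHz); conductance-based
neuron models require $\Delta t \le 25\,\mu\mathrm{s}$. The step count of a
run is $\lfloor \mathrm{duration}/\Delta t \rfloor$, computed with a small
relative guard so that exact multiples are not lost to floating-point
division.

Determinism is a contract: a `(configuration, seed)` pair reproduces a run
bit-for-bit. Two mechanisms support this. First, every stochastic block
draws from an independent child stream keyed by its name, so adding a
logging channel or another noise source never perturbs the noise seen by
existing blocks. Second, the compiled per-step loops are built with
floating-point contraction disabled, so the compiled route and the
interpreted reference route produce identical trajectories — the test
suite asserts this step-for-step for every neuron model.

All internal quantities are SI (V, A, S, F, s); configuration boundaries
accept mV/pA/nA/nS/ms with explicit conversion. This prevents the silent
factor-of-10³ unit errors that conductance-clamp setups are notorious for.

## The simulated preparations

The neuron models are the canonical published forms: leaky, quadratic and
adaptive exponential integrate-and-fire cells, the 1952 squid-axon
conductance model, and the reduced Traub–Miles model; the synapse is the
Tsodyks–Markram short-term depression/facilitation model. Integration is
explicit Euler at the engine step, with refractoriness implemented by
clamping at the reset potential. Between events the synapse dynamics are
linear, so its stepper uses the exact exponential discretization and its
steady state on a regular train matches the closed-form depression fixed
point to machine precision.

The shipped default preparation is an adaptive exponential IF cell
calibrated to a layer-5 pyramidal phenotype: resting input conductance
$g_L = 10$ nS, rest at $-70$ mV, rheobase threshold at $-50$ mV, membrane
time constant 20 ms ($C = 200$ pF), slope factor $\Delta_T = 2$ mV, spike
detected at $V_{thresh} + 5\Delta_T$, reset to $-60$ mV with 2 ms
refractoriness, adaptation $a = 2$ nS, $b = 40$ pA, $\tau_w = 144$ ms.
With this cell the conventional rule of unitary synaptic conductances at
2% and 6% of the resting input conductance gives $g_e = 0.2$ nS and
$g_i = 0.6$ nS concretely.

The pipette electrode is a series resistance with a parallel capacitance:
the electrode voltage drop relaxes toward $R_s I$ with
$\tau_e = R_s C_e$ (defaults 20 MΩ, 20 pF, i.e. $\tau_e = 0.4$ ms —
deliberately slower than a well-compensated pipette so that compensation
tests are demanding).

## Background synaptic conductances

Rather than simulating every synaptic event, the background is generated
under the diffusion approximation: each channel is an Ornstein–Uhlenbeck
process whose stationary mean and standard deviation follow the virtual
presynaptic rate,

$$\bar G_x = g_x \tau_x R_x, \qquad
  G_{Sx} = \sqrt{g_x^2 \tau_x R_x / 2}, \qquad
  D_x = G_{Sx}^2/\tau_x .$$

The variance expression is read as the standard point-conductance result
(it is the only dimensionally consistent reading of the
$\tfrac12 g^2\tau^2 R/\tau$ form). The Euler–Maruyama update is

$$G' = G + \Delta t\,(\bar G - G)/\tau + \sqrt{2 D \Delta t}\; \xi,$$

and negative excursions are *not* reflected or clipped inside the process —
clipping to zero happens only at the injection point, preserving the OU
statistics internally (the common dynamic-clamp convention). A 100 s run
reproduces the analytic mean within 1%, the standard deviation within 3%
and the correlation time within 5% at a fixed seed.

Time-varying rates map to time-varying $(\bar G(t), G_S(t), D(t))$ targets
evaluated every step, with the relaxation still governed by the fixed
$\tau_x$; the modulation is therefore low-passed by the synaptic time
constant. The `sine_modulated_background` protocol exposes this as its
*with synaptic filtering* variant; the *without filtering* variant adds the
modulated mean directly to a stationary zero-mean OU fluctuation, so only
the fluctuation — not the modulation — is low-passed. A phase parameter
(default 0) is provided for the modulation.

The balance solver returns the inhibitory rate that zeroes the mean
injected current at a voltage $V_b$,
$R_i = g_e \tau_e R_e (E_e - V_b) / (g_i \tau_i (V_b - E_i))$, with
$E_e = 0$ mV and $E_i = -80$ mV. The default $V_b = -51.85$ mV sits 1.85 mV
below the default threshold and makes the reference condition
$R_e = 7000\ \mathrm{Hz} \mapsto R_i = 2149\ \mathrm{Hz}$ exactly.

## Active electrode compensation

The electrode kernel is identified from a uniformly distributed
current probe (default ±200 pA for 10 s): the recorded potential is
regressed on the lagged probe current over $n$ taps (default 15 ms of
lags) with an intercept; the probe columns are scaled to unit variance for
conditioning, and an optional ridge term is exposed for noisy probes
(default 0). The membrane component is an exponential tail
$(R_m \Delta t/\tau_m)\,e^{-k\Delta t/\tau_m}$ fitted log-linearly to the
kernel beyond `membrane_tail_start` (default 3 ms) and subtracted from all
lags; in the simulated ladder circuit the commanded current reaches the
membrane unfiltered by the electrode, so this direct subtraction is the
exact correction and recovery of $(R_s, R_m, \tau_m)$ on simulated
circuits is the package's acceptance surface for this module. Online, the
compensated potential is
$\hat V_n = V^{rec}_n - \sum_k K_k I_{n-k}$ over a ring buffer of the last
$n$ injected-current samples; a disabled compensator passes the recording
through unchanged.

Compensation in the loop matters because conductance injection feeds the
measured potential back into the injected current: artifactual voltage from
the electrode creates positive feedback. The discrete loop gain is
approximately $G_{tot}\,\Delta R$, with $G_{tot}$ the total injected
conductance and $\Delta R$ the compensation error; with the default
electrode and a 3× background, a kernel over-estimated by 2× exceeds unit
loop gain and the run diverges — the engine's divergence detector
(non-finite state or $|V| > 1$ V) reports the offending step, and the test
suite asserts that it fires.

## Controllers

All controllers are sample-and-hold: outputs update at discrete events and
are exactly constant in between.

**Firing-rate clamp.** At each spike the rate estimate is updated by
exponential-in-interval weighting
$r \leftarrow r\,e^{-\mathrm{isi}/\tau_r} + (1/\mathrm{isi})(1 - e^{-\mathrm{isi}/\tau_r})$
(the estimator is specified only as a weighted average between history and
the inverse interval; the exponential weighting mirrors the probability
estimator and has a single timescale, default $\tau_r = 1$ s). The PID
accumulates the rate error per event (no $\Delta t$ factor), with the
derivative taken between consecutive events, and maps error in Hz to
current in nA — the gain convention under which the printed values
$P = 0.0045, I = 0.0023, D = 0$ hold a 17 Hz setpoint. The held current is
$I_0 + \mathrm{PID}(\cdot)$: the constant offset mirrors the $S_1$ term of
the stimulus-intensity law and defaults to the cell's quiescent rheobase
$g_L (V_{thresh} - E_L)$, so the spike-triggered controller receives
events from the outset (a controller that only updates on spikes cannot
start a silent cell).

**Voltage hold.** A PI law on the voltage error, integrated in V·s and
scaled to nA ($P_{pid} = 10$, $I_{pid} = 100$ defaults), with a gate: while
the gate is closed — e.g. from 10 ms before to 500 ms after each
extracellular stimulus — both the output and the integral accumulator are
frozen, so control resumes without windup. On the default preparation the
hold settles within 0.5 mV in under 2 s.

**Response-probability clamp.** After stimulus $n$, the sliding estimate
$p_n = p_{n-1} e^{-ISI/\tau} + F(1 - e^{-ISI/\tau})$ ($\tau = 600$ s,
$F = 1$ iff a spike occurred in the triggered logging window) feeds
$S_{n+1} = S_1 + G(P_{pid}\,EP_n + I_{pid}\,EI_n)$ with per-stimulus,
dimensionless error accumulation. $p$ is initialized at the target for
fast lock-in (configurable to 0). Responding is defined as at least one
detected spike in the 10 ms-pre/500 ms-post window. $S$ is a dimensionless
stimulator command mapped to biphasic pulse amplitude (symmetric,
positive-first, 200 µs phases) by a configurable scale.

**EPSP-size clamp.** The same two laws with $F$ replaced by the measured
PSP peak amplitude (extremum in a search window minus the mean of a
baseline window, signed by polarity) and $\tau = 300$ s for the sliding
amplitude average; the error is expressed in mV so that the printed gains
($P_{pid} = 1$, $I_{pid} = 0.3$, $G = 1600$) operate at a sensible
stimulator scale.

## The synthetic drift preparation

The response-probing clamps are demonstrated on tissue in the original
protocols; here they run against an explicitly synthetic stand-in whose
parameters are fixture choices, not biological claims. The preparation's
stimulus–response threshold $\theta(t)$ performs a slow OU walk
($\tau = 120$ s; sd 10% of the recruitment dynamic range) and a stimulus
of intensity $S$ evokes a spike with probability
$\mathrm{logit}^{-1}((S - \theta)/k)$ — a sigmoidal recruitment curve of
width $k = 50$ command units around $\theta_0 = 300$. For the EPSP variant
the threshold is fixed, the recruitment curve drives a Tsodyks–Markram
synapse ($U = 0.5$, $\tau_{rec} = 0.5$ s, facilitation off — fully
recovered at 4 s intervals), the synaptic efficacy drifts multiplicatively
(OU, $\tau = 120$ s, sd 15%), the full-recruitment PSP is 2 mV (so the
initial working point is 0.5 mV), and measurement noise of 0.05 mV is
added to each amplitude. The recruitment width was chosen once so that the
printed controller gains operate in a stable, well-damped regime (the
dimensionless integral-loop gain per stimulus,
$G\,I_{pid}\,\alpha\,\mathrm{d}A/\mathrm{d}S \approx 0.03$); it was not
revisited afterwards.

Stimulus sequences run in compressed time: the threshold is advanced
between stimuli by the exact OU transition over one inter-stimulus
interval (default 4 s, within the conventional 3–5 s range), so a
300-stimulus session needs no sub-interval integration. Because the real
inter-stimulus interval is preserved, the estimator timescales
($\tau = 600$ s, $\tau = 300$ s) are used as printed, with no additional
rescaling.

Replaying a recorded closed-loop stimulus sequence in open loop against a
fresh drift realization reproduces the well-known asymmetry: without
feedback the probability estimate inherits the full threshold drift and
its variance exceeds the closed-loop variance in the large majority of
paired-seed repetitions (the suite asserts the paired-mean inequality and
at least 75% of 20 pairs, since two slow OU realizations can occasionally
produce a quiet open-loop window).

## What the generators emulate — and what they do not

The simulated preparations reproduce the *control-theoretic* structure of
the experiments: conductance-dependent gain, fluctuation-driven irregular
firing, electrode artifacts, slow excitability drift, synaptic depression.
They do not model multicompartment morphology, stochastic channel noise,
temperature, electrode nonlinearities, or the biological origin of
excitability fluctuations — the drift model is a declared stand-in.
Passing tests therefore certify the protocols' closed-loop behavior and
the implementation's correctness, not biological fidelity of any
particular trace.

## Numerical and statistical choices

- Explicit Euler throughout for the neuron models (matching the fixed-step
  per-sample execution the protocols assume); the synapse and the
  event-driven drift updates use exact exponential transitions.
- The adaptive exponential current is evaluated with its exponent capped at
  10 — the spike fires at $V_{thresh} + 5\Delta_T$ before the cap can
  distort the trajectory.
- Degenerate inputs are errors, not guesses: cycles without feedback
  flags, constant probes (rank-deficient designs), non-decaying kernel
  tails, windows outside segments, balance voltages outside
  $(E_i, E_e]$.
- Cycle histograms use 32 bins per cycle and runs discard a 0.5 s onset
  transient by default; a flat histogram is fitted as $r_1 = 0$ with the
  phase reported as 0 and flagged degenerate; fitted amplitudes are
  reported nonnegative with the phase wrapped into $(-\pi, \pi]$.
- Problem sizes in the shipped tests — 60 s clamp runs at 50 µs, 10 s
  electrode probes, 300-stimulus sessions, $10^4$–$10^5$ modulation cycles,
  20 replay pairs — were chosen as the smallest runs at which each
  statistical tolerance is meaningful for a single fixed seed.
- Recovery of the sinusoidal transfer parameters from modulated-Poisson
  spikes is information-limited: the standard error of the fitted
  modulation amplitude is $\sqrt{2 r_0 / T}$, about 0.45 Hz (15% of
  $r_1 = 3$ Hz) at $10^4$ cycles of a 10 Hz process. Consistency tests
  therefore use bands of four standard errors at the stated cycle count; a
  5% claim on $r_1$ only becomes a $2\sigma$ statement around
  $4 \times 10^5$ cycles.

## Known limitations

- The block-graph engine is interpreted and intended for composition and
  moderate run lengths; the shipped protocols run their inner loops in
  compiled code. Both routes are tested for exact agreement on the models
  they share.
- Electrode/membrane separation assumes a single-exponential membrane and
  an electrode faster than `membrane_tail_start`; pathological pipettes
  with time constants overlapping the membrane's would need the full
  iterative separation procedure.
- The stimulator command is dimensionless; mapping to physical pulse
  amplitude is left to the configuration, as device units vary.
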