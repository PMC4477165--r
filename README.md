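# clamploop

Closed-loop cellular electrophysiology protocols — dynamic clamp, active
electrode compensation, firing-rate / response-probability / EPSP-size
clamps — run at the desk against **simulated neuronal preparations** instead
of acquisition hardware.

Real-time electrophysiology rigs compose their experiments from small
processing blocks: signal sources, the patched cell and its pipette, spike
detectors, sample-and-hold controllers, loggers. `clamploop` reimplements
that block library as an R package in which every preparation is an
in-silico model (integrate-and-fire and conductance-based neurons, a
Tsodyks–Markram synapse, an RC pipette electrode), so closed-loop protocols
can be developed, debugged and characterized quantitatively before any cell
is patched. It is aimed at cellular electrophysiologists and methods
developers who want an executable, reproducible reference for these
protocols.

## What it implements

**Conductance injection (dynamic clamp).** At every step the injected
current is recomputed from the instantaneous membrane potential:

    I_syn(t) = G_e(t) (E_e − V) + G_i(t) (E_i − V)

with excitatory/inhibitory background conductances generated under the
point-conductance diffusion approximation as Ornstein–Uhlenbeck processes,

    dG_x/dt = (Ḡ_x − G_x)/τ_x + √(2 D_x) ξ(t),   x ∈ {e, i}

whose stationary moments follow the presynaptic rates: `Ḡ_x = g_x τ_x R_x`,
`G_Sx² = g_x² τ_x R_x / 2`, `D_x = G_Sx²/τ_x`. Rates can be sinusoidally
modulated, `R_x(t) = R_x0 + R_x1 sin(ωt)`, and the inhibitory rate can be
solved to balance the mean injected current at a voltage V_b:
`0 = ⟨G_e⟩(E_e − V_b) + ⟨G_i⟩(E_i − V_b)`.

**Active electrode compensation (AEC).** The pipette's lag-indexed impulse
response (kernel) is identified by least squares from a uniform-noise
current probe, separated from the membrane's exponential component by a
tail fit, and the convolution of the injected current with the electrode
kernel is subtracted from the recorded potential sample by sample.

**Sample-and-hold controllers.**
- *Firing-rate clamp*: a spike-triggered estimator
  `r ← r e^(−isi/τ_r) + (1/isi)(1 − e^(−isi/τ_r))` feeds a PID law whose
  output current updates only at spike arrivals.
- *Response-probability clamp*: a sliding estimate
  `p_n = p_{n−1} e^(−ISI/τ) + F (1 − e^(−ISI/τ))` (F = 1 if the stimulus
  evoked a spike) drives the next extracellular stimulus intensity through
  `S_{n+1} = S_1 + G (P_pid EP_n + I_pid EI_n)` with `EP_n = p_target − p_n`,
  `EI_n = EI_{n−1} + EP_n`.
- *EPSP-size clamp*: the same laws with F replaced by the measured PSP peak
  amplitude.
- *Gated PI voltage hold*: holds the membrane at a target potential and is
  frozen (output and integral) around each stimulus window.

**Engine and analyses.** A fixed-step block-graph executor with explicitly
declared one-step-delay feedback edges, triggered logging windows
(10 ms pre / 500 ms post), cycle histograms with sinusoidal transfer fits
`r(t) = r0 + r1 sin(ωt + φ)`, F–I curves with gain (slope) measurement, and
ISI statistics.

## Worked example

Clamp the firing rate of the default layer-5-like adaptive exponential IF
preparation at 17 Hz while it receives a balanced high-conductance
background (R_e = 7000 Hz, R_i = 2149 Hz; g_e = 0.2 nS, g_i = 0.6 nS,
τ_e = 5 ms, τ_i = 10 ms):

```r
library(clamploop)
res <- run_protocol(protocol_config("firing_rate_clamp",
                                    duration = 60, dt = 5e-5, seed = 1,
                                    target_rate = 17,
                                    P = 0.0045, I = 0.0023, D = 0))
str(res$summary)
#> List of 5
#>  $ target         : num 17
#>  $ mean_rate_final: num 16.9
#>  $ final_window   : num 20
#>  $ R_e            : num 7000
#>  $ R_i            : num 2149
```

`mean_rate_final` is the measured firing rate over the final 20 s of the
60 s run: the spike-triggered PID holds the cell within 1% of the 17 Hz
setpoint despite the fluctuation-driven, irregular firing regime
(`R_i = 2149` is the inhibitory rate that balances the mean background
current just below threshold). The same registry exposes
`conductance_clamp`, `sine_modulated_background`, `voltage_hold`,
`response_probability_clamp` and `epsp_size_clamp`; a thin command-line
wrapper is installed under the package's `exec/` directory (sample configs
ship in `inst/extdata/`):

```sh
cli=$(Rscript -e 'cat(file.path(find.package("clamploop"), "exec", "clamploop"))')
Rscript "$cli" run config.yml --seed 1 --out runs/
Rscript "$cli" analyze runs/firing_rate_clamp_log.tsv --what isi
```

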