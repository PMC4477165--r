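# EPSP-size clamp against the synthetic drifting-efficacy preparation.
protocol: epsp_size_clamp
n_stimuli: 300
ISI: 4
target_amplitude_mV: 0.5
tau: 300
P_pid: 1
I_pid: 0.3
G: 1600
seed: 1
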