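# Spike-triggered PID firing-rate clamp on the default preparation under a
# balanced 1x high-conductance background.
protocol: firing_rate_clamp
duration: 60
dt_ms: 0.05
seed: 1
target_rate: 17
P: 0.0045
I: 0.0023
D: 0
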