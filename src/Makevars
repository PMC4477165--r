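# Disable floating-point contraction so the compiled per-step updates are
# bit-identical to the interpreted reference route (the determinism contract
# of the engine is tested step-for-step).
PKG_CXXFLAGS = -ffp-contract=off
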