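coordination_group,inverse_duration_amplitude,temporal_invariance,late_impulse
wrist,4,5,5
forearm,7,6,6
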