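# Run parameters for the fly locomotion / AIM pipeline.
pixels_per_mm: 1
frame_rate: 30.06
window_s: 21
threshold_c: 0.4
freeze_epsilon_mm: 0.05
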