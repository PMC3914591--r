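# Five-class short-segment synthetic preset: single-channel segments,
# window-length grid as used for short-term recordings.
preset: bonn
n_signals_per_class: 20
signal_length: 4096
window_grid: [64, 128, 256, 512]
window_length: 512
scheme: both
k: 10
seed: 1
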