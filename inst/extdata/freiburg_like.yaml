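# Two-class long-record synthetic preset: near-equal power, distinct
# spectral peaks; records written as multi-column CSV.
preset: freiburg
n_signals_per_class: 16
signal_length: 32768
window_grid: [512, 768, 1024, 1280]
window_length: 512
scheme: both
k: 10
seed: 1
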