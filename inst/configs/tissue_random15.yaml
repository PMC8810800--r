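stage: tissue
species: human
pattern: random
fraction: 0.15
nx: 100.0
ny: 100.0
dx_cm: 0.01
x_level: 0.0
seed: 1.0
dt_ms: 0.01
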