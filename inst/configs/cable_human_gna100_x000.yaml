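stage: cable
species: human
x_level: 0.0
gNa_scale: 1.0
n_cells: 100.0
dt_ms: 0.01
ri_kohm_cm: 0.4
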