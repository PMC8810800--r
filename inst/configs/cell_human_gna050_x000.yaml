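stage: cell
species: human
pacing_hz: 1.0
x_level: 0.0
gNa_scale: 0.5
dt_ms: 0.01
criterion_pct: 0.01
max_beats: 50.0
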