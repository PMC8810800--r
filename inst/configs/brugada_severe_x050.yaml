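stage: brugada
severity: severe
x_level: 0.5
pacing_hz: 3.33
dt_ms: 0.01
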