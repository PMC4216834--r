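# Minimal two-population model, transient synchrony near the fold: K_T = 5.5, K_C = 1.2
seed: 1
populations:
  thalamus: {center_hz: 9.25, half_width_hz: 1.25, n: 1000}
  theta: {center_hz: 6, half_width_hz: 1.5, n: 1000}
couplings:
  k_thal_to_cortex: [5.5]
  k_cortex_to_thal: [1.2]
stimulus: {intensity: 100, onset_ms: 0, duration_ms: 50}
integration: {dt_ms: 0.1, t0_ms: -100, t1_ms: 1000, thin: 10}
task:
  name: simulate
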