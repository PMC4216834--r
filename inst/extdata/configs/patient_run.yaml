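# Three-population model (thalamus + theta + alpha), patient-like feedback (reduced K_C)
seed: 1
populations:
  thalamus: {center_hz: 9, half_width_hz: 2, n: 1000}
  theta: {center_hz: 6, half_width_hz: 0.3, n: 1000}
  alpha: {center_hz: 10, half_width_hz: 1.25, n: 1000}
couplings:
  k_thal_to_cortex: [1.35, 1.7]
  k_cortex_to_thal: [0.5, 0.5]
stimulus: {intensity: 100, onset_ms: 0, duration_ms: 50}
integration: {dt_ms: 0.1, t0_ms: -100, t1_ms: 1200, thin: 10}
task:
  name: simulate
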