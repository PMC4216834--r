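# Feedback-plane scan of the three-population model plus calibration to
# the patient synchronization targets (theta 0.30, alpha 0.19).
seed: 1
populations:
  thalamus: {center_hz: 9, half_width_hz: 2, n: 1000}
  theta: {center_hz: 6, half_width_hz: 0.3, n: 1000}
  alpha: {center_hz: 10, half_width_hz: 1.25, n: 1000}
couplings:
  k_thal_to_cortex: [1.35, 1.7]
  k_cortex_to_thal: [1, 1]
stimulus: {intensity: 100, onset_ms: 0, duration_ms: 50}
task:
  name: calibrate
  engine: reduced
  targets: patient
  axis1: {coupling: k_ct, band: 1, from: 0.5, to: 10, by: 0.5}
  axis2: {coupling: k_ct, band: 2, from: 0.5, to: 10, by: 0.5}
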