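# Coarse (K_C, K_T) scan of the minimal model with the reduced engine:
# max SLI and peak frequency of the theta band per cell.
seed: 1
populations:
  thalamus: {center_hz: 9.25, half_width_hz: 1.25, n: 1000}
  theta: {center_hz: 6, half_width_hz: 1.5, n: 1000}
couplings:
  k_thal_to_cortex: [5.5]
  k_cortex_to_thal: [1.2]
stimulus: {intensity: 100, onset_ms: 0, duration_ms: 50}
task:
  name: scan
  engine: reduced
  axis1: {coupling: k_ct, band: 1, from: 0, to: 10, by: 0.5}
  axis2: {coupling: k_tc, band: 1, from: 0, to: 10, by: 0.5}
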