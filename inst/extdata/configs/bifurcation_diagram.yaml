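# One-parameter bifurcation diagram of the reduced minimal model:
# K_C fixed at 1.2, K_T swept; locates the Hopf point and the fold of
# limit cycles and labels regions I/II/III.
seed: 1
populations:
  thalamus: {center_hz: 9.25, half_width_hz: 1.25, n: 1000}
  theta: {center_hz: 6, half_width_hz: 1.5, n: 1000}
couplings:
  k_thal_to_cortex: [5.5]
  k_cortex_to_thal: [1.2]
stimulus: {intensity: 100, onset_ms: 0, duration_ms: 50}
task:
  name: bifurcate
  vary: k_tc
  band: 1
  from: 1
  to: 18
  by: 1
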