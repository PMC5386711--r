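# Scaled-down demo configuration for a fast end-to-end run:
#   progressionscope run --config demo_config.yaml --out results/
seed: 1
synthetic:
  n_mirnas: 120
  n_mrnas: 600
  group_fractions: {G1: 0.10, G2: 0.05, G3: 0.10, G4: 0.05, none: 0.70}
  n_true_edges_per_regulator: 20
  decoy_edge_rate: 0.02
trajectory:
  fc_threshold: 1.5
  p_threshold: 0.05
  early_transitions: [1, 2]
  normalize: none
integration:
  q_threshold: 0.25
  signature_fc: 1.5
  signature_p: 0.05
survival:
  alpha: 0.05
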