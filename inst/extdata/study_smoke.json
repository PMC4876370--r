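{
  "T_values": [10, 25],
  "N_values": [10],
  "sigma_u1_values": [0.25, 0.4],
  "gamma01_values": [-0.3, 0, 0.3],
  "replications": 50,
  "estimators": ["MLE-F", "MLE-R"],
  "alpha": 0.05,
  "master_seed": 1,
  "mcmc": {"chains": 4, "iterations": 3000, "burn_in": 1500}
}
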