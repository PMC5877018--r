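# Example pipeline configuration: a small synthetic study run end to end.
scenario:
  n_ct: 40
  cbg_per_ct: 3
  cbk_per_cbg: 1
  "n": 1500   # quoted: bare n is YAML shorthand for a boolean
  rho: 0.7
  sigma_cbg: 0.1
  sigma_ct: 0.1
  sigma_eps: 0.9
  exclusions:
    underweight: 30
    race: 10
    missing: 2
ss:
  epsilon: 1
  step_size: 0.001
  tolerance: 0.01
  alpha: 0.05
algorithms: [stepwise, stagewise, lars, lasso]
seed: 20
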