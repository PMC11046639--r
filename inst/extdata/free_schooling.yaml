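# free-schooling run at the paper-scale protocol (50 agents, 15 s)
n_agents: 50
duration_s: 15
dt_s: 0.01
master_seed: 1
model:
  eta: 1.0
  alpha: 0.5
  lambda_z: 1.0
experiment:
  protocol: simulate
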