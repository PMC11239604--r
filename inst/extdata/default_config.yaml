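# Default trial configuration: the worked example used throughout hierpower.
# 20 hospitals (the independent sampling units) x 8 clinics x 6 providers
# x 6 participants; three-level exchangeable cluster correlation model;
# 8 independent unit-variance outcomes averaged into an unweighted composite;
# the intervention shifts only outcome 1 (diet).
levels:
  isu: 20
  l2: 8
  l3: 6
  l4: 6
iccs:
  provider: 0.05
  clinic: 0.01
  hospital: 0.01
sigma2: 1.0
n_outcomes: 8
outcome_covariance: identity
subgroups: true          # 10 rural / 10 urban hospitals
affected_outcome: 1
alpha: 0.05
effect_grid:
  max: 1.0               # 1.0 = one SD of a single outcome
  points: 100
reps: 10000
seed: 2024
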