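# Tiny deterministic preset for fast checks: 4 observers with slope 0
# (deterministic threshold responding), no lapses, no between-subject
# variability, two orientations.
name: toy
rotation_axis: yaw
angles: [0, 30]
population:
  n_subjects: 4
  baseline_mean: 100
  baseline_sd: 0
  shadow_mean: 3
  shadow_sd: 0
  orientation_mean: 0
  orientation_sd: 0
  interaction_mean: 0
  interaction_sd: 0
  slope: 0
  lapse_rate: 0
staircase:
  level_min: 92
  level_max: 108
  step: 1
  reversal_criterion: 6
  max_trials: 200
epsilon_method: cm
pse_method: pool
bf_n_samples: 1000
alpha: 0.05
seed: 1
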