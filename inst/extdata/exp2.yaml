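# Pitch-rotation experiment preset: same protocol as exp1 with a narrower
# angle range (0, +/-15, +/-30 degrees) and a larger mean illusion.
name: exp2
rotation_axis: pitch
angles: [-30, -15, 0, 15, 30]
population:
  n_subjects: 20
  baseline_mean: 100
  baseline_sd: 1
  shadow_mean: 3.65
  shadow_sd: 1
  orientation_mean: 0
  orientation_sd: 0
  interaction_mean: 0
  interaction_sd: 0
  slope: 2
  lapse_rate: 0.02
staircase:
  level_min: 92
  level_max: 108
  step: 1
  reversal_criterion: 6
  max_trials: 200
epsilon_method: cm
pse_method: pool
bf_n_samples: 10000
alpha: 0.05
seed: 20190706
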