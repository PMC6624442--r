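# Yaw-rotation experiment preset: 20 observers, eyeshadow x 5 orientations
# (0, +/-30, +/-60 degrees), comparative grid 92-108% in 1% steps, four
# interleaved staircases per block terminating after 6 reversals.
name: exp1
rotation_axis: yaw
angles: [-60, -30, 0, 30, 60]
population:
  n_subjects: 20
  baseline_mean: 100
  baseline_sd: 1
  shadow_mean: 2.42
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
seed: 20190705
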