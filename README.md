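# illusim

Simulation and inference for staircase measurements of face size illusions
— built around the eyeshadow illusion, the overestimation of eye size
induced by eyeshadow on the upper eyelids, and the question of whether that
illusion survives rotating the face away from the frontal view.

`illusim` is for psychophysicists and methodologists who want to study the
*measurement chain* of such experiments rather than collect new human data:
it simulates two-alternative forced-choice observers, runs the interleaved
1-up/1-down staircase protocol against them, estimates points of subjective
equality (PSEs) by reversal averaging, and applies the full inferential
toolkit those studies report — two-way fully-within-subject ANOVA with
sphericity-corrected degrees of freedom and default g-prior Bayes factors.
Because every run has a configured ground truth, estimator bias, test
calibration and evidence behaviour can all be scored exactly.

## The model in brief

An observer judges which of two faces has larger eyes. The probability of
choosing the comparative face of size *x* (percent of the original eye
size) is a lapse-mixed cumulative Gaussian,

P(comparative larger) = λ + (1 − 2λ) Φ((x − PSE) / σ),

whose cell-wise PSE is additive in a subject baseline, the eyeshadow shift,
and optional orientation and interaction shifts. Four interleaved
staircases per orientation (ascending/descending × eyeshadow/plain, grid
92–108 % in 1 % steps) each terminate after six direction reversals; the
PSE estimate is the mean of the pooled reversal levels. The PSE table then
feeds:

* `two_way_rm_anova()` — classical within-subject decomposition, partial
  η² = F·df₁/(F·df₁ + df₂), Greenhouse–Geisser / Huynh–Feldt /
  Lecoutre-corrected ε, and ε-corrected p-values;
* `anova_bf()` / `bayes_factor()` — default g-prior Bayes factors (r = 1/2
  for fixed, 1 for subject effects; one g per effect family, integrated by
  seeded defensive-mixture importance sampling with a reported Monte Carlo
  error), comparing each main effect against a subject-only null and the
  interaction against the two-main-effects model.

## A worked example

```r
library(illusim)

res <- run_pipeline(preset_config("exp1", seed = 20190705))
res
#> Run: exp1 (seed 20190705)
#> Eyeshadow illusion: 1.97% on average (SE 0.20)
#>
#> shadow: F(1.00, 19.00) = 102.13, eta_p^2 = .843, p < .001, epsilon = 1.00
#> orientation: F(3.35, 63.71) = 2.36, eta_p^2 = .110, p = .073, epsilon = 0.84
#> interaction: F(3.92, 74.52) = 1.47, eta_p^2 = .072, p = .221, epsilon = 0.98
#>
#> shadow: BF = 1.01 x 10^34 (strong alternative)
#> orientation: BF = 0.05 (strong null)
#> interaction: BF = 0.15 (substantial null)
```

The `exp1` preset simulates 20 observers with a viewpoint-invariant
2.42 % eyeshadow illusion across five yaw orientations (0°, ±30°, ±60°).
The run recovers an illusion of 1.97 % (staircase estimates carry a small
compressive bias plus sampling noise; see the vignette), an overwhelming
Bayes factor for the eyeshadow effect, and null-range Bayes factors for
orientation and — decisively for the scientific question — for the
orientation × eyeshadow interaction: the simulated illusion does not vary
with viewpoint, and the analysis says so. Per-angle summaries come from
`illusion_magnitude(res$pse)`:

```r
illusion_magnitude(res$pse)
#> # A tibble: 6 × 5
#>   angle   mean_magnitude    sd    se     n
#>   <chr>            <dbl> <dbl> <dbl> <int>
#> 1 -30               1.99 1.08  0.241    20
#> 2 -60               2.04 1.65  0.370    20
#> 3 0                 1.66 1.08  0.240    20
#> 4 30                2.38 0.963 0.215    20
#> 5 60                1.80 1.37  0.307    20
#> 6 overall           1.97 0.873 0.195    20
```

Everything is a tibble in and out: `tidy()` and `glance()` methods cover
the fitted objects, `autoplot()`/`plot_staircases()`/`plot_illusion()`
draw the standard figures, and `run_pipeline(cfg, out_dir = "...")` writes
full-precision CSV/JSON plus a plain-text report, byte-identical for
identical config and seed. `preset_config("exp2", ...)` gives the
pitch-rotation variant (0°, ±15°, ±30°, mean shift 3.65 %);
`recovery_study()` replicates the whole chain to score bias, RMSE and
coverage.

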