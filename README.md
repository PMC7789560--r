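# hybridreach

Desk-scale simulation and analysis of **hybrid trans-humeral prosthesis
control**: can the four distal joints of an arm (elbow flexion, forearm
pronation-supination, wrist deviation, wrist extension) be driven from the
three residual shoulder angles — and how much does knowing the *goal*
(target position and tilt) help?

The package emulates the full experiment in software:

* a seven-DoF kinematic arm (forward kinematics, joint-angle extraction,
  damped-least-squares inverse kinematics with null-space redundancy
  resolution);
* a pick-and-place task over a 5 × 5 × 2 target grid (8 cm pitch) with five
  frontal-plane tilts, 6-D target zones (spatial + angular tolerance),
  1 s hold-to-complete and 15 s timeout at 90 Hz;
* a **synthetic subject** that generates naturalistic reaching recordings
  (minimum-jerk joint trajectories, filtered motor noise, shoulder sway,
  target-dependent redundancy resolution) and a closed-loop compensating
  user model for hybrid control, including discouraged-but-permitted trunk
  compensation;
* two multilayer-perceptron regressors
  (input → 256 → 256 → dropout 0.5 → 64 → 4): **C+** receives the shoulder
  angles plus target context (egocentric shoulder-to-target vector and
  tilt), **C−** the shoulder angles only;
* the evaluation machinery: pooled offline RMSE, approach time/speed, the
  3-SD shoulder-dispersion ellipsoid volume SV = 36π·σ₁σ₂σ₃ (≈97% coverage
  for normal data), reaching-posture variability, PCA postural synergies,
  principal-angle distances between synergy subspaces
  (θ = arccos σ_min(AᵀB): 0° identical spans, 90° orthogonal), and
  ANOVA/Kruskal-Wallis condition comparisons with Bonferroni-corrected
  post hocs (0.05/3 = 0.0167).

## Worked example

A one-subject miniature of the protocol (acquisition → train C+/C− →
two hybrid test phases → natural baseline), with shortened target orders:

```r
library(hybridreach)

cfg <- experiment_config(
  n_subjects = 1, min_whole = 30, min_subset = 16,
  max_whole = 30, max_subset = 16,      # truncated desk-scale orders
  hyper = predictor_hyper(max_epochs = 40), master_seed = 7)
m <- run_experiment(cfg)

m$results$rmse_table
#>   subject network  dataset      rmse
#> 1       1      C+ training  2.041097
#> 2       1      C- training  2.362876
#> 3       1      C+ baseline  5.869849
#> 4       1      C- baseline 10.139316

m$results$online_table
#>   subject condition   mean_at  mean_as    sv_cm3 success_rate
#> 1       1         N 0.3840278 52.80767  32.58831            1
#> 2       1        C+ 0.7055556 28.58708  39.26961            1
#> 3       1        C- 2.0305556 18.46268 414.43583            1

round(m$analyses[[1]]$dist_to_n, 1)
#>   C+   C-  MC+  MC-
#> 27.6 68.8 12.4 15.2
```

Reading the output: on held-out baseline data the context-aware network
roughly halves the distal prediction error (5.9° vs 10.1° pooled RMSE; on
the small training set both memorise well). Online, natural control (N)
reaches targets fastest (mean approach speed 53 cm/s), hybrid control with
context (C+) is intermediate (29 cm/s) with near-natural shoulder
dispersion, and context-unaware hybrid control (C−) is slowest (18 cm/s)
with an order of magnitude more compensatory trunk motion (SV ≈ 414 cm³ vs
≈ 33 cm³ under N). The synergy subspace of C+ postures lies far closer to
the natural one (27.6°) than C−'s (68.8°) at three principal components.

With ≥ 3 subjects, `m$stats` adds the cross-subject comparisons (paired T
on RMSE; ANOVA/Kruskal-Wallis + corrected post hocs on approach speed,
approach time and SV), and `render_report()` writes the four result tables
(`t-rmse`, `t-online`, `t-variability`, `t-subspace`) with a JSON manifest.

## Documentation

The methods vignette (`vignettes/hybridreach-methods.Rmd`) describes the
arm model and conventions, the inverse-kinematics solver, what the
synthetic subject does and does not emulate, the predictor training
choices, every evaluation metric, and the package's numerical and design
decisions.
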