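# percross

Analysis of dyadic **perceptual-crossing** experiments: a minimal paradigm
of social perception in which two players, isolated from one another, each
move an avatar along an invisible circular 1D space (600 units, wrapping)
with binary tactile feedback whenever their avatar overlaps another object.
Each player can feel three objects — the partner's avatar, a "shadow" decoy
rigidly attached to the partner's avatar 150 units away, and a static lure —
and may click once per trial to claim they found the partner, afterwards
rating the clarity of the partner's perceived presence on the 4-point
Perceptual Awareness Scale (PAS). The scientific question is whether
perceptual clarity tracks an individual's own correct recognition, or only
*mutual* recognition at the level of the dyad.

The package provides the full pipeline for such experiments:

* **Environment**: torus geometry, overlap/sensor mechanics, and a
  scriptable tick-level trial simulator (`world_config()`,
  `simulate_trial()`).
* **Data model**: validated session containers with CSV/JSON round-tripping
  (`session_dataset()`, `read_session()`, `write_session()`).
* **Click classification**: nearest-candidate target assignment with an
  ambiguity flag replacing manual trajectory review
  (`classify_session()`).
* **Descriptives**: click/success/joint-success counts, conditional PAS
  tables, team scores, inter-click-interval densities with a closed-form
  uniform-independence null (`count_summary()`, `interval_density()`,
  `null_interval_cdf()`).
* **Path model**: a hierarchical Bayesian probit path model with piecewise
  learning curves. On the latent probit scale, individual success follows
  `Phi(a_i + b_i (min(t, tau_i) - 1) + lambda_S D)`, joint success
  `Phi(c_j + lambda_G D)`, and PAS an ordinal probit with predictor
  `u_i + v_i (min(t, tauP_i) - 1) + gamma_S S + gamma_G G + gamma_D D`,
  dyad-correlated residuals (`rho`) and free cutpoints, where `D`
  indicates an inter-click delay under 3 s (`pc_fit()`,
  `posterior_summary()`, `indirect_effect()`).
* **Synthetic data** with known ground truth at two fidelity levels
  (`generate_events()`, `generate_behavioral()`), parameter-recovery
  calibration (`pc_recovery()`) and an end-to-end report
  (`run_report()`). A thin command-line front end lives in
  `inst/scripts/percross.R`.

## Worked example

```r
library(percross)

syn <- generate_events(synthetic_config(), seed = 42)  # 10 teams x 20 trials
out <- trial_outcomes(syn$dataset)
count_summary(out)
#> trials 200 | clicks 327/400 (82%) | correct 237 (72%) | joint 71 (36%)
#> PAS 1..4 overall: 21 94 109 96

iv <- out$interclick_interval[out$joint_success & !is.na(out$interclick_interval)]
interval_density(iv)$p_below      # P(interval < 3 s | joint success)
#> [1] 0.227
null_interval_cdf(3, 60)          # the same probability under independence
#> [1] 0.0975
```

A click was produced in 327 of 400 opportunities (82%), 72% of clicks hit
the partner's avatar, and 36% of trials were jointly successful. Jointly
successful clicks cluster in time: the estimated probability of an
inter-click delay under 3 s (0.23) is far above the 0.0975 expected if both
players clicked independently and uniformly — the signature of mutual,
near-synchronous recognition.

Fitting the path model and summarising the posterior:

```r
fit <- pc_fit(pc_model_data(syn$dataset), seed = 1)
posterior_summary(fit)   # means + 95% HPDIs for lambda_S, lambda_G,
                         # gamma_S, gamma_G, gamma_D, mu_tauS, mu_tauP, rho
hpdi(indirect_effect(fit))  # delay -> joint success -> PAS pathway
```

Interpretation mirrors the design: `gamma_G` (joint success raising PAS) is
the dyadic-clarity effect, `gamma_S` the individual one, `lambda_G` and
`lambda_S` the benefits of sub-3-s synchrony for joint and individual
recognition, and `rho` the residual within-dyad PAS correlation.

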