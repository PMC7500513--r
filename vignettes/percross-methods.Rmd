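---
title: "Models and methods in percross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in percross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experiment and the data

In a perceptual-crossing session two players each control an avatar on an
invisible circle of 600 units via a trackball, receiving all-or-none
vibrotactile feedback whenever their own avatar (a 4-unit interval) overlaps
one of three objects: the partner's avatar, a "shadow" decoy rigidly
attached to the partner's avatar at a 150-unit offset, or a static lure.
Trials last 60 s. Each player may click once per trial to claim they found
the partner, and afterwards rates the clarity of the partner's perceived
presence on the 4-point Perceptual Awareness Scale (PAS): no experience,
ambiguous, almost clear, clear. A standard design runs 10 teams for 20
trials each; unbalanced designs (teams with fewer recorded trials) are
supported throughout.

`percross` represents a session as a trial roster, a table of click events
(with target label and PAS), an optional table of avatar trajectories at
native timestamps, and the world configuration. Everything round-trips
through plain CSV (one directory: `events.csv`, `trials.csv`, `world.json`,
optionally `trajectories.csv`) or a single JSON file whose schema ships in
`inst/schema/`. The roster is part of the format because trials without any
click carry no event row yet enter every denominator.

## World mechanics and conventions

Coordinates are continuous in `[0, 600)`; all objects are half-open
intervals `[x, x + 4)` anchored at their left edge, so touching edges do not
count as contact and a tiling of the circle is unambiguous. The shadow
offset is applied in the positive direction by default; the original
direction is not observable from event data, so the sign is configurable.
Distances between objects are measured anchor-to-anchor along the shorter
arc. The bundled simulator advances the world at a 0.01-s tick and a player
controller sees only its own sensor stream, exactly like a human
participant; real logs are never resampled, readers preserve native
timestamps.

## Click-target classification

The original studies assigned click targets automatically from distances at
the click time, then reviewed trajectory plots by hand. `percross`
implements the automatic stage as a deterministic rule and replaces the
manual stage by an ambiguity flag. The candidates for a player's click are
only the three objects that player can feel. A click is assigned to the
nearest candidate if its anchor distance is at most `max_assign_distance`
(default 8 units, two object lengths — the radius is not documented in the
source studies, so it is configurable and `classify_sensitivity()` tabulates
how every headline count reacts to it). Clicks whose two nearest candidates
differ by less than `ambiguity_margin` (default 2 units) are flagged for
human review; exact ties, a measure-zero event, resolve by the fixed
priority avatar > shadow > static. The partner position at the click time is
linearly interpolated on the torus along the shorter arc between the two
bracketing trajectory samples.

## Descriptive analyses

`trial_outcomes()` reduces each trial to: who clicked, whether each click
was correct (target = partner's avatar; shadow and static clicks are both
wrong), joint success (both clicked and both correct), the inter-click
interval (defined only when both clicked), and the dichotomized delay
indicator, 1 iff the interval is strictly below 3 s. The boundary is strict
because "within 3 s" concerns an open time scale and the boundary has
probability zero for continuous click times; the choice is inconsequential
and documented. Team scores award +1 per correct and -1 per wrong click.

Under the null that the two players click independently and uniformly over
a trial of length `T`, the inter-click delay `|X - Y|` has CDF
`1 - ((T - d)/T)^2`; at `d = 3`, `T = 60` this equals 0.0975. Observed
interval distributions are estimated by a Gaussian kernel density with
reflection at both support boundaries (so the estimate integrates to one on
`[0, T]`) and Silverman's rule bandwidth; both method and bandwidth are
arguments, since any smooth estimate of `P(interval < 3 s)` from a few
dozen observations carries appreciable smoothing error.

## The hierarchical Bayesian path model

Observation unit: a player-trial with a click, nested in players (m = 1, 2)
within teams (j). Three probit submodels are linked as a path model:

* **Individual success** `S`: `S ~ Bernoulli(Phi(a_i + b_i (min(t, tauS_i) - 1)
  + lambdaS D))`. Each individual has an intercept `a_i`, a non-negative
  learning slope `b_i`, and a breakpoint `tauS_i`: performance improves
  linearly over the learning stage and is constant in the consolidation
  stage. `D` is the trial's sub-3-s delay indicator.
* **Joint success** `G`: `G ~ Bernoulli(Phi(c_j + lambdaG D))` with team
  intercepts `c_j`. Although joint success is a deterministic function of
  the two individual outcomes, the path model treats it as its own
  endogenous variable with a delay effect; a configuration flag lets the
  generator produce `G` either way (see below).
* **PAS** `Y in {1..4}`: ordinal probit with latent mean
  `u_i + v_i (min(t, tauP_i) - 1) + gammaS S + gammaG G + gammaD D`,
  cutpoints `kappa1 < kappa2 < kappa3`, unit residual SD, and residual
  correlation `rho` between the two dyad members' latent variables in
  trials where both PAS responses are observed. A missing PAS (historically
  about 1% of clicks) contributes nothing to the likelihood
  (missing-at-random).

Identification of the ordinal submodel fixes the latent residual SD to 1
and the hyper-mean of the PAS intercepts `u_i` to 0, leaving three free
cutpoints. Learning slopes are constrained non-negative (the learning stage
allows improvement, by assumption) through truncated-normal hierarchies.
Breakpoints follow truncated-normal hierarchies on `[1, T]` whose
hyper-means `mu_tauS`, `mu_tauP` get Uniform(1, T) priors. Regression
effects and intercept hyper-means get Normal(0, 2.5^2) priors;
random-effect SDs half-Normal(1); breakpoint SDs half-Normal(5); `rho`
Uniform(-0.99, 0.99). All scales are latent-probit units; all priors are
overridable through `pc_priors()`.

Sampling is Gibbs/slice via JAGS with the ordinal outcomes handled by
thresholded latent (bivariate) normals. Chains start from neutral values
except the breakpoints, which start at trial 2 in odd chains and mid-range
in even chains: breakpoints are the slowest-mixing quantities, and
overdispersed starts make the split R-hat flag poor traversal instead of
hiding it. Convergence is a surfaced warning (R-hat > 1.01 or ESS < 400 on
any reported parameter), never a silent failure. `hpdi()` computes highest
posterior density intervals by the narrowest-window scan of the sorted
draws. The indirect delay effect on clarity is reported as the draw-wise
product `lambdaG * gammaG`; a category-scale contrast (expected PAS shift
when the joint-success probability moves from its D = 0 to its D = 1 value)
is available as an alternative.

The observed-data log-likelihood is also implemented directly
(`pc_log_likelihood()`), with dyad-correlated ordinal terms evaluated by
conditioning and adaptive quadrature; it exists so that the model's exact
probability content can be tested against independent closed forms and 2-D
quadrature, and it doubles as a check that the sampler and the written
model agree.

## Synthetic data: what it emulates and what it does not

The event-level generator (`generate_events()`) draws sessions exactly from
the generative process above. Its defaults are calibrated once to the
study-scale conditions: 10 teams by 20 trials of 60 s, an 80% click rate,
roughly 72% correct clicks, PAS marginals near 6/30/33/31 percent, and path
coefficients at the empirically relevant values (joint-success effect on
PAS 0.69, delay effects 1.01 on joint and 0.70 on individual success,
individual-success effect -0.16, delay effect on PAS 0.14, breakpoint means
3.2 and 5.1). Inter-click delays follow a mixture: with probability 0.2 the
two clicks are separated by an Exponential gap of mean 1.5 s
("synchronized" recognitions), otherwise both times are independent
Uniform(0, 60); this reproduces sub-3-s delay probabilities of the observed
order (around 0.25 under joint success against the 0.0975 uniform null).
The cutpoint defaults (-1.3, 0.3, 1.25) were fixed by matching the marginal
PAS table at the default effect sizes before any testing against them.

Joint success poses a representational choice: in the fitted path model `G`
has its own submodel, but in the event tables `G` is necessarily the
conjunction of two correct clicks. The generator therefore has two modes:
`"derived"` (default; `G` = both correct, consistent with everything
downstream of `events.csv`) and `"submodel"` (the exact generative
counterpart of the fitted model, used for parameter recovery, where a
ground-truth `lambda_g` exists by construction). This is also why the
parameter-recovery harness consumes the generator's in-memory observation
arrays rather than re-deriving them from the event files.

The behavioural generator (`generate_behavioral()`) runs the tick-level
simulator with search-and-dwell controllers (sweep until contact, dwell and
oscillate on contact, click under a constant hazard once contact is
sustained) and records ground-truth targets from the exact geometry at each
click. It emulates the kinematic texture of real trials well enough to
exercise interpolation and classification end to end, but it does not model
human strategy: no turn-taking, no deliberate shadow-testing, no
post-contact pursuit. Passing tests on synthetic data therefore validate
the pipeline's correctness, not any behavioural realism claim.

## Problem sizes and numerical choices

The test suite and the acceptance script size their computations to desk
scale as a design choice: parameter recovery runs 10 replicates of 40 teams
by 20 trials (about 1300 click observations each) with 2 chains of 1200
retained iterations after 900 warm-up/adaptation sweeps; the headline refit
in the acceptance script uses 2 chains of 2500 iterations on a 10-team
session. Breakpoint hyper-means are the weakest-identified quantities at
the default effect sizes (learning raises success probability by only about
0.1 over the first three trials), and their posteriors mix an order of
magnitude more slowly than the regression effects; the reported effective
sample sizes and R-hat flags make this visible in every summary. Degenerate
inputs are handled explicitly: datasets in which every click succeeds (or
fails) produce a prior-dominated fit with a warning; density estimation
refuses fewer than five intervals; HPDIs require at least 100 draws.

## Known limitations

* The converter for the original study's deposited spreadsheet is a stub:
  the artifact defines its own schemas, and the deposited file's exact
  layout must be mapped once inspected.
* The behavioural controllers are stress-test stand-ins, not cognitive
  models.
* With weakly informative priors and study-scale data, the breakpoint
  hyper-means are diffuse; their point estimates should be read together
  with their intervals and diagnostics.
* The path model treats joint success as its own outcome (following the
  source design); users who prefer the deterministic reading can fit with
  the derived `G` and ignore `lambda_g`.
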