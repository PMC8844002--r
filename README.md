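# shadepath

Hierarchical Bayesian modelling of pedestrian sun avoidance in path choice.

When people walk through a hot city they trade distance against sun
exposure: a longer route in the shade can *feel* shorter than a direct route
in the sun. shadepath estimates that trade-off from two-alternative
forced-choice (2AFC) route experiments. Each route option is described by
the metres walked in sun, under tree shade and under building shade
(`a_sun`, `a_tree`, `a_shade`), and a participant's perceived cost of an
option is

```
c = beta_j * [a_sun + (1 - rho) * a_tree] + a_shade + rho * a_tree
```

where `beta_j > 0` is the participant's distance-inflating sun coefficient
(`beta_j = 1.16` means sun-lit metres feel 16% longer) and `rho` in [0, 1]
is the perceived tree-shade intensity (1: trees shade like buildings, 0:
like no shade at all). Choices are logistic in the cost difference with a
per-choice-set temperature `tau_k`, and participants share a Gamma
population prior on `beta_j` through hyperparameters `d, e ~ Normal(0, 1)`
with `beta_j ~ Gamma(exp(d + e), exp(d - e))`.

The package provides, end to end:

* **Scene shading** — sun position from a NOAA-style ephemeris plus ray-grid
  casting over path strips against extruded building footprints and
  ellipsoidal tree crowns (`solar_position()`, `cast_fractions()`,
  `path_option_composition()`, GeoJSON scene I/O).
* **Choice model** — costs, choice probabilities, trial-strategy
  classification (sun-minimising / distance-minimising / optimal /
  non-optimal) and indifference arithmetic (`path_cost()`,
  `classify_trial()`, `sun_equivalent_distance()`).
* **Hierarchical inference** — a built-in No-U-Turn Hamiltonian Monte Carlo
  sampler (C++, analytic gradients) with rank-normalised split R-hat and
  bulk effective-sample-size diagnostics (`build_choice_model()`,
  `sample_posterior()`, `mcmc_diagnostics()`, `summarize_posterior()`).
* **Synthetic cohorts** — a generator reproducing the study's statistical
  structure so the whole pipeline is testable without field data
  (`sim_config()`, `simulate_study()`, `generate_scene()`).
* **Study I/O and reporting** — coded event logs, cross-coder agreement,
  treatment-decision flagging, eligibility filtering, and report tables
  (`parse_events()`, `apply_eligibility()`, `report_posterior()`,
  `report_strategies()`).

## Worked example

Simulate a study-sized cohort, fit it, and read off the headline
quantities:

```r
library(shadepath)

sim <- simulate_study(sim_config(), seed = 1)     # 46 participants x 13 trials
decisions <- sim$decisions[!sim$decisions$is_test, ]
fit <- sample_posterior(build_choice_model(decisions),
                        chains = 4, tune = 2000, draws = 10000, seed = 1)
summarize_posterior(fit)
```

```
<shadepath_summary> 95% credible intervals

Population-level quantities:
         quantity  mean lower upper p_gt_1
      beta_pooled 1.173 0.754 1.673  0.777
 beta_pooled_set1 1.186 0.766 1.694  0.788
 beta_pooled_set2 1.161 0.742 1.649  0.765
       beta_exp2e 1.176 1.069 1.298  0.999
              rho 0.536 0.185 0.873     NA
           tau[1] 0.226 0.167 0.305     NA
           tau[2] 0.242 0.177 0.330     NA

46 participant-level beta_j summaries in $participants; full parameter table in $parameters.
```

The generating truth here was a population-mean `beta` of 1.16,
`rho = 0.5` and `tau_k = 0.2`: the pooled `beta` posterior mean of 1.17
says sun-lit distance is perceived about 17% longer in this synthetic
cohort; `p_gt_1` is the posterior mass on sun aversion; `rho` near 0.5
means tree shade is felt as about half as relieving as building shade (its
interval is wide -- 46 participants x 12 choices is little information
about `rho`). A `beta` of 1.16 also means 100 m of full shade is perceived
as equal to 86 m of sun (`sun_equivalent_distance(100, 1.16)`), or 50 m of
shade plus 43 m of sun (`mixed_exposure_sun_component(100, 50, 1.16)`);
`indifference_table(c(1.16, 1.84))` tabulates these equivalences.

Sampler health for this fit (`mcmc_diagnostics(fit)`): minimum bulk ESS
5953 across all 51 parameters, maximum split R-hat 1.0008, no divergent
transitions.

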