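---
title: "Modelling pedestrian sun avoidance in path choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pedestrian sun avoidance in path choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

shadepath quantifies a specific behavioural question: when a pedestrian in a
hot climate chooses between two routes, how much extra walking distance are
they willing to accept to stay out of the sun, and how is tree shade weighed
against the deeper shade of buildings? The package implements the full chain
needed to answer it from a two-alternative forced-choice (2AFC) field
experiment: geometric computation of each route's sun--shade composition,
a parametric cost model of the choice, hierarchical Bayesian estimation, and
a synthetic-data generator that makes every stage testable without field
data.

## The choice model

Each route option is summarised by three metric lengths: `a_sun` walked in
direct sun, `a_tree` under tree crowns and `a_shade` under building shadow.
The perceived cost of an option for participant $j$ is

$$ c = \beta_j\,[a^{sun} + (1-\rho)\,a^{tree}] + a^{shade} + \rho\,a^{tree}, $$

with two behavioural parameters:

* $\beta_j > 0$, the **distance-inflating sun coefficient**: metres in the
  sun count $\beta_j$ times. $\beta_j = 1.16$ means sun-exposed walking
  feels 16% longer; equivalently, shaded distance is discounted by
  $1/\beta_j \approx 0.86$.
* $\rho \in [0,1]$, the **perceived tree-shade intensity**: a tree-shaded
  stretch is treated as a mixture of $\rho$ full shade and $1-\rho$ full
  sun. At $\rho = 1$ trees shade like buildings; at $\rho = 0$ they might as
  well not be there. A 50% intensity makes 100 m of tree shade equivalent
  to 50 m of sun plus 50 m of building shade.

At $\beta_j = 1$ the $\rho$ terms cancel and the cost is simply the route
length -- the model nests distance-minimising behaviour exactly.

A trial presents options A and B; the probability of taking A is logistic in
the cost difference $\Delta c = c^{(A)} - c^{(B)}$:

$$ p(\text{choose } A) = \frac{1}{1 + \exp(\Delta c / \tau_k)}, $$

where $\tau_k > 0$ is a per-choice-set temperature: the smaller it is, the
more deterministically the cheaper option wins. Lengths are multiplied by a
single scale factor (0.01, i.e. hectometres) before entering $\Delta c$;
because the cost is linear this is equivalent to scaling $\Delta c$ itself,
and the package applies it at model-building time
(`build_choice_model(length_scale = 0.01)`). The $\tau_k$ prior is only
sensible on that scale.

## Priors and hierarchy

Participants share a population: $\beta_j \sim \mathrm{Gamma}(e^{d+e},
e^{d-e})$ (shape/rate) with $d, e \sim \mathrm{Normal}(0,1)$, so the
population mean of $\beta_j$ is $e^{2e}$. This $(d,e)$ parameterisation
decorrelates the shape and rate and is used exactly as stated -- no centred
alternative is provided. The remaining priors are $\rho \sim
\mathrm{Beta}(1,1)$ (uniform) and $\tau_k \sim \mathrm{Gamma}(12.5, 50)$.
Note a quirk carried over deliberately: that Gamma prior has mean
$12.5/50 = 0.25$ under the shape/rate convention, although it is described
in the source study as targeting a mean of 0.2; shadepath implements the
printed prior. Under shape/*scale* the mean would be 625 -- absurd on the
hectometre scale -- which is why shape/rate is used throughout.

Two population-level readings of $\beta$ exist and are both reported by
`summarize_posterior()`: the pooled distribution of all participants'
$\beta_j$ draws (the headline number), and the posterior of $e^{2e}$, the
mean of the population Gamma. They are distinct estimands that agree
closely in practice; reporting both makes the choice explicit.

## Sampling and diagnostics

The posterior is sampled by a No-U-Turn sampler (dynamic Hamiltonian Monte
Carlo with slice termination) written for this model in C++, with analytic
gradients of the joint log density on the unconstrained scale
$(d, e, \log\beta_j, \mathrm{logit}\,\rho, \log\tau_k)$. Warmup uses
dual-averaging step-size adaptation (target acceptance 0.8) and Stan-style
expanding windows for a diagonal mass matrix; the defaults are 4 chains,
2000 warmup iterations and 10000 kept draws per chain. Chains run
sequentially from one seeded stream, so a fit is bit-reproducible given its
seed. Divergent transitions after warmup are counted and the fit is flagged
(with a warning) when they exceed 0.1% of draws; divergences are never
silently accepted. The test suite cross-checks this sampler against an
independent MCMC implementation of the same model in JAGS: posterior means
agree to a fraction of a posterior standard deviation.

Convergence is assessed with rank-normalised split $\hat R$ (maximum of the
bulk and folded variants) and bulk effective sample size via Geyer's initial
monotone sequence on rank-normalised split chains -- the now-standard
definitions. Degenerate inputs are handled explicitly: constant draws give
`NA` rather than a division blow-up, identical chain copies give
$\hat R \approx 1$, and a stuck chain inflates $\hat R$ through the rank
transform. At the default settings on a study-sized cohort (46 participants,
12 treatment decisions each) the minimum bulk ESS across all parameters is
several thousand and $\hat R \le 1.01$ for every parameter.

## Scene shading

When compositions are not tabulated they can be computed from a 2.5D scene:
building footprints extruded to their heights, tree crowns as axis-aligned
ellipsoids (the simplest parametric convex hull of a crown), and each path
option as one or more strip polygons. Wide (6 m) paths are represented by 5
strips of 1.2 m. For a given decision instant, the sun's azimuth and
elevation come from a NOAA-style ephemeris (accuracy well under 0.5° for
1950--2100; timezone-naive timestamps are rejected rather than guessed).
One ray is shot towards the sun from every 0.1 m lattice-cell centre inside
a strip; a ray through a building extrusion marks building shade, a ray
through a crown (and no building -- buildings block completely, crowns only
partially, so they take precedence) marks tree shade, the rest is sun. The
strip with the lowest sun fraction represents the option; building shade
under 15% of a wide path is re-counted as sun (too thin a sliver to walk
in, strictly "less than" 15%); fractions times the centreline length give
the metric composition. Grid-cell centres sit on an absolute lattice, so
identical inputs give bit-identical fractions, and the discretisation error
against the analytic single-wall shadow is bounded by
`2 * grid_step / strip_width`, which the tests verify over randomised
wall/sun configurations. Ties for the lowest sun fraction go to the lowest
strip index. Penumbra, diffuse radiation and radiant-temperature modelling
are out of scope.

## The synthetic cohort generator

`simulate_study()` emulates the statistical structure of the field study:
46 participants by default, 13 trials each of which one is a designated test
trial (a clearly dominated option, at least 1.5× longer and 2× sunnier --
choosing it excludes the participant), two choice sets split evenly across
participants, total option lengths in 40--250 m, 70% trade-off trials among
the non-test trials, $\beta_j$ drawn from the Gamma population with mean
1.16 and variance 0.04, $\rho = 0.5$, $\tau_k = 0.2$, and Bernoulli
outcomes from the logistic rule.

The *composition* of each option -- not dictated by the cohort shape -- is
designed for parameter identifiability, mirroring how the field choice sets
were laid out to maximise informative trade-offs:

* Tree-vs-building opposition. The shaded portion of an option is split
  between tree and building shade with a U-shaped Beta(0.15, 0.15) share,
  opposed between the two options of a trial (one tree-lined, one built-up).
  $\rho$ affects the cost difference only through
  $\Delta a^{tree}(1-\beta_j)$, so without strong tree-shade contrasts it is
  essentially unidentified.
* Cost balance. In trade-off trials the longer option's length is set so the
  two costs approximately tie at reference parameters
  ($\beta = $ population mean, $\rho = 0.5$), with jitter. Saturated
  choices (probability near 0 or 1) carry almost no information.
* Long, heavily shaded options and mild dominance margins, for the same
  reason.

At the recovery scale of 200 participants × 13 trials this design yields a
$\rho$ posterior standard deviation near 0.06, so posterior means of
$\rho$, $\tau_k$ and the population $\beta$ land within ±0.1 of the
generating truth in roughly nine out of ten seeded replicates -- the
calibration the test suite checks (5 replicates, one miss allowed). At the
study's own scale (46 × 12) the $\rho$ interval is wide; that is a finding
about the design, not a defect of the sampler.

What the generator does *not* emulate: order and fatigue effects (the model
assumes independent decisions), weather-driven sun-state changes within a
session (all synthetic decisions default to `full_sun`), covariates such as
gender or temperature, and any correlation between a participant's
$\beta_j$ and their trial compositions. Passing tests on synthetic data
therefore validate the pipeline's internal consistency, not these
assumptions about real pedestrians.

## Study-shaped data handling

`parse_events()` reads the coded video-event schema (decision, end-of-trial,
sun-presence, sun-exposure, water-intake events; ISO-8601 timestamps with
explicit offsets at 1 s resolution); malformed rows are set aside into an
error report, never silently dropped. `coder_agreement()` flags pairs of
cross-coded events that differ in decision label, sun-presence state, or
start/end time by strictly more than 5 s. `flag_treatment_decisions()`
attaches to each decision the most recent prior sun-presence state;
decisions under `full_sun` or `cloudy_sun` (both cast usable shadows; the
set is configurable) are treatment decisions -- the only ones informative
about sun avoidance. `apply_eligibility()` removes ineligible participants
and the test trial, marks test-trial failures, and keeps zero-treatment
participants in the accounting but out of the fit. Which trial is the test
trial is study configuration, deliberately not a constant.

## Numerical choices and degenerate inputs

* Choice probabilities are evaluated on the log-odds scale; extreme
  $\Delta c/\tau$ saturates at 0/1 without overflow.
* Strict inequalities define trade-off trials; ties on both axes are
  `indifferent`, a tie on one axis falls to dominance.
* Reported indifference equivalences round to whole metres; internal
  computation is unrounded (`round_m = FALSE` exposes it).
* A strip too small to contain any lattice point is an error naming the
  strip, as is a sun at or below the horizon.
* Fits with a single chain refuse to compute $\hat R$.

## Limitations

The real-data refit depends on the study's deposited decisions table, which
is not redistributed here; `refit_deposited_study()` implements the
pipeline against a local copy with a schema-mapping hook, since the
deposit's exact column layout is not fixed by the package. Computed tree
shade uses idealised ellipsoidal crowns, so compositions for real sites will
deviate from any rendered-scene ground truth. The model deliberately
excludes covariates, sequential effects and alternative link functions.
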