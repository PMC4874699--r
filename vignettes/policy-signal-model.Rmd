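---
title: "A state-space model for policy signals in wolf population growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A state-space model for policy signals in wolf population growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolfpolicy)
library(dplyr)
```

## The scientific question

Wildlife agencies sometimes liberalize the culling of protected carnivores on
the theory that giving residents legal recourse will reduce poaching. This
package implements a hierarchical Bayesian analysis designed to test that
theory on recovering grey wolf populations monitored by annual counts in two
neighbouring states. The key idea is to separate a policy **signal** — the
proportion `D` of each wolf-year during which culling was legally allowed —
from its **implementation** — the number `H` of wolves actually culled, which
is fully reported and enters the model as known removals. If growth slows
when culling is merely *allowed*, over and above the wolves actually removed,
the residual explanation (after ruling out density dependence and
super-additive mortality) is a change in unobserved illegal killing.

## The model

Time is measured in wolf-years: year `t` runs from 15 April of `t - 1`
through 14 April of `t`, inclusive, with exact calendar day counts (leap
years have 366 days). The `policy_timeline` functions clip dated authority
periods to wolf-years and count days inclusively, so a period spanning a full
wolf-year gives exactly `D = 1` and disjoint sub-periods add without double
counting.

For each state `s` the latent population follows

* growth: `r[s,t] = beta0[s] + beta1 * D[s,t]` — `beta0` is state-specific,
  the signal effect `beta1` is shared between states (the analysis reports a
  single posterior for the signal effect while allowing the two recoveries
  different baseline rates);
* projection: `N_det = max(N[s,t-1] * exp(r) - gamma * H[s,t], 1e-3)`, where
  `gamma` measures additivity of culling mortality (1 = additive, < 1
  compensatory, > 1 super-additive);
* process noise: `N[s,t] ~ Lognormal(log N_det, sigma_proc)`.

Counts are observed through a Poisson–Gamma (negative binomial) layer:
a minimum count has mean `theta_min * N` with `theta_min` uniform on [0, 1]
(minimum counts undercount), and the first state's maximum counts have mean
`theta_max * N` with `theta_max` uniform on [1, 10]. The Gamma mixing sd
`sigma_obs` gives marginal variance `mean + sigma_obs^2`. Years without a
census contribute no observation term but stay in the latent chain.

Culling is placed *after* growth (`N_prev * exp(r) - gamma * H`): the growth
rate is then a *potential* growth rate excluding the culled wolves, which is
the quantity the derived summaries report. The alternative ordering
`(N_prev - gamma * H) * exp(r)` can be explored by pre-transforming the
removals column; we kept a single canonical ordering in the likelihood to
keep the reported `r` interpretable.

### Priors

All hyperparameters live in a single editable list ([default_priors()]) and
can be loaded from YAML; nothing is hard-coded downstream. Defaults:
diffuse `Normal(0, 10^2)` on the growth coefficients; `Half-Normal(1)` on the
log-scale process sd and `Half-Normal(50)` on the count-scale observation
sds; uniforms on the count factors' natural ranges; and an informative
`Normal(1, 0.25^2)` truncated to positive values on `gamma`, centred on the
additivity reported for North American wolf populations. The original
analysis's exact prior table is not available in the source text we worked
from, so these are reconstructions stated in the same families; they are
deliberately weak except for `gamma`, whose informativeness is the
documented scientific choice. The initial latent population of each state is
lognormal, centred on the first observed minimum count divided by the prior
mean (0.5) of `theta_min`, with log-sd 1 — the data quickly dominate this
choice.

## Sampling

`fit_state_space()` runs a self-contained blocked adaptive random-walk
Metropolis sampler (compiled core): scalar blocks for each hyperparameter
(log-scale proposals for positive parameters, logit-scale for the bounded
count factors), single-site log-scale updates for every latent population,
and one joint "scale ridge" block that moves all latent populations up while
moving both count factors down — the direction along which the likelihood is
nearly flat — which substantially improves mixing of `theta_min` and
`theta_max`. Proposal scales adapt by Robbins–Monro towards 30% acceptance
(inside the conventional 20–40% band) and are frozen after the adaptation
phase so the retained draws target the posterior exactly.

The default settings reproduce the study protocol: 8 chains, 100 000
iterations thinned by 10 after 50 000 adaptation/update iterations.
Simulation studies use the first-class `"test"` preset (4 chains x 5 000
iterations, thin 5) and the auxiliary submodels the `"short"` preset
(2 chains x 3 000); these desk-scale sizes are the package's chosen
trade-off between replication count and per-fit precision in its own
calibration studies, and the coverage checks in the test suite are run at
exactly these sizes. Everything is deterministic given the seed.

Initialization is data-driven rather than prior-driven: latent populations
start at observed counts scaled by a drawn count factor (log-interpolated
across missing years), intercepts at mean log count ratios, with per-chain
jitter and bounded re-tries on a non-finite posterior. Drawing
initializations from the diffuse priors themselves would start chains
absurdly far from the data and waste the adaptation budget.

## Convergence diagnostics

`gelman_rubin()` implements the classic potential scale reduction factor
`sqrt(((n-1)/n W + B/n)/W)` without the later sampling-variability
correction (available via `correct = TRUE`). `heidelberger_welch()`
implements the stationarity test (Cramér–von Mises statistic of the
standardized cumulative-sum process, long-run variance from an AIC-selected
autoregressive fit, initial 10% increments discarded up to 50%) and the
relative halfwidth test; a zero mean makes the halfwidth criterion not
applicable rather than a failure. `convergence_gate()` requires PSRF < 1.1
(conventional; no numeric threshold is prescribed by the protocol) and
per-chain stationarity for every parameter; reporting functions refuse — or
stamp their output `NOT CONVERGED` — when the gate fails.

## Density-dependence side-models

Slowing growth in a growing population could simply be negative density
dependence, so three auxiliary Bayesian submodels relate demographic rates
to population size: mean pack size (latent Poisson size, Gamma observation
with ±1-wolf error), the probability a pack reproduces (Bernoulli with
logit-linear dependence), and total occupied area (normal linear model).
The latent integer pack size is summed out in closed form rather than
sampled, which is exact to numerical truncation and much faster. The
population-size covariate defaults to the first state's observed minimum
counts (a fixed covariate); fitting the side-models jointly with the
state-space model would entangle weakly identified scales at this data
size. A single reproduction intercept is fitted by default, with a
`year_intercepts` switch, since year-specific coefficients are not
identifiable from one or two reproduction records per year in small years.
`density_dependence_report()` declares negative density dependence only
when `P(slope < 0) > 0.95`.

## The synthetic-data generator

`simulation_config()` defaults encode the study conditions: two states, 18
wolf-years, baseline growth 0.16 and 0.14, signal effect -0.04, additive
culling, initial populations 75 and 60 (which put the first state's final
population at the observed few-hundred-to-two-thousand scale), process sd
0.05, count factors 0.9 and 1.1 with observation sds of 10 wolves, a
synthetic 12-period policy timeline starting spring 2003, and removals drawn
as `H ~ Poisson(0.05 * N_grown * D)` — culling only while allowed, at the
tens-of-wolves scale. The final census of the second state is blanked in
`default_paperlike_config()` to mirror the one missing count in the study
data. Degenerate limits are honoured exactly: with zero process and
observation noise the generated counts equal the deterministic exponential
skeleton, which anchors the deterministic-limit test. Because real census
bounds are jointly reported, the generator orders the minimum/maximum draws
within a state-year (`pmin`/`pmax`); at realistic population sizes the two
layers barely overlap, so this coherence step is almost always a no-op, but
it guarantees generated tables satisfy the input-validation invariants.

What the generator does *not* emulate: spatially explicit pack structure,
immigration between states, observer effort trends, or any feedback from
population size onto the policy process. Passing parameter-recovery and
calibration tests on these synthetic data therefore demonstrates internal
correctness of the model-sampler-reporting chain under the stated generative
assumptions — not that the real count series satisfies those assumptions.

## Numerical choices

* Over-culling floors the deterministic projection at `1e-3` wolves so the
  lognormal location stays defined; realistic trajectories never approach it.
* The Poisson–Gamma marginal is evaluated as the corresponding negative
  binomial mass (`size = m^2/sigma^2`, `mu = m`), exact and stable, and
  reduces to the Poisson as `sigma_obs -> 0`.
* Parameters outside prior support yield `-Inf` from the joint log-posterior
  (sampler rejection), never an exception; invalid *inputs* (e.g. a
  non-positive observation sd) are errors.
* The compiled log-posterior and the R reference implementation are tested
  to agree to 1e-10; the brute-force term-by-term oracle in the test suite
  uses independently written density formulas.
* Ties/zero cases: a zero posterior mean makes the halfwidth test `NA`;
  `P(beta1 > 0) = 0` reports the probability ratio as `">max"`.
* Operating-characteristic tests of the stationarity diagnostic use chains
  of length 2000: the long-run variance estimator partially absorbs a linear
  trend, and shorter chains lose rejection power against it — a property of
  the test itself, not of this implementation.

## Limitations

The signal covariate is an annual aggregate; sub-annual dynamics are out of
scope. Poaching is never estimated directly — the analysis quantifies how
growth responds to the legal-status signal and rules out alternatives, and
inference beyond that is narrative. With only ~18 years x 2 states the
count-factor scales (`theta_min`, `theta_max`) are weakly identified; their
posteriors lean on the uniform supports, which is faithful to the original
design but means latent population *levels* carry more uncertainty than
growth *rates*.

## A worked example

```{r example, eval = FALSE}
cfg <- default_paperlike_config()
ds <- simulate_dataset(cfg, seed = 42)
fit <- fit_state_space(ds$state_year, settings = sampler_settings("test", seed = 1))
tidy(fit)
derived_growth_summary(fit, check_convergence = FALSE)
autoplot(fit)
```

The README shows the printed output of this example; `run_pipeline()` wraps
the same steps (plus validation, the density-dependence fits and report
files) behind one call.
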