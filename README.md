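# wolfpolicy

Bayesian state-space analysis of how a *culling-policy signal* affects the
growth of recovering grey wolf populations observed through imperfect annual
counts.

## The problem

Two neighbouring US states monitored their recolonizing wolf populations
with annual minimum counts (plus maximum counts in one state) over ~18
wolf-years, while federal court decisions repeatedly switched state culling
authority on and off — a replicated quasi-experiment. The question: does
merely *allowing* culling change population growth, over and above the
wolves actually removed? A slowdown tied to the legal-status signal rather
than to the removals, with density dependence and super-additive mortality
ruled out, points to a change in unobserved poaching.

The package is for quantitative ecologists who want to fit this model to
their own count series, or to study its behaviour on synthetic data with
known truth.

## The model

For state *s* and wolf-year *t* (15 April to 14 April, inclusive):

- growth: `r[s,t] = beta0[s] + beta1 * D[s,t]`, where `D` is the proportion
  of the wolf-year during which culling was legally allowed;
- latent dynamics: `N[s,t] ~ Lognormal( log( max(N[s,t-1] e^r - gamma * H[s,t], eps) ), sigma_proc )`,
  with `H` the reported removals and `gamma` their additivity multiplier
  (1 = additive, < 1 compensatory, > 1 super-additive);
- observation: counts are Poisson with Gamma-mixed means `theta_min * N`
  (minimum counts, `theta_min` in [0,1]) and `theta_max * N` (maximum
  counts, `theta_max` in [1,10]) — marginally negative binomial with
  variance `mean + sigma_obs^2`.

`beta1` is the policy-signal effect: the change in potential growth rate
(excluding culled wolves) caused by a year-long culling authorization,
shared between states. Three auxiliary submodels (mean pack size, pack
reproduction probability, occupied area vs population size) check for
negative density dependence as an alternative explanation.

Inference is by a self-contained blocked adaptive random-walk Metropolis
sampler (compiled core) whose default protocol is 8 chains of 100 000
iterations thinned by 10 after 50 000 adaptation iterations, with
Gelman–Rubin and Heidelberger–Welch convergence gates.

## Worked example

```r
library(wolfpolicy)

cfg <- default_paperlike_config()          # study-condition generator
ds  <- simulate_dataset(cfg, seed = 42)    # counts, culling, policy, packs, area
fit <- fit_state_space(ds$state_year, settings = sampler_settings("test", seed = 1))
tidy(fit)
#> # A tibble: 9 × 6
#>   term          estimate std.error conf.low conf.high    ess
#>   <chr>            <dbl>     <dbl>    <dbl>     <dbl>  <dbl>
#> 1 beta0[MI]       0.154     0.0232   0.111     0.203   501.
#> 2 beta0[WI]       0.212     0.0199   0.173     0.252  1008.
#> 3 beta1          -0.102     0.0448  -0.191    -0.0159  589.
#> 4 gamma           0.999     0.250    0.505     1.49   1986.
#> 5 sigma_proc      0.0609    0.0206   0.0252    0.105   240.
#> 6 theta_min       0.910     0.0547   0.817     0.996    58.6
#> 7 theta_max       1.11      0.0680   1.00      1.23     57.1
#> 8 sigma_obs_min  12.3       5.61     1.54     23.8     436.
#> 9 sigma_obs_max   7.80      6.07     0.321    22.3    1667.

derived_growth_summary(fit, check_convergence = FALSE)
#> Potential growth rate by policy signal (posterior mean +/- sd [95% CI]):
#>   MI, D = 0: r = 0.154 +/- 0.023 [0.111, 0.203]
#>   MI, D = 1: r = 0.053 +/- 0.036 [-0.021, 0.123]
#>   WI, D = 0: r = 0.212 +/- 0.020 [0.173, 0.252]
#>   WI, D = 1: r = 0.110 +/- 0.037 [0.033, 0.181]
#> P(beta1 < 0) = 0.989; P(beta1 > 0) = 0.011; decline/increase ratio = 85.96
```

Read: with no signal this synthetic dataset's populations grow at ~15–21%
per year; a year-long culling authorization lowers the growth rate by the
posterior `beta1` (here −0.10; the generator's truth was −0.04 and its 95%
CI covers it), and a growth decline is ~86 times more likely than an
increase. `autoplot(fit)` draws the fitted latent trajectories with their
95% credible band over the observed counts; `plot_signal_effect(fit)` draws
the posterior of `beta1` with the negative region shaded. `run_pipeline()`
chains validation, the signal-covariate computation, the state-space and
density-dependence fits, diagnostics and report files behind one call, and
`inst/scripts/wolfpolicy-cli.R` wraps it for the shell.

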