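# pcmcalib

Simulation tools for studying **calibration** of patient-reported outcome
(PRO) instruments analysed in the Rasch measurement framework, in the
context of two-arm randomized clinical trials.

## The problem

PRO endpoints are questionnaire scores measuring latent constructs (pain,
fatigue, disability, ...). When the instrument has been developed with
Rasch measurement theory, the analysis model for `J` polytomous items with
`M` ordered response categories (coded `0..M-1`) is the partial credit
model (PCM): the probability that patient `i` answers category `k` on item
`j` is

    P(X_ij = k | θ_i, δ_j) ∝ exp( k·θ_i − Σ_{l≤k} δ_jl )

with latent trait `θ_i` and item category thresholds `δ_jl` on a common
logit scale. *Calibration* fixes the `δ_jl` at values estimated from a
previous reference sample, so that trial measurements are expressed in the
same unit as every other application of the instrument (traceability). The
alternative — re-estimating the item parameters on the trial data itself —
might adapt better to the trial population but breaks comparability.

This package implements the machinery to quantify, by Monte-Carlo
simulation, what calibration costs in operating-characteristic terms. A
random-effect PCM with a treatment covariate decomposes the latent trait as

    θ_i = μ0 + γ·g_i + θres_i,   θres_i ~ N(0, σ²)

with `g_i` the arm indicator, so `γ` is the treatment effect on the latent
scale (a standardized mean difference when σ² = 1). Two comparison methods
are covered:

* **Wald test** on `γ̂` from the marginal-maximum-likelihood (MML) fit of
  the group-covariate model;
* **t-test** on expected a posteriori (EAP) person estimates from a
  no-covariate fit.

Each is run both **calibrated** (thresholds anchored at values fitted on a
separate calibration sample) and **non-calibrated** (thresholds free on the
trial data), and the study runner tabulates type-I error, power, position
bias and the SD of the estimated treatment effect over replications.

## Worked example

```r
library(pcmcalib)

# a "Rasch-built" archetype bank: item locations spread over the continuum
bank <- make_archetype_bank(J = 4, M = 3, archetype = 2)
bank
#> Partial credit model item bank: 4 items, 3 categories (0..2)
#>       location delta_1 delta_2
#> item1  -1.0000 -1.6461 -0.3539
#> item2  -0.3333 -0.9794  0.3128
#> item3   0.3333 -0.3128  0.9794
#> item4   1.0000  0.3539  1.6461

# calibration study: 250 patients, latent trait N(0, 1)
set.seed(2026)
calibration <- simulate_responses(
  bank, draw_latent(population_spec(mean = 0, variance = 1, n = 250)))
cal_fit <- fit_random_pcm(calibration, fix_latent_mean = TRUE)
cal_fit
#> Random-effect PCM fit (free items): 250 subjects, 4 x 3
#>   mu0 = 0.0000  sigma2 = 1.1144  loglik = -960.71  converged: TRUE

# trial: 200 patients per arm, true effect gamma = 0.2
trial <- simulate_trial(bank, trial_spec(200, mu0 = 0, gamma = 0.2))

# calibrated analysis 1: anchored MML fit, Wald test on gamma
anchored <- fit_random_pcm(trial, include_group = TRUE,
                           fixed_items = as_item_bank(cal_fit))
wald_group_test(anchored)
#> wald_gamma: effect = 0.1626, statistic = 1.1983, p = 0.2308

# calibrated analysis 2: EAP scores from a no-covariate fit, then a t-test
scoring_fit <- fit_random_pcm(trial, fixed_items = as_item_bank(cal_fit))
eap <- eap_latent(trial, scoring_fit)
ttest_eap(eap, trial$group)
#> ttest_eap: effect = 0.1009, statistic = 1.1951 (df = 398), p = 0.2328
```

The Wald pathway estimates the treatment effect without systematic bias
(here `γ̂ = 0.16` against a true 0.2, within one SE), while the EAP
pathway's common-prior shrinkage attenuates the observed group difference
(`0.10`) — on a short 4-item instrument by roughly 40% — yet its smaller
replication-to-replication variability leaves the two tests with nearly the
same power. These single-trial numbers become systematic once replicated;
`run_scenario()` / `run_grid()` do exactly that:

```r
sc <- scenario_spec(J = 4, M = 3, n_trial = 200, gamma = 0.2,
                    n_replications = 200, seed = 1)
crit <- compute_criteria(run_scenario(sc), gamma_true = 0.2)
```

A YAML-driven grid runner and a command-line front end
(`inst/cli/pcmcalib.R` with `simulate`, `fit` and `run-study` subcommands)
cover full study grids; see `inst/extdata/example_study.yaml`.

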