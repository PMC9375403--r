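---
title: "Calibrated and non-calibrated PCM analyses of PRO trial endpoints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated and non-calibrated PCM analyses of PRO trial endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmcalib)
```

## Why this package exists

When a patient-reported outcome (PRO) instrument has been developed under
Rasch measurement theory, trial analysts face a choice. They can *calibrate*
— fix the item parameters at values estimated from a reference sample, so
every application of the instrument measures in the same unit — or they can
re-estimate the item parameters on the trial data itself, which adapts the
scale to the trial population at the price of comparability. `pcmcalib`
provides the full simulation loop needed to compare the two strategies on
equal footing: data generation from a partial credit model, marginal
maximum likelihood estimation with and without anchored items, two
treatment-comparison methods, and the Monte-Carlo bookkeeping (type-I
error, power, position bias, dispersion of the effect estimate).

## The measurement model

For `J` items with `M` ordered categories (coded `0..M-1`), the partial
credit model (PCM) gives

$$P(X_{ij} = k \mid \theta_i, \boldsymbol\delta_j) =
\frac{\exp\!\big(k\theta_i - \sum_{l\le k}\delta_{jl}\big)}
     {\sum_{r=0}^{M-1}\exp\!\big(r\theta_i - \sum_{l\le r}\delta_{jl}\big)},$$

where $\theta_i$ is the latent trait and $\delta_{jl}$ the threshold at
which categories $l-1$ and $l$ are equally likely; the empty sum for
$k = 0$ is zero. The item location $\delta_j$ is the mean of the item's
thresholds. All probability evaluations run in log space with
max-subtraction, so $|\theta|$ up to 50 poses no overflow problem.

In the trial analysis model the latent trait is decomposed as
$\theta_i = \mu_0 + \gamma g_i + \theta^{res}_i$ with arm indicator
$g_i \in \{0, 1\}$ and $\theta^{res}_i \sim N(0, \sigma^2)$, so $\mu_0$ is
the placebo-arm latent mean and $\gamma$ the treatment effect — a
standardized mean difference when the within-arm variance is 1, as in all
simulated conditions.

## Archetype item banks

`make_archetype_bank()` builds the two instrument archetypes used
throughout:

* **Archetype 1** ("parallel items", typical of classical-test-theory
  development): item locations packed between −0.25 and 0.25, thresholds
  spread widely around each location (normal-percentile offsets, SD 2.5).
* **Archetype 2** ("item hierarchy", typical of Rasch-built instruments):
  locations regularly spaced between −1 and 1, tight thresholds
  (SD 1.5).

Threshold offsets sit at the exact 1/3, 2/3 (or 0.2 … 0.8) normal
quantiles. We use exact thirds rather than the 0.33/0.66 rounding for
consistency with the exact fifths; the difference is below 0.01 latent
units and the literal variant remains available via
`percentiles = "literal"`. After construction all thresholds are shifted by
a common constant so their grand mean is zero, anchoring the scale origin
at the calibration population mean; with the exact percentile offsets this
shift is exactly zero by symmetry, so the default banks equal their
uncentered form.

## What the generator emulates — and what it does not

`simulate_trial()` draws equal-sized arms with
$\theta \sim N(\mu_0, 1)$ and $N(\mu_0 + \gamma, 1)$ and generates
responses item-wise from the PCM; `draw_latent()` covers calibration
samples ($N(0, 1)$ or $N(0, 2)$). The simulated world is deliberately
ideal: responses follow the PCM exactly, latent traits are normal, there
are no missing responses, no differential item functioning, and arms are
exactly balanced. Passing operating-characteristic tests therefore
demonstrates properties of the *methods* under a correctly specified
model, not robustness to the misfit, skewness or missingness of real PRO
data. Mistargeting is emulated solely through the trial latent mean
$\mu$ (up to 2 logits above the instrument center), which is enough to
reproduce ceiling effects on short instruments.

## Estimation

`fit_random_pcm()` maximizes the marginal likelihood: each subject's
conditional response probability is integrated over the normal latent
distribution by Gauss-Hermite quadrature. The compiled core returns the
analytic score (posterior-expected complete-data score) alongside the
log-likelihood, and optimization uses `optim(method = "L-BFGS-B")`.
Standard errors come from the observed information matrix, obtained by
central finite differences of the analytic gradient at the maximum. No
claim of algorithmic equivalence with any particular software is made —
only of estimand equivalence: the same marginal likelihood is maximized.

**Identification.** Exactly one location constraint is active in each
configuration:

* calibration fits fix the latent mean at zero and leave all thresholds
  free (matching the calibration population convention);
* free-item trial fits constrain the grand threshold mean to zero and
  estimate $\mu_0$. Internally the optimizer absorbs the location into the
  thresholds and the constraint is applied afterwards by the PCM's exact
  location invariance (shifting $\theta$ and all $\delta_{jl}$ by the same
  constant leaves every probability unchanged), which avoids constrained
  optimization entirely;
* anchored fits estimate $\mu_0$ freely — the anchor carries the origin.

**Quadrature.** The rule is fixed (non-adaptive; adaptive quadrature is
out of scope). Fixed rules concentrate nodes near the prior mean, while a
subject scoring at the instrument ceiling has a posterior several logits
away; accuracy there is bought only with node count. Measured per-subject
log-likelihood errors against a 2001-point trapezoid oracle: at 21 nodes,
about $2\times10^{-6}$ for a 4-item/3-category instrument but up to
$3\times10^{-2}$ for 10 items with 5 categories under mistargeting; 101
nodes reach $10^{-7}$ for all variance-1 conditions; 201 nodes keep every
condition of the design grid (including calibration variance 2) below
$10^{-6}$. The package default is therefore **201 nodes**. The cost is
linear in the node count and immaterial next to the replication loop.

**Degenerate inputs.** Thresholds are box-bounded at ±15 so fits remain
finite when a category is never observed (possible under heavy
mistargeting); such fits are flagged (`unobserved_category`, `bound_hit`)
rather than rejected, and non-converged optimizer exits are flagged and
never silently reported as converged. Starting values are thresholds at
the anchor or zero, $\mu_0 = \gamma = 0$, $\sigma^2 = 1$.

## Person estimates and the choice of EAP prior

`eap_latent()` computes posterior means by quadrature. The default prior is
the fitted marginal latent distribution from the *no-covariate* fit — one
common prior for all subjects, as when scoring precedes (and is blind to)
the group comparison. This choice matters: a common prior shrinks every
estimate toward the overall mean, so the between-arm difference in mean EAP
is attenuated, most strongly for short instruments — the source of the
negative position bias of the t-test pathway (about −0.08 at
$J = 4, M = 3$, shrinking to −0.02 at $J = 10, M = 5$). A group-conditional
prior (`by_group = TRUE`) removes most of that attenuation and is provided
for comparison, but is not the default because it answers a different
question.

## Group comparison

`wald_group_test()` refers $\hat\gamma/\mathrm{SE}(\hat\gamma)$ to the
standard normal (the conventional reference for MML estimates; the
simulation design does not distinguish it from a $t$ reference at the
sample sizes involved). `ttest_eap()` performs a pooled-variance Student
t-test — arms are equal-sized by design — with Welch available behind a
flag. $\alpha$ is 0.05 two-sided throughout.

## The study runner

`run_replication()` executes one replication: simulate calibration and
trial samples, fit the calibration model, then produce four cells
(calibrated/non-calibrated × Wald/t-test). Seeding is hierarchical: a
scenario-level stream yields one seed per replication, which yields
separate sub-seeds for the calibration and trial draws — so any
replication can be recomputed in isolation, execution order is irrelevant,
and concurrent execution would give byte-identical results.
`compute_criteria()` summarizes converged replications (rejection rate,
signed bias with its absolute value — sign conventions for "position bias"
differ between reports — and the SD of the effect estimate), always
printing `n_used`/`n_flagged` so exclusions are auditable. True latent
traits are carried in the datasets for diagnostics but are never visible to
the estimation path.

`run_grid()` crosses scenario parameters (a YAML config or
`default_grid()`, which reproduces the headline 36-scenario design:
J ∈ {4, 7, 10} × M ∈ {3, 5} × 200/500 per arm × μ ∈ {0, 0.5, 2}, archetype
2, calibration 250/variance 1, γ = 0.2 with a γ = 0 companion run for
type-I error).

## Problem sizes and what the tests compute

The test suite validates the quadrature against slow grid-integration
oracles, every closed-form example against independent hand computations,
and the Monte-Carlo operating characteristics at 200 replications per
scenario for six design cells (short/long instrument, 200/500 per arm,
with and without mistargeting) — enough for rate standard errors of about
1.5–3.5 percentage points, with tolerances set accordingly. The
`scripts/acceptance.R` entry point re-runs those six cells from scratch and
writes the resulting rates, bias and SD as JSON. Full 500-replication grids
are a configuration change (`n_replications = 500`), not a code change.

## Known limitations

* Cross-sectional, equal-allocation, complete-response trials only;
  no longitudinal designs, no missing data, no DIF.
* Only marginal (random-effect) estimation: no conditional or pairwise
  conditional maximum likelihood, no MCMC, no weighted-likelihood person
  estimates.
* The fixed quadrature rule buys tail accuracy with node count; users
  fitting instruments much longer than 10 items, or latent variances well
  above 2, should increase `n_nodes` (and can verify stability by
  doubling it, as the tests do).
* Simulated item banks always have ordered thresholds; disordered
  thresholds, common in poorly functioning real instruments, are not a
  simulated condition.
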