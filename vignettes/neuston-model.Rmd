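---
title: "Modelling neuston and plastic densities from dual-observer net tows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neuston and plastic densities from dual-observer net tows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuston)
```

## The problem

Subtropical gyres concentrate floating material — both obligate neuston
(*Velella*, *Porpita*, *Janthina*, *Glaucus*, *Physalia*) and plastic — in
accumulation zones such as the North Pacific "Garbage Patch".  Surveys of
these regions produce awkward data: a handful of net tows (tens, not
hundreds), sites chosen deliberately along routes of predicted high debris
concentration rather than at random, counts instead of densities with many
zeros for rare taxa, and a photographic counting protocol in which two
observers independently count the same image, so that neither count is the
true number of objects in the sample.

This package implements a joint hierarchical Bayesian treatment of all of
these features, together with the simulation, checking and sensitivity
machinery needed to trust the output at such small sample sizes.

## The observation model

Each tow sweeps an area $A_i$ (km²).  For category $j$ at site $i$ the
number of potentially visible objects is latent,
$$N_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
  \lambda_{ij} = A_i \exp(\eta_{ij}),$$
and each observer's count is an independent binomial thinning of $N_{ij}$
with a per-category detection probability $p_j$ shared by the two
observers.  Marginalising $N_{ij}$ gives the bivariate compound Poisson
law: with $Y_1 = U_1 + W$, $Y_2 = U_2 + W$,
$$U_1, U_2 \sim \mathrm{Poisson}\{\lambda p (1-p)\}, \quad
  W \sim \mathrm{Poisson}(\lambda p^2),$$
all independent.  Its marginals are $\mathrm{Poisson}(\lambda p)$, the
covariance of the pair is $\lambda p^2$, and the inter-observer correlation
equals $p$ — which is what makes $p$ estimable from double counts at all.
`dual_count_logpmf()` evaluates the exact log pmf by the finite sum over
the shared component; `dual_count_pmf_oracle()` keeps the brute-force
truncated latent sum as an independent cross-check (they agree to $10^{-10}$
relative error on a $\lambda \times p \times y$ grid in the test suite).
Detection is confounded with absolute density — only $\lambda p$ is well
identified — so the package's headline statistics are deliberately
functionals that do not involve the intercepts or $p$.

## The hierarchical regression

Log density of potentially visible objects is a multivariate linear
function of the dimensionless tracer concentration $c_i$ from a
surface-drift accumulation model (treated as known, because sites were
chosen on its basis) and a-priori patch membership $z_i$:
$$\eta_{ij} = \beta_{0j} + \beta_{1j} x_i + \beta_{2j} z_i
  + \beta_{3j} x_i z_i + \varepsilon_{ij}, \qquad x_i = \ln c_i,$$
with observation-level random effects
$\varepsilon_i \sim \mathrm{MVN}(0, \Sigma)$,
$\Sigma = \mathrm{diag}(\tau)\,\Omega\,\mathrm{diag}(\tau)$.  The $J \times
J$ correlation matrix $\Omega$ carries the residual associations between
categories' log densities — including the neuston–plastic association of
interest — conditional on the covariates.  The single-count variant
(`fit_single_count()`, `fit_three_region()`) replaces the pair of counts by
one Poisson count without a detection stage and the patch indicator by
$K - 1$ region dummies plus their log-tracer interactions; with $K = 2$ its
design matrix reduces exactly to the patch design.

### Priors

Defaults (all overridable per category through `default_priors()`):

* slopes, patch effects and interactions: normal(0, 2) — on the log scale
  a two-standard-deviation effect is a factor of $e^4 \approx 55$ in
  density, comfortably wider than any plausible gradient;
* intercepts: normal(0, 10).  With swept areas of order $10^{-3}$ km² and
  observed densities spanning roughly $10^2$–$10^5$ km⁻², intercepts must
  reach $\ln(10^5) \approx 11.5$; a prior with sd 2 would actively fight
  the data there, so the intercept column gets its own wide scale;
* random-effect scales: half-normal(1) ($\tau = 1$ means site-to-site
  density varying by a factor of $e^{\pm 2}$, which matches the strong
  patchiness of surface slicks);
* $\Omega$: LKJ with concentration 2, placing mild mass toward the
  identity so correlations are shrunk when the data carry little
  information (important for the rare taxa);
* $p_j$: Beta(2, 2), keeping detection probabilities away from the
  boundaries during inference (the pmf itself accepts $p = 1$ for checks).

### Sampling

The posterior is explored with an adaptive Metropolis-within-Gibbs sampler
written in C++, on the unconstrained scale (log $\tau$, logit $p$, and
$\Omega$ through tanh-transformed canonical partial correlations of its
Cholesky factor, whose LKJ density and transform Jacobian are both
row-local).  Random effects use the non-centered parametrization by
default (`centered = TRUE` is available and agrees within Monte Carlo
error — a test asserts this).

Plain componentwise random walks mix very poorly here, for reasons worth
recording because they are properties of the model, not the sampler:

* informative counts pin $\eta_{ij}$, so coefficients can only move if a
  whole column of random effects moves in compensation.  The sampler
  therefore includes *shear* moves that translate $(\beta_j,
  \varepsilon_{\cdot j})$ jointly along directions that leave every linear
  predictor — hence the entire likelihood — unchanged, with the proposal
  drawn in the metric of $(X^\top X)^{-1}$; only prior terms enter the
  acceptance ratio;
* $\tau$ and $\Omega$ coordinates drag pinned effects along in the
  non-centered parametrization, so they also receive interweaved updates in
  centered coordinates (effects held fixed, likelihood cancels) after which
  the non-centered coordinates are recomputed — the
  ancillarity–sufficiency interweaving idea;
* only $\lambda_{ij} p_j$ is well identified, so $\beta_{0j}$ and
  $\mathrm{logit}\,p_j$ lie on a ridge; a dedicated move shifts
  $\mathrm{logit}\,p_j$ and compensates the intercept by $\ln(p^{\rm
  old}/p^{\rm new})$, keeping every expected observed count fixed;
* a covariance-adaptive block per category (Haario-style, learned during
  warmup only) handles the remaining within-category correlations.

All proposal scales and covariances adapt during warmup only, so the
post-warmup chain is a fixed Markov kernel.  Defaults are 4 chains, 1000
warmup and 1000 retained draws; with 22 sites and 6 categories a fit takes
a few seconds, and split-$\hat R$, bulk and tail effective sample sizes are
attached to every fit (`glance()` summarises them; the weakly identified
intercept/detectability and rare-taxa correlation coordinates are the slow
ones, as expected).

## Derived statistics

All headline quantities are functionals of the posterior draws, computed
per draw:

* **Region contrast** $\Delta_j$: the difference in expected log density
  between inside and outside, each averaged over its region's distribution
  of log tracer.  In closed form
  $\Delta_j = \beta_{2j} + \beta_{1j} (m_{\rm in} - m_{\rm out}) +
  \beta_{3j} m_{\rm in}$ with $m$ the weighted mean log tracer; random
  effects average out and the intercepts and $p_j$ cancel, so $\Delta$ is
  robust to catchability and detectability biases.  `prob_positive()`
  reports $P(\Delta > 0)$.
* **Marginal correlations** $\rho_{jk}$ between two categories' log
  densities over a region: covariate-driven covariance plus $\Sigma$,
  $\rho = (\mathrm{Cov}_{x,z}(\mu_j, \mu_k) + \Sigma_{jk}) /
  \sqrt{\cdots}$, computed from weighted covariate moments.  A Monte Carlo
  sampling oracle (draw $(x, z)$ and $\varepsilon$, correlate the linear
  predictors) verifies the closed form in the tests.
* **Total-neuston correlation**: $\ln \sum_{j \in \text{neuston}}
  e^{\eta_j}$ against plastic's $\eta$ — a log-sum-exp of correlated
  lognormals with no closed form, so it is Monte Carlo per posterior draw.
  The default is $10^4$ points per draw: the Monte Carlo standard error of
  a correlation is about $(1-\rho^2)/\sqrt{n}$, so $10^4$ gives \~0.01,
  well below the posterior spread; raise `n` for publication-grade third
  decimals.
* **Prior pushforwards** (`prior_pushforward()`): the same functionals
  applied to draws from the prior, for the "did the data actually inform
  this?" comparison.  On study-scale synthetic fits the posterior
  $\Delta$ spread is several-fold smaller than the prior's.
* **Fitted curves** (`fitted_curve()`): posterior mean and equal-tailed
  bands of $\eta(x, z) + \ln p_j$, the *detectable* log density, which is
  the scale on which observed mean counts are comparable to the model.

The covariate distribution of a region defaults to the tracer values of
the grid cells in its threshold-derived mask, with equal weights
(`region_covariate_sample()`); the observed sites' values are a
one-argument alternative.  The choice is exposed because both are
reasonable readings of "averaged over the region's tracer distribution";
$\Delta$ moves little between them when the masks track the sites.

## The synthetic-data generator

`make_tracer_field()` builds a smooth strictly positive concentration
field (background plus Gaussian bump, normalised to maximum 1);
`select_sites()` places sites without replacement with probability
proportional to tracer (power configurable), 12 inside and 10 outside the
patch mask by default; `simulate_counts()` draws effects, latent counts
and the two thinned counts with exactly the model's generative structure —
and is the *same* code the posterior predictive check uses for replicate
data.  Default truth values put the abundant taxa at $10^3$–$10^5$ km⁻²,
make *Glaucus* and *Physalia* rare enough that most of their counts are
zero, and use swept areas uniform on $[8 \times 10^{-4}, 1.7 \times
10^{-3}]$ km² (a 0.9 m net mouth towed for 30 minutes at 1–2 knots).

What the generator does *not* emulate — so passing tests say nothing about
these — is spatial autocorrelation beyond the tracer gradient (slicks,
clustered trawls), temporal change over a multi-week expedition, net-type
selectivity differences, and observer asymmetry; the model itself assumes
all of these away, as stated.

## Model validation

* **Posterior predictive checks** (`posterior_predictive()`): for a
  subsample of draws, a full replicate dataset at the observed covariates;
  discrepancy statistics are the per-category zero fraction, maximum and
  total count, chosen to expose overdispersion and rare-taxon behaviour.
* **Leave-one-out** (`loo_pointwise()`): with observation-level effects a
  conditional LOO is invalid, so the pointwise likelihood integrates out
  the held-out site's effect vector.  The integrand is far narrower than
  the prior when counts are informative, so naive Monte Carlo over
  $\mathrm{MVN}(0, \Sigma)$ is hopeless; for every (site, draw) pair a
  Laplace approximation is built by Newton iteration (the likelihood is
  separable across categories, making the Hessian diagonal-plus-$\Sigma^{-1}$)
  and draws come from a defensive mixture of the matched normal and the
  prior, exactly reweighted.  Importance ratios are Pareto-smoothed; the
  generalized-Pareto shape is estimated with the Zhang–Stephens
  empirical-Bayes fit and sites with $\hat k > 0.7$ are flagged, with an
  optional exact refit.  On a 6-site dataset IS and exact refits agree
  closely wherever $\hat k$ is small (a test asserts this).
* **Sensitivity refits**: `refit_without()` (dropping a site errors if a
  region would be emptied) and `recode_region()` for the
  borderline-membership check.
* **Parameter recovery** (`recovery_experiment()`): simulate–fit–check
  replication reporting 95% interval coverage and normalised ranks for the
  slopes, patch effects, detection probabilities and $\Delta$.

## Numerical choices and problem sizes

The pmf uses a growable $\log k!$ table rather than repeated `lgamma`
calls; tie-breaks and degenerate cases ($\lambda = 0$, $p = 1$, empty
regions, a single region, zero-row data for prior checks) are all defined
and tested.  Every stage's randomness derives from one master seed by
hashing the stage name (`stage_seed()`), so pipeline artifacts are
byte-identical across reruns — a test and the acceptance script both
assert this.

The shipped checks use deliberately modest sizes chosen so the full suite
runs in minutes while leaving each check comfortably powered: study-scale
fits with 2 chains × 800/800 iterations, recovery at 10 replicates of 100
sites with 2 × 600/600, Monte Carlo oracles at $10^4$–$10^5$ draws.  For
real analyses use the defaults (4 × 1000/1000) or more, and replicate
recovery experiments at 50+.

## Known limitations

Detection probabilities are shared between observers and there are no
false positives, by construction.  Absolute densities are weakly
identified (the posterior of $\beta_0 + \ln p$ is far tighter than either
alone — a test asserts the variance ratio), so report $\Delta$ and $\rho$,
not intercepts.  The sampler is a random-walk scheme with tailored moves,
not a gradient-based one: for much larger surveys (hundreds of sites) a
Hamiltonian sampler would scale better.  The LKJ concentration matters for
rare taxa, whose correlations are prior-dominated; sensitivity to it is
worth checking in any application.  Spatially structured covariance
(slicks, clustered trawls) is deliberately out of scope.
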