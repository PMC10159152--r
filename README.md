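# neuston

Hierarchical Bayesian analysis of floating life (obligate neuston) and
plastic densities in ocean gyre accumulation zones, from dual-observer
net-tow surveys.

## The problem

Net-tow surveys of accumulation zones such as the North Pacific "Garbage
Patch" ask whether obligate neuston — *Velella* (by-the-wind sailors),
*Porpita* (blue buttons), *Janthina* (violet snails), *Glaucus* (blue sea
dragons) and *Physalia* (Portuguese man-o-war) — concentrate where floating
plastic does. The data fight back: a few dozen tows at most, sites placed
deliberately along routes of predicted high debris concentration, raw
counts with many zeros for rare taxa, and a photographic protocol in which
two observers independently count each image, so neither count is the true
number of objects in the sample.

This package models all of that jointly:

* **Observation model.** The two counts of category *j* at site *i* are
  independent binomial thinnings, with shared detection probability
  *p<sub>j</sub>*, of a latent Poisson count with mean
  λ<sub>ij</sub> = A<sub>i</sub> exp(η<sub>ij</sub>), where A<sub>i</sub>
  is the swept area (km²). Marginally each count is
  Poisson(λp), and the inter-observer correlation equals *p* — the
  bivariate compound Poisson distribution (`dual_count_logpmf()`).
* **Log-density regression.** η<sub>ij</sub> = β₀ⱼ + β₁ⱼxᵢ + β₂ⱼzᵢ +
  β₃ⱼxᵢzᵢ + εᵢⱼ with x = ln tracer concentration (a dimensionless
  surface-drift accumulation field, treated as known), z the a-priori
  patch membership, and site-level random effects
  εᵢ ~ MVN(0, Σ) whose correlation matrix links the categories' log
  densities (LKJ prior). Posterior sampling is an adaptive
  Metropolis-within-Gibbs sampler in C++ with likelihood-invariant shear
  moves and interweaved updates that handle this model's identifiability
  ridges (see the vignette).
* **Derived statistics.** Region-averaged inside-vs-outside log-density
  contrasts Δⱼ, marginal correlations ρ between each taxon's and plastic's
  log densities (and for total neuston), their posterior probabilities of
  being positive, prior pushforwards, and fitted detectable-density
  curves. Δ and ρ do not involve the intercepts or detection
  probabilities, so they are robust to catchability biases.
* **Validation.** Posterior predictive checks, Pareto-smoothed
  importance-sampling leave-one-out cross-validation with the site-level
  effect integrated out (Laplace-matched proposals), sensitivity refits
  (site removal, region recoding), and simulate–fit–check
  parameter-recovery experiments.
* **Re-analysis variant.** A single-count Poisson model over three survey
  areas with pairwise region contrasts and per-area correlations, for
  surveys with one laboratory count per sample.
* **Synthetic data.** A generator with the model's exact generative
  structure (tracer field, tracer-biased site selection, thinned dual
  counts), so every stage is testable without external data.

## Worked example

Simulate a survey at the study's scale (22 tows, 12 inside / 10 outside
the patch, six categories), fit the model, and compute the headline
statistics:

```r
library(neuston)
library(dplyr)

scen  <- scenario_config(seed = 1)
field <- make_tracer_field(scen)
sites <- select_sites(field, scen)
obs   <- simulate_counts(sites, default_truth(), scen)

region_density_summary(density_from_counts(obs))
#> # A tibble: 2 × 5
#>   region  n_sites median     q1     q3
#>   <chr>     <int>  <dbl>  <dbl>  <dbl>
#> 1 inside       12 41355. 28989. 71871.
#> 2 outside      10  6779.  4648. 13649.
```

Total neuston densities (numbers km⁻², mean of the two observers' counts
over swept area, summed over the five taxa) are an order of magnitude
higher inside the patch — the qualitative signature the model then
quantifies:

```r
fit <- fit_posterior(obs, chains = 2, warmup = 800, iter = 800, seed = 7)

cov_in  <- covariate_sample(log(obs$tracer[obs$region == "inside"]), "inside")
cov_out <- covariate_sample(log(obs$tracer[obs$region == "outside"]), "outside")

delta_in_out(fit, cov_in, cov_out) |>
  group_by(category) |>
  summarise(mean = mean(delta), lower = quantile(delta, .025),
            upper = quantile(delta, .975), p_positive = prob_positive(delta))
#> # A tibble: 6 × 5
#>   category   mean    lower upper p_positive
#>   <chr>     <dbl>    <dbl> <dbl>      <dbl>
#> 1 Glaucus   4.33  -0.00272 9.75       0.974
#> 2 Janthina  1.68   0.671   2.89       0.999
#> 3 Physalia -0.925 -2.85    0.990      0.159
#> 4 Porpita   1.03  -0.109   2.33       0.96
#> 5 Velella   1.95   1.02    2.92       1
#> 6 plastic   2.06   1.32    2.80       1
```

`delta` is the difference in expected natural-log density between the
inside- and outside-patch regions, averaged over each region's tracer
distribution: a mean of 1.95 for *Velella* is an e^1.95 ≈ 7-fold higher
expected density inside, with posterior probability ≈ 1 that the
difference is positive. The rare taxa (*Glaucus*, *Physalia*) have wide,
prior-dominated contrasts, exactly as mostly-zero counts warrant.

```r
cov_all <- bind_rows(cov_in, cov_out) |> mutate(weight = weight / sum(weight))
marginal_correlation(fit, cov_all) |>
  group_by(category_a) |>
  summarise(mean = mean(rho), p_positive = prob_positive(rho))
#> # A tibble: 5 × 3
#>   category_a   mean p_positive
#>   <chr>       <dbl>      <dbl>
#> 1 Glaucus     0.656      0.992
#> 2 Janthina    0.458      0.994
#> 3 Physalia   -0.345      0.182
#> 4 Porpita     0.271      0.906
#> 5 Velella     0.558      0.999
```

Each row is the marginal correlation between that taxon's and plastic's
log densities over the whole study region, combining covariate-driven and
residual (random-effect) association. `glance(fit)` and `tidy(fit)` give
sampler diagnostics and posterior summaries; `plot_delta()`,
`plot_correlations()`, `plot_fitted_curves()` and `autoplot()` draw the
standard figures; `run_pipeline()` chains the whole analysis and writes
every artifact with content fingerprints.

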