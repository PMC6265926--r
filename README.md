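# geoadditive

Bayesian geo-additive binary regression for record-level survey data, built
for analyses of the kind used to map contraceptive prevalence among women of
childbearing age across a country's districts: which socio-economic factors
are associated with use, how the two age variables act nonlinearly, and
which districts sit above or below the national level after adjusting for
everything else. The intended users are biostatisticians and
epidemiologists working with DHS-style extracts (one row per respondent:
binary outcome, categorical covariates, continuous ages, district and
cluster codes).

## The model

For woman *i* in district *j*,

    y_ij ~ Bernoulli(p_ij)
    logit(p_ij) = w_ij' beta  +  f1(current age_i)  +  f2(age at first cohabitation_i)  +  f_spat(s_j)

* `beta` — treatment-coded fixed effects of the categorical covariates
  (diffuse normal priors), reported as odds ratios with 95% credible
  intervals against named reference levels;
* `f1`, `f2` — nonparametric smooth effects with second-order random-walk
  (RW2) priors on the whole-year age grids;
* `f_spat` — structured district effects with an intrinsic conditional
  autoregressive (ICAR) prior over the district adjacency graph
  (`Q = diag(n_j) − A`), drawn as a choropleth.

Four nested structures (fixed only / + smooths / + spatial / + both) are
fitted and ranked by the deviance information criterion
`DIC = D̄ + p_D`, `p_D = D̄ − D(θ̄)`. Posterior sampling is exact MCMC via
Polya-Gamma data augmentation: `omega_i ~ PG(1, eta_i)` makes the logistic
likelihood conditionally Gaussian, so each Gibbs cycle draws all
coefficients jointly from one multivariate normal, with sum-to-zero
constraints on each smooth and on the spatial field imposed by
conditioning-by-kriging. The package also ships the descriptive stage that
precedes such models (method-mix prevalence, cross-tabulations with Pearson
chi-square screening at the 5% level) and a synthetic DHS-like survey
generator with known truth, so the whole workflow runs with no restricted
data access.

## Worked example

```r
library(geoadditive)

spec   <- simulation_spec(n_women = 3000, seed = 1)  # DHS-like conditions
survey <- simulate_survey(spec)

prevalence_by_method(survey)
#>   method          n   pct
#> 1 none         1390  46.3
#> 2 traditional   149   5
#> 3 modern       1461  48.7

screen_covariates(survey, c("education", "wealth", "working", "radio"))
#>   covariate statistic    df  p_value significant
#> 1 education      2.15     3 0.541    FALSE
#> 2 wealth        18.9      4 0.000840 TRUE
#> 3 working       14.8      1 0.000122 TRUE
#> 4 radio          1.37     1 0.241    FALSE

fit <- fit_model(survey, graph = spec$graph, spec = model_spec(4),
                 mcmc = mcmc_settings(4000, 1000, 3, seed = 1))
tidy(fit)
#>   term                estimate std.error odds.ratio conf.low conf.high
#> 1 (Intercept)           -0.908     0.322      0.403    0.222     0.787
#> 2 education:primary      0.160     0.103      1.17     0.968     1.44
#> 3 education:secondary    0.147     0.151      1.16     0.864     1.57
#> 4 education:tertiary     0.318     0.235      1.37     0.866     2.15
#> 5 wealth:middle          0.405     0.126      1.50     1.16      1.91
#> # ... 23 more rows

glance(fit)
#>   model_id     n n_draws D_bar   p_D   DIC
#> 1        4  3000    1000 3875.  52.7 3927.
```

The `tidy()` rows read exactly like the fixed-effect tables of published
analyses: `odds.ratio = exp(estimate)` is the multiplicative change in the
odds of contraceptive use relative to the covariate's reference level
(here e.g. tertiary vs no education), with the equal-tailed 95% credible
interval on the same scale. At n = 3,000 the education screening is
insignificant in this replicate while wealth and working status are — the
screening stage gates covariates into the multivariate model at the 5%
level. `autoplot(fit)` draws the smooth age effects with their credible
bands; `plot_spatial_effects(fit)` draws the district map on a diverging
scale centred at zero; `compare_models(...)` fits all four structures and
ranks them by DIC.

A command-line workflow (`simulate` / `describe` / `fit` / `compare` /
`map`) is available through `inst/cli/geoadditive.R` and `run_cli()`.

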