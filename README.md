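# htebayes

Bayesian shrinkage and regression models for subgroup treatment effects.

## What it is for

Clinical trials are powered for the *average* treatment effect, yet the
questions that matter for treatment decisions are subgroup-level: does the
drug work for women over 65 with a high ejection fraction? Crossing the
baseline covariates yields `G` mutually exclusive subgroups with true
effects `theta_g` (mean differences, log-odds ratios or log-hazard
ratios), but within-subgroup estimates `theta_hat_g` are noisy and
one-at-a-time interaction tests lose power to multiplicity corrections.

`htebayes` fits a suite of seven Bayesian models to the per-subgroup
summary pairs `(theta_hat_g, s_g)` under the sampling model

```
theta_hat_g | theta_g ~ Normal(theta_g, s_g^2)
```

ranging from complete pooling to full stratification, with the basic
hierarchical shrinkage model at the center:

```
theta_g | tau, omega ~ Normal(tau, omega^2)
tau   ~ Normal(0, sigma_tau^2)          (default sigma_tau^2 = 1000)
omega ~ Half-Normal(sigma_omega^2)      (default sigma_omega^2 = 100)
```

Its posterior means obey the shrinkage identity
`E(theta_g | y) ≈ tau_hat + E(r | y) (theta_hat_g - tau_hat)` with
`r(omega, s_g) = omega^2 / (omega^2 + s_g^2)`: noisy subgroups borrow
strength from the rest. Dixon–Simon-style interaction regressions
(first-order, and extended with second/third-order terms under
per-order heterogeneity scales) capture the correlation between subgroups
that share covariate levels. Model comparison uses the DIC
(`DIC = D_bar + p_D`, differences under 3–5 are not meaningful), model
criticism uses posterior predictive checks on the median/SD/min/max of
the subgroup estimates, and prior robustness is probed with a
sensitivity grid over half-normal scales and an approximate Jeffreys
prior. Frequentist comparators (univariate and unstructured
treatment–covariate interaction Wald tests, Bonferroni adjustment) and a
minimal Newton/Breslow Cox partial-likelihood core for per-subgroup
log-hazard ratios are included.

## Worked example

The package bundles a synthetic 12-subgroup summary table
(gender x age x ejection-fraction tertile) generated from the shrinkage
model itself with `tau = -0.3`, `omega = 0.2` on the log-hazard-ratio
scale (negative = benefit).

```r
library(htebayes)
data <- read_summary_table(
  system.file("extdata", "solvd_like_synthetic_summary.csv",
              package = "htebayes"),
  effect_scale = "log_hr")

fit <- run_mcmc(make_model("basic_shrinkage", data$frame), data,
                n_iter = 4000, n_burn = 1000, chains = 2, seed = 7)
fit
#> MCMC fit of 'basic_shrinkage': 2 chain(s) x 3000 retained draws;
#> max split-Rhat = 1.005 (converged)

s <- summarize_posterior(fit, thresholds = 0)
head(s$effects[, c("subgroup", "mean", "2.5%", "97.5%")], 4)
#>                            subgroup       mean       2.5%      97.5%
#> 1   gender=F/age=<=65/ejecfrac=high -0.5073434 -0.8805581 -0.2098119
#> 2 gender=F/age=<=65/ejecfrac=medium -0.2356630 -0.5155190  0.1356217
#> 3    gender=F/age=<=65/ejecfrac=low -0.4217834 -0.7572204 -0.1197058
#> 4    gender=F/age=>65/ejecfrac=high -0.4672453 -0.8189944 -0.1820618
```

The posterior mean of the overall effect `tau` is `-0.366`; raw estimates
are pulled toward it, more strongly for the noisy female subgroups
(`s_g = 0.25`, expected shrinkage fraction `E(r|y) = 0.34`) than for the
male subgroups (`s_g = 0.12`, `E(r|y) = 0.64`). The `thresholds = 0`
column of the summary gives `P(theta_g < 0 | y)` per subgroup — the direct
probability-of-benefit statement.

```r
dic(fit)
#> DIC ('basic_shrinkage'): D_bar = 12.402, p_D = 7.166, DIC = 19.568

ppc_statistics(posterior_predictive_draws(fit, n_rep = 1000, seed = 7),
               data)$table[, c("statistic", "observed", "p_value")]
#>   statistic    observed p_value
#> 1    median -0.36820753   0.516
#> 2        sd  0.24761708   0.512
#> 3       min -0.79100515   0.504
#> 4       max  0.02646714   0.566
```

`p_D ≈ 7` sits between the 1 effective parameter of complete pooling and
the 12 of full stratification — partial pooling in action. All four
predictive p-values are near 0.5: no sign of misfit (unsurprising, as the
fixture was generated from this model).

See `vignettes/bayesian-subgroup-analysis.Rmd` for the model suite,
priors, sampler and design decisions, and `inst/cli/hte.R` for the
command-line pipeline (`simulate`, `summarize`, `fit`, `compare`, `ppc`,
`sensitivity`, `report`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hte.R", package = "htebayes"))')" \
    fit --config config.yaml --out results/
```

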