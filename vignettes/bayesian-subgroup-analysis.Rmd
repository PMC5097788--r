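---
title: "Bayesian models for heterogeneity of treatment effect across subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian models for heterogeneity of treatment effect across subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(htebayes)
```

## The problem

A randomized trial reports a beneficial average treatment effect, but
clinicians want to know whether particular kinds of patients — women over
65 with a high ejection fraction, say — benefit more, less, or perhaps not
at all. Crossing a handful of categorical baseline covariates partitions
the trial population into `G` mutually exclusive subgroups, each with its
own true treatment effect `theta[g]`. Within-subgroup sample sizes are
small, so the raw per-subgroup estimates `theta_hat[g]` are noisy, and the
usual frequentist toolbox (one interaction test per covariate plus a
multiplicity correction) can only detect that *some* interaction exists —
it neither quantifies the per-subgroup effects nor answers direct
questions like "what is the probability this subgroup benefits?".

This package implements a Bayesian treatment of the problem: all subgroup
effects are placed in one joint model, so each subgroup borrows strength
from the rest, and every clinical question becomes a posterior
probability. The frequentist interaction tests are included as
comparators.

## Data reduction

Every Bayesian model here consumes only the per-subgroup summary pair
`(theta_hat[g], se[g])` and the sampling approximation

    theta_hat[g] | theta[g] ~ Normal(theta[g], se[g]^2).

The reduction from subject-level data is performed by
`compute_subgroup_summaries()`: difference of arm means with the pooled
two-sample standard error (continuous outcomes), log-odds ratio with the
Woolf standard error (binary), or the log-hazard ratio from a one-covariate
Cox proportional-hazards fit inside each subgroup (survival). Treating
`se[g]` as known ignores its sampling uncertainty; with moderate subgroup
sizes this is a standard and usually benign approximation, but for very
small subgroups the posterior intervals inherit that optimism.

A zero cell in a binary 2-by-2 table raises an error rather than applying
a silent continuity correction, because a correction changes
`theta_hat[g]` in a way the user should control; pre-aggregating or
merging levels is their decision. Rows with missing covariate values are
dropped with a reported count.

## The model suite

Seven models span the pooling spectrum. All share the normal sampling
model above and a diffuse `Normal(0, sigma_tau2)` prior (default
`sigma_tau2 = 1000`) on unstructured location parameters.

1. **pooled** — `theta[g] = tau` for all `g`: no heterogeneity.
2. **stratified** — independent `theta[g]`: no pooling; the Bayesian
   mirror of the fully stratified frequentist analysis.
3. **basic_shrinkage** — `theta[g] ~ Normal(tau, omega^2)` with
   `tau ~ Normal(0, sigma_tau2)` and a half-normal prior on `omega`. The
   posterior mean obeys (up to Monte-Carlo error and the posterior
   correlation between the shrinkage fraction and `tau`)

       E(theta[g] | y) ≈ tau_hat + E(r | y) (theta_hat[g] - tau_hat),
       r(omega, s_g) = omega^2 / (omega^2 + s_g^2),

   so noisier subgroups are shrunk harder toward the overall effect.
4. **basic_regression** — `theta = tau + X beta` on the order-1
   interaction design, each coefficient with its own diffuse prior.
5. **regression_plus_shrinkage** — adds exchangeable deviations
   `phi[g] ~ Normal(0, omega^2)` to the regression surface.
6. **dixon_simon** — `theta = tau + X beta` with
   `beta ~ Normal(0, omega^2)` sharing one heterogeneity scale, which
   shrinks the interaction coefficients jointly toward zero and induces a
   correlation structure where subgroups sharing covariate levels are more
   similar a priori.
7. **extended_dixon_simon** — adds second- and third-order interaction
   products, each order with its own scale `omega1, omega2, omega3` under
   independent priors. With more than three covariates, interactions above
   order three are not modeled — the coefficient count would explode and
   three-way terms already exhaust what subgroup-level data can support.

The roster deliberately includes the two pooling extremes (1 and 2): they
complete the compromise that the shrinkage models interpolate and give DIC
comparisons fixed reference points. Models 4 and 5 are only sketched in
the methodological literature this suite follows; the concrete forms
above (diffuse independent coefficient priors; a single shared scale for
the additive deviations) are this package's documented reading, stated
here because no canonical formulation exists to defer to. The prior
variance `sigma_tau2` is reused for stratified effects and diffuse
regression coefficients — a package convention keeping the prior count
small.

Dummy (reference-level) coding is used throughout, never sum-to-zero
coding, so a coefficient reads as the change from the declared reference
level; the first declared level of each covariate is its reference.
Subgroups are ordered lexicographically (first covariate slowest), and
every downstream vector indexes subgroups by that ordering.

## Priors for the heterogeneity scale

`omega` is the between-subgroup standard deviation of the true effects:
the single most influential parameter when `G` is small. The default
prior is Half-Normal with "variance" hyperparameter 100. A pitfall
deserves emphasis: Half-Normal(b^2) here means the law of `b |Z|`, so the
hyperparameter 100 corresponds to scale 10. Handy multipliers of the
scale: the prior median of `omega` is 0.674 sigma, the 75th percentile
1.150 sigma, the 99th percentile 2.576 sigma. Because the notation
"Half-Normal(0.1)" is ambiguous between variance and scale conventions,
`prior_spec()` accepts either `sigma_omega2` (variance) or `omega_scale`
(scale) and records which was meant.

The alternative is an approximate Jeffreys prior on `omega^2`,
proportional to `1/omega^2` above a truncation point `eps = 0.005` and
flat below it (continuous at the join). It is improper in the right tail
as written, so the sampler truncates at `omega^2 <= 1e4`; posterior mass
near that bound would indicate the prior choice is doing real work and
should be revisited. A *skeptical* analysis — concentrating the prior near
zero to down-weight large heterogeneity — is expressed by shrinking the
half-normal scale.

`sensitivity_grid()` automates the recommended robustness exercise:
refit one model under a list of priors (several half-normal scales plus
the Jeffreys option is the natural grid) and tabulate the per-subgroup
posterior means and intervals side by side, with every cell run from the
same master seed so that differences between cells reflect the priors and
not Monte-Carlo noise. Sensitivity is largest when `G` is small or the
true heterogeneity is near zero.

## Sampling

`run_mcmc()` uses Metropolis-free Gibbs sampling. Conditional on the
heterogeneity scales, every model is linear-Gaussian: subgroup effects
come from the closed-form conjugate conditional
(`conditional_theta_posterior()`), and coefficient blocks from their
multivariate-normal full conditionals via a Cholesky solve. Each scale
`omega` is updated by slice sampling on `log(omega)` with the Jacobian
correction; sampling on the log scale avoids the boundary sticking near
`omega = 0` that plagues random-walk updates precisely in the
small-heterogeneity regime where the prior matters most. The pooled,
stratified and basic-regression posteriors are exactly Gaussian and are
sampled directly.

Defaults: 4 chains, 5000 iterations, 2500 burn-in, no thinning — generous
for these conditionally conjugate models at `G` up to a few dozen, where
mixing is fast. Initialization is deterministic (effects at
`theta_hat`, overall effect at the precision-weighted mean, coefficients
at zero, scales at `sd(theta_hat)` floored at 1e-3), and per-chain RNG
substreams are derived from one master seed, so results are exactly
reproducible. Split-Rhat is computed per parameter; any value above 1.1
flags the fit non-converged — the flag is returned (and surfaced as a
nonzero CLI exit status), never silently dropped.

## Model comparison and checking

For the normal sampling model the deviance is
`D(theta) = sum_g ((theta_hat[g] - theta[g]) / s_g)^2`, and `dic()`
reports the posterior expected deviance `D_bar`, the effective number of
parameters `p_D = D_bar - D(theta_bar)`, and `DIC = D_bar + p_D`. The
identities hold by construction; `p_D` is nonnegative up to Monte-Carlo
error because the deviance is quadratic. As a calibration anchor, the
stratified model with informative data has `p_D` near `G`. DIC
differences below about 3 (to 5) are not meaningful, and `dic_table()`
annotates them as such.

Posterior predictive checks draw replicate data sets
`theta_hat_rep[g] ~ Normal(theta_g_draw, s_g^2)` and compare the scalar
statistics median, SD, minimum and maximum across subgroups with their
observed values. The p-value convention is fixed as
`P(T(y_rep) >= T(y) | y)` with ties counted in; values outside
(0.05, 0.95) are flagged. Checks are done on the `theta_hat` scale — the
scale the models actually see. Default 1000 replicates.

## The synthetic-data generators

`simulate_summary_data()` draws directly from the two-stage normal model
(`theta[g] ~ Normal(tau, omega^2)`, `theta_hat[g] ~ Normal(theta[g],
se[g]^2)`) and returns the generating truth. The bundled 12-subgroup
fixture (`inst/extdata/solvd_like_synthetic_summary.csv`) was produced
this way with `tau = -0.3`, `omega = 0.2`, and standard errors of 0.25
for the six smaller (female) subgroups and 0.12 for the six larger
(male) ones — magnitudes chosen to resemble a large mortality trial with
a 2:4 imbalance in subgroup sizes on the log-hazard-ratio scale. It is a
synthetic stand-in, not trial data.

`simulate_subject_data()` generates subject-level records with known
per-subgroup effects: normal outcomes with unit residual SD, Bernoulli
outcomes around a baseline logit of zero, or exponential event times with
control rate 1. Censoring marks a Bernoulli(`censor_rate`) subset of
subjects as censored at a uniform time before their event, which matches
the requested censoring fraction exactly in expectation; it is a fixture
convention, not an independent-censoring mechanism, and should not be
used to study censoring processes themselves.

What these generators do *not* emulate: correlation between covariates
(subgroup sizes are balanced by design), non-normal sampling error in
`theta_hat[g]`, uncertainty in `se[g]`, non-proportional hazards, or
informative censoring. Tests passing on this synthetic world demonstrate
the estimation machinery is correct under the stated model, not that the
model fits any particular trial.

## Numerical choices and edge cases

* Cox core: Breslow tie handling (not Efron) — simpler, and it matches a
  desk-checkable grid-search oracle; risk sets are right-continuous
  (a subject censored at an event time is still at risk there). Newton
  steps are halved when the partial log-likelihood decreases; convergence
  requires max |score| < 1e-8 within 50 iterations; a coefficient passing
  |beta| > 15 is reported as monotone-likelihood divergence naming the
  covariate. Constant or aliased covariate columns are rejected up front.
* Wald tests everywhere (not likelihood ratio): one fit per test and a
  direct correspondence with reported coefficient/SE tables; in small
  samples Wald and LR tests can disagree, which is the price of that
  convention.
* Bonferroni is the only multiplicity adjustment offered, raw and
  adjusted p-values are always reported side by side.
* `se[g] = 0` is invalid everywhere (it would give the likelihood
  infinite weight); validation errors cite the offending row.
* Degenerate `omega = 0` is representable in `conditional_theta_posterior`
  and via `fixed = list(omega = 0)` in `run_mcmc()` (complete shrinkage),
  but the samplers keep `omega > 0` when it is a free parameter.
* 95% intervals are used throughout the reporting layer.

## Problem sizes used in the test suite

The package's own checks run at deliberately desk-sized settings chosen
to keep Monte-Carlo error well inside the asserted tolerances: conjugate
and shrinkage-identity checks use 20,000-50,000 retained draws on the
12-subgroup fixture; parameter-recovery coverage uses 100 replicate fits
at `G = 50`, `tau = -0.3`, `omega = 0.25`, `se = 0.1` with 4000 retained
draws each; predictive-check self-consistency uses 100 simulated trials
of the 12-subgroup design; interaction-test calibration uses 1000 null
data sets of 200 subjects. These sizes are stated so that a reader can
judge the Monte-Carlo resolution of each claim.

## A worked example

```{r example}
frame <- build_subgroup_frame(list(
  covariate_spec("gender", c("F", "M")),
  covariate_spec("age", c("<=65", ">65")),
  covariate_spec("ejecfrac", c("high", "medium", "low"))
))
data <- read_summary_table(
  system.file("extdata", "solvd_like_synthetic_summary.csv",
              package = "htebayes"),
  effect_scale = "log_hr")

fit <- run_mcmc(make_model("basic_shrinkage", data$frame), data,
                n_iter = 4000, n_burn = 1000, chains = 2, seed = 7)
summarize_posterior(fit, thresholds = 0)
shrinkage_factors(fit)
dic(fit)
ppc_statistics(posterior_predictive_draws(fit, n_rep = 1000, seed = 7),
               data)
```

## Known limitations

Only categorical effect modifiers are supported (continuous ones must be
discretized by the user, and how they are cut is consequential).
Summary-level modeling discards within-subgroup covariance and treats
`se[g]` as known. There is no model averaging, no WAIC/LOO, no calibrated
(Meng-style) posterior predictive p-values, and no Efron ties, stratified
baselines, or time-varying covariates in the Cox core. The extended
interaction model stops at third-order terms. These are scope decisions,
not oversights.
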