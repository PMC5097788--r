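#' Half-normal distribution: quantiles, density, CDF, sampling
#'
#' The half-normal distribution with scale `sigma` is the distribution of
#' `sigma * |Z|` for standard normal `Z`. It is the default prior for the
#' between-subgroup heterogeneity scale `omega`; in the Half-Normal(b^2)
#' notation used for that prior, `b` is the scale passed here (so a prior
#' "variance" hyperparameter of 100 means scale 10). Useful reference
#' multipliers of the scale: median 0.674, 75th percentile 1.150, 99th
#' percentile 2.576.
#'
#' @param p Probability in `[0, 1)`.
#' @param sigma Nonnegative scale.
#' @return `half_normal_quantile` returns `sigma * qnorm((1 + p) / 2)`.
#' @examples
#' half_normal_quantile(c(0.5, 0.75, 0.99), 1)
#' @export
half_normal_quantile <- function(p, sigma) {
  if (any(p < 0 | p >= 1)) stop("domain error: p must lie in [0, 1)")
  if (any(sigma < 0)) stop("domain error: sigma must be nonnegative")
  sigma * stats::qnorm((1 + p) / 2)
}

#' @rdname half_normal_quantile
#' @param y Evaluation point(s), `y >= 0` on the support.
#' @export
half_normal_cdf <- function(y, sigma) {
  if (any(sigma <= 0)) stop("domain error: sigma must be positive")
  ifelse(y < 0, 0, 2 * stats::pnorm(y / sigma) - 1)
}

#' @rdname half_normal_quantile
#' @export
half_normal_logpdf <- function(y, sigma) {
  if (any(sigma <= 0)) stop("domain error: sigma must be positive")
  ifelse(y < 0, -Inf, log(2) + stats::dnorm(y, 0, sigma, log = TRUE))
}

#' @rdname half_normal_quantile
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @export
half_normal_sample <- function(n, sigma, seed = NULL) {
  if (any(sigma < 0)) stop("domain error: sigma must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  abs(stats::rnorm(n, 0, sigma))
}

#' Approximate Jeffreys prior for the heterogeneity variance
#'
#' Unnormalized log density of the approximate Jeffreys prior on
#' `omega^2`: proportional to `1 / omega^2` for `omega^2 >= eps` and flat
#' at `1 / eps` below (continuous at `eps`; with the default
#' `eps = 0.005` the flat part has height 200). The prior is improper in
#' the right tail, so samplers using it truncate at `omega^2 <= 1e4`.
#'
#' @param omega_sq Positive value(s) of `omega^2`.
#' @param eps Positive truncation point.
#' @return Unnormalized log density.
#' @export
jeffreys_approx_logdensity <- function(omega_sq, eps = 0.005) {
  if (any(omega_sq <= 0)) stop("domain error: omega_sq must be positive")
  if (eps <= 0) stop("domain error: eps must be positive")
  ifelse(omega_sq >= eps, -log(omega_sq), -log(eps))
}

#' Prior specification for the Bayesian subgroup models
#'
#' Bundles the hyperparameters shared by all seven models: the variance
#' `sigma_tau2` of the mean-zero normal priors on location parameters
#' (overall effect, stratified effects, diffuse regression coefficients)
#' and the prior for the heterogeneity scale `omega` - either
#' Half-Normal(`sigma_omega2`) (variance convention: scale
#' `sqrt(sigma_omega2)`) or the approximate Jeffreys prior on `omega^2`
#' with truncation `eps`. Because "Half-Normal(v)" is ambiguous between a
#' variance and a scale reading, `omega_scale` can be given instead of
#' `sigma_omega2` to state the scale convention explicitly.
#'
#' Defaults `sigma_tau2 = 1000` and `sigma_omega2 = 100` are diffuse on
#' the effect scales used here (mean differences, log-odds or log-hazard
#' ratios). A skeptical analysis concentrates the prior near zero by
#' shrinking these.
#'
#' @param family Prior family for `omega`: `"half_normal"` or
#'   `"jeffreys"`.
#' @param sigma_tau2 Variance of the normal prior on location parameters.
#' @param sigma_omega2 Variance hyperparameter of the half-normal prior.
#' @param omega_scale Scale of the half-normal prior; overrides
#'   `sigma_omega2` when supplied.
#' @param eps Truncation point of the approximate Jeffreys prior.
#' @param label Optional display label (used in sensitivity grids).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(family = c("half_normal", "jeffreys"),
                       sigma_tau2 = 1000, sigma_omega2 = 100,
                       omega_scale = NULL, eps = 0.005, label = NULL) {
  family <- match.arg(family)
  if (sigma_tau2 <= 0 || sigma_omega2 <= 0)
    stop("domain error: prior variances must be positive")
  if (eps <= 0) stop("domain error: eps must be positive")
  scale <- if (!is.null(omega_scale)) {
    if (omega_scale <= 0) stop("domain error: omega_scale must be positive")
    omega_scale
  } else sqrt(sigma_omega2)
  if (is.null(label))
    label <- if (family == "jeffreys")
      sprintf("Jeffreys(eps=%g)", eps)
    else sprintf("Half-Normal(scale=%g)", scale)
  structure(list(family = family, sigma_tau2 = sigma_tau2,
                 omega_scale = scale, eps = eps, label = label),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior spec:", x$label, "| sigma_tau^2 =", x$sigma_tau2, "\n")
  invisible(x)
}

# log prior density for omega (on the omega scale, not omega^2), including
# the change of variables for the Jeffreys-on-omega^2 family, truncated at
# omega^2 <= 1e4 to keep the posterior proper
omega_logprior <- function(omega, prior) {
  if (omega <= 0) return(-Inf)
  if (prior$family == "half_normal") {
    half_normal_logpdf(omega, prior$omega_scale)
  } else {
    if (omega^2 > 1e4) return(-Inf)
    jeffreys_approx_logdensity(omega^2, prior$eps) + log(2 * omega)
  }
}
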