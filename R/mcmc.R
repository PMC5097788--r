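#' Closed-form conditional posterior of a subgroup effect
#'
#' With the overall effect `tau` and heterogeneity scale `omega` held
#' fixed, the conditional posterior of `theta[g]` given
#' `theta_hat[g] ~ N(theta[g], s^2)` and `theta[g] ~ N(tau, omega^2)` is
#' normal with mean `tau + r * (theta_hat - tau)` where
#' `r = omega^2 / (omega^2 + s^2)` is the shrinkage fraction, and variance
#' `(1/s^2 + 1/omega^2)^{-1}`. `omega = 0` gives complete shrinkage:
#' mean `tau`, variance 0.
#'
#' @param theta_hat Observed subgroup estimate(s).
#' @param s Positive standard error(s).
#' @param tau Overall effect.
#' @param omega Nonnegative heterogeneity scale.
#' @return List with `mean` and `variance` (vectorized over inputs).
#' @export
conditional_theta_posterior <- function(theta_hat, s, tau, omega) {
  if (any(s <= 0)) stop("domain error: s must be positive")
  if (any(omega < 0)) stop("domain error: omega must be nonnegative")
  r <- omega^2 / (omega^2 + s^2)
  # (1/s^2 + 1/omega^2)^{-1} = r * s^2, which also covers omega = 0
  list(mean = tau + r * (theta_hat - tau), variance = r * s^2)
}

# univariate slice sampler (stepping out, then shrinkage), Neal (2003)
slice_sample_1d <- function(x0, logf, w = 1, m = 50L) {
  fx0 <- logf(x0)
  n_eval <- 1L
  logy <- fx0 - stats::rexp(1)
  u <- stats::runif(1) * w
  L <- x0 - u
  R <- x0 + (w - u)
  j <- floor(stats::runif(1) * m)
  k <- (m - 1L) - j
  while (j > 0 && { n_eval <- n_eval + 1L; logf(L) > logy }) {
    L <- L - w; j <- j - 1L
  }
  while (k > 0 && { n_eval <- n_eval + 1L; logf(R) > logy }) {
    R <- R + w; k <- k - 1L
  }
  repeat {
    x1 <- stats::runif(1, L, R)
    n_eval <- n_eval + 1L
    if (logf(x1) >= logy) return(list(x = x1, n_eval = n_eval))
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# slice update of omega on the log scale; `dev` are the zero-mean normal
# deviates governed by omega (theta - tau, beta, or phi)
update_omega <- function(omega, dev, prior) {
  n <- length(dev)
  ss <- sum(dev^2)
  target <- function(u) {
    om <- exp(u)
    lp <- omega_logprior(om, prior)
    if (!is.finite(lp)) return(-Inf)
    -n * u - ss / (2 * om^2) + lp + u  # likelihood + prior + log-Jacobian
  }
  res <- slice_sample_1d(log(omega), target)
  list(omega = exp(res$x), n_eval = res$n_eval)
}

# one MVN draw of coefficients b for y ~ N(Wb, diag(s2)), b ~ N(0, diag(1/pp))
draw_coefs <- function(W, y, s2, prior_prec) {
  P <- crossprod(W, W / s2) + diag(prior_prec, ncol(W))
  R <- chol(P)
  mu <- backsolve(R, forwardsolve(t(R), crossprod(W, y / s2)))
  drop(mu) + drop(backsolve(R, stats::rnorm(ncol(W))))
}

# single-chain Gibbs sampler; returns post-burn-in, thinned draws matrix
gibbs_chain <- function(spec, data, n_iter, n_burn, thin, chain_seed,
                        fixed = list()) {
  set.seed(chain_seed)
  G <- spec$G
  y <- data$theta_hat
  s2 <- data$se^2
  pr <- spec$priors
  st2 <- pr$sigma_tau2
  lay <- spec$layout
  keep <- seq(n_burn + 1L, n_iter, by = thin)
  n_keep <- length(keep)
  out <- matrix(NA_real_, n_keep, spec$n_params,
                dimnames = list(NULL, spec$param_names))
  n_eval_total <- 0L
  n_slice <- 0L

  if (spec$name == "pooled") {
    prec <- sum(1 / s2) + 1 / st2
    mu <- sum(y / s2) / prec
    out[, 1L] <- stats::rnorm(n_keep, mu, sqrt(1 / prec))
  } else if (spec$name == "stratified") {
    prec <- 1 / s2 + 1 / st2
    mu <- (y / s2) / prec
    for (g in seq_len(G))
      out[, g] <- stats::rnorm(n_keep, mu[g], sqrt(1 / prec[g]))
  } else if (spec$name == "basic_regression") {
    W <- cbind(1, spec$X)
    p <- ncol(W)
    P <- crossprod(W, W / s2) + diag(1 / st2, p)
    R <- chol(P)
    mu <- drop(backsolve(R, forwardsolve(t(R), crossprod(W, y / s2))))
    Z <- matrix(stats::rnorm(p * n_keep), p, n_keep)
    out[, seq_len(p)] <- t(mu + backsolve(R, Z))
  } else if (spec$name == "basic_shrinkage") {
    theta <- y
    tau <- if (!is.null(fixed$tau)) fixed$tau else
      sum(y / s2) / sum(1 / s2)
    omega <- if (!is.null(fixed$omega)) fixed$omega else
      max(stats::sd(y), 1e-3)
    row <- 0L
    for (it in seq_len(n_iter)) {
      cp <- conditional_theta_posterior(y, data$se, tau, omega)
      theta <- stats::rnorm(G, cp$mean, sqrt(cp$variance))
      if (is.null(fixed$tau)) {
        prec_t <- G / omega^2 + 1 / st2
        tau <- stats::rnorm(1, sum(theta) / omega^2 / prec_t,
                            sqrt(1 / prec_t))
      }
      if (is.null(fixed$omega)) {
        up <- update_omega(omega, theta - tau, pr)
        omega <- up$omega
        n_eval_total <- n_eval_total + up$n_eval
        n_slice <- n_slice + 1L
      }
      if (it > n_burn && (it - n_burn - 1L) %% thin == 0L) {
        row <- row + 1L
        out[row, ] <- c(theta, tau, omega)
      }
    }
  } else if (spec$name == "dixon_simon") {
    W <- cbind(1, spec$X)
    p_beta <- ncol(spec$X)
    b <- numeric(ncol(W))
    b[1L] <- sum(y / s2) / sum(1 / s2)
    omega <- if (!is.null(fixed$omega)) fixed$omega else
      max(stats::sd(y), 1e-3)
    row <- 0L
    for (it in seq_len(n_iter)) {
      b <- draw_coefs(W, y, s2, c(1 / st2, rep(1 / omega^2, p_beta)))
      if (is.null(fixed$omega)) {
        up <- update_omega(omega, b[-1L], pr)
        omega <- up$omega
        n_eval_total <- n_eval_total + up$n_eval
        n_slice <- n_slice + 1L
      }
      if (it > n_burn && (it - n_burn - 1L) %% thin == 0L) {
        row <- row + 1L
        out[row, ] <- c(b, omega)
      }
    }
  } else if (spec$name == "regression_plus_shrinkage") {
    W <- cbind(1, spec$X)
    p <- ncol(W)
    phi <- numeric(G)
    b <- numeric(p)
    b[1L] <- sum(y / s2) / sum(1 / s2)
    omega <- if (!is.null(fixed$omega)) fixed$omega else
      max(stats::sd(y), 1e-3)
    row <- 0L
    for (it in seq_len(n_iter)) {
      b <- draw_coefs(W, y - phi, s2, rep(1 / st2, p))
      resid <- y - drop(W %*% b)
      v_phi <- 1 / (1 / s2 + 1 / omega^2)
      phi <- stats::rnorm(G, v_phi * resid / s2, sqrt(v_phi))
      if (is.null(fixed$omega)) {
        up <- update_omega(omega, phi, pr)
        omega <- up$omega
        n_eval_total <- n_eval_total + up$n_eval
        n_slice <- n_slice + 1L
      }
      if (it > n_burn && (it - n_burn - 1L) %% thin == 0L) {
        row <- row + 1L
        out[row, ] <- c(b, phi, omega)
      }
    }
  } else {  # extended_dixon_simon
    prefixes <- c("beta", "gamma", "delta")
    orders <- spec$orders
    W <- cbind(1, do.call(cbind, spec$X_orders[orders]))
    block_sizes <- vapply(spec$X_orders[orders], ncol, integer(1L))
    block_idx <- split(1L + seq_len(sum(block_sizes)),
                       rep(orders, block_sizes))
    omegas <- rep(max(stats::sd(y), 1e-3), length(orders))
    b <- numeric(ncol(W))
    b[1L] <- sum(y / s2) / sum(1 / s2)
    row <- 0L
    for (it in seq_len(n_iter)) {
      pp <- 1 / st2
      for (o in orders)
        pp <- c(pp, rep(1 / omegas[o]^2, block_sizes[o]))
      b <- draw_coefs(W, y, s2, pp)
      for (o in orders) {
        up <- update_omega(omegas[o], b[block_idx[[as.character(o)]]], pr)
        omegas[o] <- up$omega
        n_eval_total <- n_eval_total + up$n_eval
        n_slice <- n_slice + 1L
      }
      if (it > n_burn && (it - n_burn - 1L) %% thin == 0L) {
        row <- row + 1L
        out[row, ] <- c(b, omegas)
      }
    }
  }
  attr(out, "slice_evals_per_update") <-
    if (n_slice > 0L) n_eval_total / n_slice else NA_real_
  out
}

#' Fit a Bayesian subgroup model by MCMC
#'
#' Samples the posterior of a [make_model()] specification given
#' subgroup-level summary data, by Gibbs sampling: subgroup effects and
#' location coefficients are drawn from their normal full conditionals
#' (the models are conditionally linear-Gaussian), and each heterogeneity
#' scale `omega` is drawn by slice sampling on the log scale (with
#' Jacobian correction) against its half-normal or approximate Jeffreys
#' prior. The pooled, stratified and basic-regression models have exactly
#' Gaussian posteriors and are sampled directly.
#'
#' Chains are initialized deterministically (effects at `theta_hat`, the
#' overall effect at the precision-weighted mean, coefficients at zero,
#' scales at the SD of `theta_hat`, floored at 1e-3); per-chain RNG
#' substreams are derived from the master `seed`, so a rerun with the same
#' seed reproduces the draws exactly. Split-Rhat is reported per
#' parameter; the fit is flagged non-converged (returned, not an error)
#' when any Rhat exceeds 1.1.
#'
#' @param spec An [make_model()] object.
#' @param data A [subgroup_summary()].
#' @param n_iter Iterations per chain (including burn-in).
#' @param n_burn Burn-in iterations discarded per chain.
#' @param chains Number of chains (at least 1; 2+ needed for Rhat).
#' @param thin Thinning interval.
#' @param seed Master integer seed.
#' @param fixed Optional named list holding `tau` and/or `omega` fixed
#'   (supported by the models that have them); used for conjugate
#'   verification and degenerate-prior analyses.
#' @return An object of class `hte_fit`: `draws` (list of per-chain
#'   matrices, burn-in removed), `spec`, `data`, `rhat`, `converged`,
#'   `seed`, sampling settings and `sampler_info`.
#' @export
run_mcmc <- function(spec, data, n_iter = 5000L, n_burn = 2500L,
                     chains = 4L, thin = 1L, seed = 1L, fixed = list()) {
  stopifnot(inherits(spec, "hte_model"), inherits(data, "subgroup_summary"))
  if (data$frame$G != spec$G)
    stop("invalid spec: data and model disagree on the number of subgroups")
  if (n_iter <= n_burn) stop("invalid spec: n_iter must exceed n_burn")
  if (chains < 1L) stop("invalid spec: chains must be >= 1")
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  draws <- vector("list", chains)
  evals <- numeric(chains)
  for (ch in seq_len(chains)) {
    draws[[ch]] <- gibbs_chain(spec, data, n_iter, n_burn, thin,
                               chain_seeds[ch], fixed)
    evals[ch] <- attr(draws[[ch]], "slice_evals_per_update")
  }
  rhat <- split_rhat(draws)
  converged <- all(rhat <= 1.1, na.rm = TRUE)
  structure(list(draws = draws, spec = spec, data = data,
                 n_iter = n_iter, n_burn = n_burn, thin = thin,
                 chains = chains, seed = seed, rhat = rhat,
                 converged = converged,
                 sampler_info = list(
                   slice_evals_per_update = mean(evals, na.rm = TRUE))),
            class = "hte_fit")
}

#' @export
print.hte_fit <- function(x, ...) {
  cat("MCMC fit of '", x$spec$name, "': ", x$chains, " chain(s) x ",
      nrow(x$draws[[1L]]), " retained draws; max split-Rhat = ",
      format(max(x$rhat, na.rm = TRUE), digits = 4),
      if (x$converged) " (converged)" else " (NOT converged)", "\n",
      sep = "")
  invisible(x)
}

# split-Rhat per parameter over a list of chain matrices
split_rhat <- function(chain_list) {
  n <- nrow(chain_list[[1L]])
  half <- n %/% 2L
  halves <- list()
  for (m in chain_list) {
    halves[[length(halves) + 1L]] <- m[seq_len(half), , drop = FALSE]
    halves[[length(halves) + 1L]] <- m[seq(n - half + 1L, n), ,
                                       drop = FALSE]
  }
  p <- ncol(chain_list[[1L]])
  out <- numeric(p)
  for (j in seq_len(p)) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1L))
    vars <- vapply(halves, function(h) stats::var(h[, j]), numeric(1L))
    W <- mean(vars)
    B <- half * stats::var(means)
    if (!is.finite(W) || W <= 0) { out[j] <- 1; next }
    out[j] <- sqrt(((half - 1) / half * W + B / half) / W)
  }
  stats::setNames(out, colnames(chain_list[[1L]]))
}

#' Pooled posterior draws of the subgroup effects
#'
#' Applies the model's effect map to every retained draw and pools the
#' chains, yielding a draws-by-G matrix of `theta[g]` samples.
#'
#' @param fit An [run_mcmc()] fit.
#' @return Numeric matrix, one column per subgroup.
#' @export
theta_draws <- function(fit) {
  stopifnot(inherits(fit, "hte_fit"))
  pooled <- do.call(rbind, fit$draws)
  th <- model_theta_matrix(fit$spec, pooled)
  colnames(th) <- paste0("theta[", seq_len(fit$spec$G), "]")
  th
}

# pooled draws of a single named parameter
param_draws <- function(fit, name) {
  pooled <- do.call(rbind, fit$draws)
  if (!name %in% colnames(pooled))
    stop("unsupported model: no parameter '", name, "' in model '",
         fit$spec$name, "'")
  pooled[, name]
}

# Monte-Carlo standard error by batch means
mcse_batch <- function(x) {
  n <- length(x)
  b <- max(2L, floor(sqrt(n)))
  nb <- n %/% b
  if (nb < 2L) return(NA_real_)
  bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  stats::sd(bm) / sqrt(nb)
}

#' Summarize a posterior fit
#'
#' Moments and quantiles over pooled chains, for every model parameter and
#' for the G subgroup effects implied by the effect map, plus per-subgroup
#' posterior probabilities `P(theta[g] < c | y)` for user thresholds `c`.
#' Monte-Carlo standard errors of the means use batch means.
#'
#' @param fit An [run_mcmc()] fit.
#' @param thresholds Numeric vector of effect-scale thresholds `c`.
#' @return An object of class `hte_summary`: `params` and `effects`
#'   data.frames (mean, sd, 2.5/25/50/75/97.5 percent quantiles, MCSE;
#'   `effects` also carries subgroup labels), `prob_below` (G x
#'   thresholds matrix), `n_draws`.
#' @export
summarize_posterior <- function(fit, thresholds = numeric(0)) {
  stopifnot(inherits(fit, "hte_fit"))
  pooled <- do.call(rbind, fit$draws)
  if (nrow(pooled) < 1L) stop("invalid state: no retained draws")
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  summ <- function(m) {
    data.frame(
      mean = colMeans(m),
      sd = apply(m, 2L, stats::sd),
      t(apply(m, 2L, stats::quantile, probs = qs)),
      mcse = apply(m, 2L, mcse_batch),
      check.names = FALSE)
  }
  params <- summ(pooled)
  params <- cbind(parameter = colnames(pooled), params)
  params$rhat <- unname(fit$rhat)
  rownames(params) <- NULL
  th <- theta_draws(fit)
  effects <- summ(th)
  effects <- cbind(subgroup = fit$data$frame$labels, effects)
  rownames(effects) <- NULL
  prob_below <- NULL
  if (length(thresholds)) {
    prob_below <- sapply(thresholds, function(cc) colMeans(th < cc))
    prob_below <- matrix(prob_below, ncol = length(thresholds),
                         dimnames = list(fit$data$frame$labels,
                                         paste0("P(theta<", thresholds,
                                                ")")))
  }
  structure(list(params = params, effects = effects,
                 prob_below = prob_below, thresholds = thresholds,
                 n_draws = nrow(pooled), model = fit$spec$name),
            class = "hte_summary")
}

#' @export
print.hte_summary <- function(x, digits = 4, ...) {
  cat("posterior summary ('", x$model, "', ", x$n_draws, " draws)\n",
      sep = "")
  df <- x$effects
  df[-1L] <- lapply(df[-1L], round, digits = digits)
  print(df)
  if (!is.null(x$prob_below)) print(round(x$prob_below, digits))
  invisible(x)
}

#' Posterior expected shrinkage fractions
#'
#' For models with a heterogeneity scale `omega`, computes the posterior
#' mean of the shrinkage fraction `r(omega, s[g]) = omega^2 /
#' (omega^2 + s[g]^2)` per subgroup. Values near 0 mean the subgroup
#' estimate is pulled almost completely to the overall effect; values
#' near 1 mean essentially no pooling. Noisier subgroups (larger `s[g]`)
#' always have smaller `r`, i.e. are shrunk harder.
#'
#' @param fit An [run_mcmc()] fit of a model with an `omega` parameter
#'   (basic shrinkage, Dixon-Simon, regression plus shrinkage).
#' @param data A [subgroup_summary()]; defaults to the data the model was
#'   fitted to.
#' @param omega_param Name of the scale parameter (e.g. `"omega1"` to
#'   examine one order of the extended Dixon-Simon model).
#' @return Named numeric vector of length G with values in (0, 1).
#' @export
shrinkage_factors <- function(fit, data = fit$data, omega_param = "omega") {
  stopifnot(inherits(fit, "hte_fit"))
  if (!omega_param %in% fit$spec$param_names)
    stop("unsupported model: '", fit$spec$name,
         "' has no '", omega_param, "' parameter")
  om <- param_draws(fit, omega_param)
  r <- sapply(data$se, function(s) mean(om^2 / (om^2 + s^2)))
  stats::setNames(r, data$frame$labels)
}

#' Export draws as a long CSV
#'
#' One column per named parameter plus `chain` and `iter` columns.
#'
#' @param fit An [run_mcmc()] fit.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "hte_fit"))
  rows <- lapply(seq_along(fit$draws), function(ch) {
    m <- fit$draws[[ch]]
    data.frame(chain = ch, iter = seq_len(nrow(m)), m, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
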