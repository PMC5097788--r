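#' Deviance of a subgroup-effect vector
#'
#' The goodness-of-fit measure underlying the DIC for the normal sampling
#' model: `D(theta) = sum_g ((theta_hat[g] - theta[g]) / s[g])^2`.
#'
#' @param theta Numeric vector of length G.
#' @param data A [subgroup_summary()].
#' @return Nonnegative scalar; zero iff `theta` equals `theta_hat`.
#' @export
subgroup_deviance <- function(theta, data) {
  stopifnot(inherits(data, "subgroup_summary"))
  if (length(theta) != data$frame$G)
    stop("invalid spec: theta length ", length(theta),
         " does not match G = ", data$frame$G)
  sum(((data$theta_hat - theta) / data$se)^2)
}

#' Deviance information criterion of a fitted model
#'
#' Computes the posterior expected deviance `D_bar`, the deviance at the
#' posterior-mean effects `D(theta_bar)`, the effective number of
#' parameters `p_D = D_bar - D(theta_bar)`, and
#' `DIC = D_bar + p_D = 2 D_bar - D(theta_bar)`. Lower DIC is better;
#' differences below about 3-5 between models are not meaningful.
#'
#' @param fit An [run_mcmc()] fit.
#' @param data A [subgroup_summary()]; defaults to the fitted data.
#' @return An object of class `hte_dic` with `D_bar`, `D_at_mean`, `p_D`,
#'   `DIC`, `model`.
#' @export
dic <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "hte_fit"))
  th <- theta_draws(fit)
  if (nrow(th) < 1L) stop("invalid state: no retained draws")
  dev_draws <- colSums((t(th) - data$theta_hat)^2 / data$se^2)
  D_bar <- mean(dev_draws)
  D_at_mean <- subgroup_deviance(colMeans(th), data)
  p_D <- D_bar - D_at_mean
  structure(list(D_bar = D_bar, D_at_mean = D_at_mean, p_D = p_D,
                 DIC = D_bar + p_D, model = fit$spec$name),
            class = "hte_dic")
}

#' @export
print.hte_dic <- function(x, ...) {
  cat(sprintf("DIC ('%s'): D_bar = %.3f, p_D = %.3f, DIC = %.3f\n",
              x$model, x$D_bar, x$p_D, x$DIC))
  invisible(x)
}

#' DIC comparison table across fitted models
#'
#' @param fits Named list of [run_mcmc()] fits of the same data.
#' @param data A [subgroup_summary()]; defaults to the first fit's data.
#' @return A data.frame sorted by DIC with columns `model`, `D_bar`,
#'   `p_D`, `DIC`, `delta_DIC` and `assessment` (differences under 3
#'   flagged "not meaningful").
#' @export
dic_table <- function(fits, data = fits[[1L]]$data) {
  rows <- lapply(fits, function(f) {
    d <- dic(f, data)
    data.frame(model = d$model, D_bar = d$D_bar, p_D = d$p_D, DIC = d$DIC)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$DIC), , drop = FALSE]
  tab$delta_DIC <- tab$DIC - tab$DIC[1L]
  tab$assessment <- ifelse(tab$delta_DIC == 0, "best",
                           ifelse(tab$delta_DIC < 3,
                                  "not meaningful (< 3)",
                                  ifelse(tab$delta_DIC <= 5,
                                         "borderline (3-5)", "worse")))
  rownames(tab) <- NULL
  tab
}

#' Draws from the posterior predictive distribution
#'
#' Generates hypothetical replicate data sets from the fitted model: each
#' replicate takes one posterior draw of the subgroup effects
#' `theta[1..G]` and adds `Normal(0, s[g]^2)` sampling noise, mimicking
#' the assumed sampling model of the observed estimates.
#'
#' @param fit An [run_mcmc()] fit.
#' @param data A [subgroup_summary()]; defaults to the fitted data.
#' @param n_rep Number of replicates (at most the retained draws).
#' @param seed Integer seed.
#' @return Numeric matrix (`n_rep` x G) of replicated `theta_hat` vectors.
#' @export
posterior_predictive_draws <- function(fit, data = fit$data, n_rep = 1000L,
                                       seed = 1L) {
  stopifnot(inherits(fit, "hte_fit"))
  th <- theta_draws(fit)
  if (n_rep > nrow(th))
    stop("invalid spec: n_rep (", n_rep, ") exceeds available draws (",
         nrow(th), ")")
  set.seed(seed)
  take <- sample.int(nrow(th), n_rep)
  G <- ncol(th)
  reps <- th[take, , drop = FALSE] +
    matrix(stats::rnorm(n_rep * G, 0, rep(data$se, each = n_rep)),
           n_rep, G)
  colnames(reps) <- colnames(th)
  reps
}

ppc_stat_funs <- list(median = stats::median, sd = stats::sd,
                      min = min, max = max)

#' Posterior predictive checks with scalar test statistics
#'
#' Applies each test statistic `T` across the G-vector of every replicate
#' and compares with the observed value `T(theta_hat)`. The posterior
#' predictive p-value is `P(T(y_rep) >= T(y) | y)`, ties counted in;
#' statistics with p-value below 0.05 or above 0.95 are flagged
#' discrepant.
#'
#' @param replicates Matrix from [posterior_predictive_draws()].
#' @param observed A [subgroup_summary()].
#' @param statistics Character vector among `"median"`, `"sd"`, `"min"`,
#'   `"max"`.
#' @return An object of class `hte_ppc`: data.frame with the observed
#'   value, replicate mean and 2.5/97.5 percent band, p-value and
#'   discrepancy flag per statistic, plus the replicate count.
#' @export
ppc_statistics <- function(replicates, observed,
                           statistics = c("median", "sd", "min", "max")) {
  stopifnot(inherits(observed, "subgroup_summary"))
  if (nrow(replicates) < 100L)
    stop("invalid spec: at least 100 replicates required")
  unknown <- setdiff(statistics, names(ppc_stat_funs))
  if (length(unknown))
    stop("invalid spec: unknown statistic(s): ",
         paste(unknown, collapse = ", "))
  rows <- lapply(statistics, function(st) {
    f <- ppc_stat_funs[[st]]
    t_rep <- apply(replicates, 1L, f)
    t_obs <- f(observed$theta_hat)
    p <- mean(t_rep >= t_obs)
    data.frame(statistic = st, observed = t_obs,
               rep_mean = mean(t_rep),
               rep_q2.5 = unname(stats::quantile(t_rep, 0.025)),
               rep_q97.5 = unname(stats::quantile(t_rep, 0.975)),
               p_value = p, discrepant = p < 0.05 | p > 0.95)
  })
  structure(list(table = do.call(rbind, rows), n_rep = nrow(replicates)),
            class = "hte_ppc")
}

#' @export
print.hte_ppc <- function(x, digits = 4, ...) {
  cat("posterior predictive checks (", x$n_rep, " replicates)\n", sep = "")
  df <- x$table
  df[-c(1L, 7L)] <- lapply(df[-c(1L, 7L)], round, digits = digits)
  print(df)
  invisible(x)
}

#' Prior-sensitivity grid
#'
#' Refits the same model structure on the same data under a grid of priors
#' for the heterogeneity scale (e.g. several half-normal scales and an
#' approximate Jeffreys prior) and tabulates posterior means and credible
#' intervals of the subgroup effects side by side. Every cell reuses the
#' same master seed so differences between cells reflect the priors, not
#' Monte-Carlo noise. Cells that fail the split-Rhat check are flagged but
#' still returned.
#'
#' @param name Model name (see [make_model()]).
#' @param data A [subgroup_summary()].
#' @param prior_grid List of at least two [prior_spec()] objects.
#' @param n_iter,n_burn,chains,seed MCMC settings shared by all cells.
#' @return An object of class `hte_sensitivity`: `cells` (list of
#'   per-prior lists with `prior`, `summary`, `converged`),
#'   `effects_table` (long data.frame of per-subgroup posterior mean and
#'   95 percent interval per prior), and `max_mean_change` (largest
#'   absolute change of any subgroup posterior mean across cells).
#' @export
sensitivity_grid <- function(name, data, prior_grid, n_iter = 5000L,
                             n_burn = 2500L, chains = 4L, seed = 1L) {
  stopifnot(inherits(data, "subgroup_summary"))
  if (length(prior_grid) < 2L)
    stop("invalid spec: prior grid needs at least 2 cells")
  cells <- lapply(prior_grid, function(pr) {
    spec <- make_model(name, data$frame, pr)
    fit <- run_mcmc(spec, data, n_iter = n_iter, n_burn = n_burn,
                    chains = chains, seed = seed)
    list(prior = pr, summary = summarize_posterior(fit),
         converged = fit$converged)
  })
  tabs <- lapply(cells, function(cl) {
    ef <- cl$summary$effects
    data.frame(prior = cl$prior$label, subgroup = ef$subgroup,
               mean = ef$mean, lower = ef[["2.5%"]],
               upper = ef[["97.5%"]], converged = cl$converged)
  })
  effects_table <- do.call(rbind, tabs)
  means <- sapply(cells, function(cl) cl$summary$effects$mean)
  max_change <- max(apply(means, 1L, function(r) diff(range(r))))
  structure(list(cells = cells, effects_table = effects_table,
                 max_mean_change = max_change, model = name),
            class = "hte_sensitivity")
}

#' @export
print.hte_sensitivity <- function(x, digits = 4, ...) {
  cat("prior-sensitivity grid ('", x$model, "', ",
      length(x$cells), " cells); max posterior-mean change = ",
      format(x$max_mean_change, digits = digits), "\n", sep = "")
  for (cl in x$cells)
    cat(" -", cl$prior$label,
        if (!cl$converged) "[flagged: non-converged]" else "", "\n")
  invisible(x)
}
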