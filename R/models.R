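#' Interaction design matrix over subgroups
#'
#' Builds the subgroup-by-coefficient indicator matrix used by the
#' regression models. Order 1 has one column per non-reference level of
#' each covariate (`X[g, jk] = 1` when subgroup g carries level k+1 of
#' covariate j), giving `sum_j (K_j - 1)` columns. Order 2 contains all
#' pairwise products of order-1 columns taken from distinct covariates;
#' order 3 all triple products from three distinct covariates. Rows follow
#' the frame's subgroup ordering.
#'
#' @param frame A [build_subgroup_frame()] object.
#' @param order Interaction order: 1, 2 or 3 (at most the number of
#'   covariates).
#' @return A numeric matrix with `frame$G` rows and named columns.
#' @examples
#' frame <- build_subgroup_frame(list(
#'   covariate_spec("gender", c("F", "M")),
#'   covariate_spec("age", c("<=65", ">65"))
#' ))
#' design_matrix(frame, 1)
#' @export
design_matrix <- function(frame, order = 1L) {
  stopifnot(inherits(frame, "subgroup_frame"))
  J <- length(frame$covariates)
  if (!order %in% 1:3) stop("invalid spec: order must be 1, 2 or 3")
  if (order > J)
    stop("invalid spec: order ", order, " exceeds the number of covariates (",
         J, ")")
  # per-covariate groups of order-1 indicator columns
  groups <- lapply(frame$covariates, function(cv) {
    cols <- sapply(cv$levels[-1L], function(lvl)
      as.numeric(frame$subgroups[[cv$name]] == lvl))
    cols <- matrix(cols, nrow = frame$G)
    colnames(cols) <- paste0(cv$name, "=", cv$levels[-1L])
    cols
  })
  if (order == 1L) {
    out <- do.call(cbind, groups)
    return(out)
  }
  combos <- utils::combn(J, order, simplify = FALSE)
  cols <- list()
  for (cb in combos) {
    grids <- lapply(cb, function(j) seq_len(ncol(groups[[j]])))
    idx <- expand.grid(rev(grids))[, rev(seq_along(cb)), drop = FALSE]
    for (r in seq_len(nrow(idx))) {
      prod_col <- rep(1, frame$G)
      nm <- character(0)
      for (m in seq_along(cb)) {
        g <- groups[[cb[m]]]
        prod_col <- prod_col * g[, idx[r, m]]
        nm <- c(nm, colnames(g)[idx[r, m]])
      }
      cols[[paste(nm, collapse = ":")]] <- prod_col
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  out
}

model_names <- c("pooled", "stratified", "basic_shrinkage",
                 "basic_regression", "regression_plus_shrinkage",
                 "dixon_simon", "extended_dixon_simon")

#' Specify one of the seven Bayesian subgroup models
#'
#' Constructs the declarative specification (parameter layout, design
#' matrices, priors) of a Bayesian model for subgroup treatment effects
#' `theta[g]`, all sharing the sampling model
#' `theta_hat[g] | theta[g] ~ Normal(theta[g], se[g]^2)`:
#'
#' * `pooled` - a single common effect: `theta[g] = tau`,
#'   `tau ~ N(0, sigma_tau2)`.
#' * `stratified` - independent effects: `theta[g] ~ N(0, sigma_tau2)`,
#'   no pooling.
#' * `basic_shrinkage` - exchangeable hierarchy
#'   `theta[g] ~ N(tau, omega^2)`, `tau ~ N(0, sigma_tau2)`, `omega` from
#'   the prior in `priors` (half-normal by default).
#' * `basic_regression` - `theta = tau + X beta` with order-1 interaction
#'   design `X`, each coefficient with an independent diffuse
#'   `N(0, sigma_tau2)` prior (no shared variance component).
#' * `regression_plus_shrinkage` - `theta = tau + X beta + phi` adding
#'   exchangeable subgroup deviations `phi[g] ~ N(0, omega^2)`.
#' * `dixon_simon` - `theta = tau + X beta` with the coefficients drawn
#'   from a common distribution `beta ~ N(0, omega^2)`, shrinking the
#'   interaction effects toward zero.
#' * `extended_dixon_simon` - adds second- and third-order interaction
#'   columns, with a separate heterogeneity scale per interaction order
#'   (`omega1, omega2, omega3`), each with an independent prior.
#'   Interactions beyond order 3 are not modeled.
#'
#' @param name Model name (see above).
#' @param frame A [build_subgroup_frame()] object.
#' @param priors A [prior_spec()].
#' @return An object of class `hte_model` with elements `name`, `frame`,
#'   `priors`, `layout` (named index slices into the parameter vector),
#'   `param_names`, `n_params`, and design matrices where applicable.
#' @export
make_model <- function(name, frame, priors = prior_spec()) {
  stopifnot(inherits(frame, "subgroup_frame"),
            inherits(priors, "prior_spec"))
  if (!name %in% model_names)
    stop("invalid spec: unknown model '", name, "'; choose one of: ",
         paste(model_names, collapse = ", "))
  G <- frame$G
  J <- length(frame$covariates)
  theta_names <- paste0("theta[", seq_len(G), "]")
  spec <- list(name = name, frame = frame, G = G, priors = priors)
  if (name == "pooled") {
    spec$param_names <- "tau"
    spec$layout <- list(tau = 1L)
  } else if (name == "stratified") {
    spec$param_names <- theta_names
    spec$layout <- list(theta = seq_len(G))
  } else if (name == "basic_shrinkage") {
    spec$param_names <- c(theta_names, "tau", "omega")
    spec$layout <- list(theta = seq_len(G), tau = G + 1L, omega = G + 2L)
  } else if (name %in% c("basic_regression", "dixon_simon",
                         "regression_plus_shrinkage")) {
    X <- design_matrix(frame, 1L)
    p <- ncol(X)
    spec$X <- X
    beta_names <- paste0("beta[", colnames(X), "]")
    if (name == "basic_regression") {
      spec$param_names <- c("tau", beta_names)
      spec$layout <- list(tau = 1L, beta = 1L + seq_len(p))
    } else if (name == "dixon_simon") {
      spec$param_names <- c("tau", beta_names, "omega")
      spec$layout <- list(tau = 1L, beta = 1L + seq_len(p),
                          omega = p + 2L)
    } else {
      spec$param_names <- c("tau", beta_names,
                            paste0("phi[", seq_len(G), "]"), "omega")
      spec$layout <- list(tau = 1L, beta = 1L + seq_len(p),
                          phi = 1L + p + seq_len(G), omega = p + G + 2L)
    }
  } else {  # extended_dixon_simon
    orders <- seq_len(min(J, 3L))
    Xs <- lapply(orders, function(o) design_matrix(frame, o))
    names(Xs) <- paste0("order", orders)
    spec$X_orders <- Xs
    coef_prefix <- c("beta", "gamma", "delta")
    nm <- "tau"
    layout <- list(tau = 1L)
    pos <- 1L
    for (o in orders) {
      p_o <- ncol(Xs[[o]])
      nm <- c(nm, paste0(coef_prefix[o], "[", colnames(Xs[[o]]), "]"))
      layout[[coef_prefix[o]]] <- pos + seq_len(p_o)
      pos <- pos + p_o
    }
    for (o in orders) {
      nm <- c(nm, paste0("omega", o))
      layout[[paste0("omega", o)]] <- pos + 1L
      pos <- pos + 1L
    }
    spec$param_names <- nm
    spec$layout <- layout
    spec$orders <- orders
  }
  spec$n_params <- length(spec$param_names)
  structure(spec, class = "hte_model")
}

#' @export
print.hte_model <- function(x, ...) {
  cat("Bayesian subgroup model '", x$name, "': ", x$n_params,
      " parameters, G = ", x$G, "\n", sep = "")
  print(x$priors)
  invisible(x)
}

#' Map a parameter vector to the subgroup effects
#'
#' The effect map of a model: returns the G-vector `theta` implied by a
#' full parameter vector. Linear in the parameters for the regression
#' models; the identity on the `theta` (plus `phi`) slices otherwise.
#'
#' @param spec An [make_model()] object.
#' @param params Numeric vector matching `spec$param_names`.
#' @return Numeric vector of length `spec$G`.
#' @export
model_effects <- function(spec, params) {
  stopifnot(inherits(spec, "hte_model"))
  if (length(params) != spec$n_params)
    stop("invalid spec: parameter vector length ", length(params),
         " does not match layout (", spec$n_params, ")")
  lay <- spec$layout
  switch(spec$name,
    pooled = rep(params[lay$tau], spec$G),
    stratified = params[lay$theta],
    basic_shrinkage = params[lay$theta],
    basic_regression = params[lay$tau] + drop(spec$X %*% params[lay$beta]),
    dixon_simon = params[lay$tau] + drop(spec$X %*% params[lay$beta]),
    regression_plus_shrinkage = params[lay$tau] +
      drop(spec$X %*% params[lay$beta]) + params[lay$phi],
    extended_dixon_simon = {
      th <- rep(params[lay$tau], spec$G)
      prefixes <- c("beta", "gamma", "delta")
      for (o in spec$orders)
        th <- th + drop(spec$X_orders[[o]] %*% params[lay[[prefixes[o]]]])
      th
    })
}

# theta for a whole draws matrix (rows = iterations); returns iter x G
model_theta_matrix <- function(spec, draws) {
  lay <- spec$layout
  switch(spec$name,
    pooled = matrix(draws[, lay$tau], nrow(draws), spec$G),
    stratified = draws[, lay$theta, drop = FALSE],
    basic_shrinkage = draws[, lay$theta, drop = FALSE],
    basic_regression = draws[, lay$tau] +
      draws[, lay$beta, drop = FALSE] %*% t(spec$X),
    dixon_simon = draws[, lay$tau] +
      draws[, lay$beta, drop = FALSE] %*% t(spec$X),
    regression_plus_shrinkage = draws[, lay$tau] +
      draws[, lay$beta, drop = FALSE] %*% t(spec$X) +
      draws[, lay$phi, drop = FALSE],
    extended_dixon_simon = {
      th <- matrix(draws[, lay$tau], nrow(draws), spec$G)
      prefixes <- c("beta", "gamma", "delta")
      for (o in spec$orders)
        th <- th + draws[, lay[[prefixes[o]]], drop = FALSE] %*%
          t(spec$X_orders[[o]])
      th
    })
}

#' Joint log posterior of a model
#'
#' Evaluates, up to an additive constant, the log posterior
#' `sum_g log N(theta_hat[g] | theta[g](params), se[g]^2) + log prior`.
#' Returns `-Inf` for parameter values outside the support (nonpositive
#' heterogeneity scales).
#'
#' @param spec An [make_model()] object.
#' @param params Numeric vector matching the model's layout.
#' @param data A [subgroup_summary()].
#' @return Scalar log posterior density (unnormalized).
#' @export
log_posterior <- function(spec, params, data) {
  stopifnot(inherits(spec, "hte_model"), inherits(data, "subgroup_summary"))
  if (length(params) != spec$n_params)
    stop("invalid spec: parameter vector length ", length(params),
         " does not match layout (", spec$n_params, ")")
  lay <- spec$layout
  pr <- spec$priors
  sd_tau <- sqrt(pr$sigma_tau2)
  lp <- 0
  omega_slices <- grep("^omega", names(lay), value = TRUE)
  for (os in omega_slices) {
    if (params[lay[[os]]] <= 0) return(-Inf)
    lp <- lp + omega_logprior(params[lay[[os]]], pr)
  }
  if (!is.finite(lp)) return(-Inf)
  theta <- model_effects(spec, params)
  lp <- lp + sum(stats::dnorm(data$theta_hat, theta, data$se, log = TRUE))
  lp <- lp + switch(spec$name,
    pooled = stats::dnorm(params[lay$tau], 0, sd_tau, log = TRUE),
    stratified = sum(stats::dnorm(params[lay$theta], 0, sd_tau, log = TRUE)),
    basic_shrinkage = {
      om <- params[lay$omega]
      sum(stats::dnorm(params[lay$theta], params[lay$tau], om, log = TRUE)) +
        stats::dnorm(params[lay$tau], 0, sd_tau, log = TRUE)
    },
    basic_regression = stats::dnorm(params[lay$tau], 0, sd_tau, log = TRUE) +
      sum(stats::dnorm(params[lay$beta], 0, sd_tau, log = TRUE)),
    dixon_simon = stats::dnorm(params[lay$tau], 0, sd_tau, log = TRUE) +
      sum(stats::dnorm(params[lay$beta], 0, params[lay$omega], log = TRUE)),
    regression_plus_shrinkage =
      stats::dnorm(params[lay$tau], 0, sd_tau, log = TRUE) +
      sum(stats::dnorm(params[lay$beta], 0, sd_tau, log = TRUE)) +
      sum(stats::dnorm(params[lay$phi], 0, params[lay$omega], log = TRUE)),
    extended_dixon_simon = {
      out <- stats::dnorm(params[lay$tau], 0, sd_tau, log = TRUE)
      prefixes <- c("beta", "gamma", "delta")
      for (o in spec$orders)
        out <- out + sum(stats::dnorm(params[lay[[prefixes[o]]]], 0,
                                      params[lay[[paste0("omega", o)]]],
                                      log = TRUE))
      out
    })
  lp
}
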