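test_that("order-1 design matrices count subgroups per level", {
  X <- design_matrix(frame_223(), 1)
  expect_equal(dim(X), c(12L, 4L))
  expect_equal(unname(colSums(X)), c(6, 6, 4, 4))
  # brute-force oracle: indicator of carrying the non-reference level
  frame <- frame_223()
  for (j in seq_along(frame$covariates)) {
    cv <- frame$covariates[[j]]
    for (k in seq_along(cv$levels)[-1]) {
      col <- paste0(cv$name, "=", cv$levels[k])
      expect_equal(unname(X[, col]),
                   as.numeric(frame$subgroups[[cv$name]] == cv$levels[k]))
    }
  }
  expect_error(design_matrix(frame, 4), "order")
})

test_that("higher-order designs are products of distinct covariate columns", {
  frame <- frame_22()
  X2 <- design_matrix(frame, 2)
  expect_equal(ncol(X2), 1L)
  both <- frame$subgroups$gender == "F" & frame$subgroups$age == "old"
  expect_equal(unname(X2[, 1]), as.numeric(both))

  X3 <- design_matrix(frame_222(), 3)
  expect_equal(ncol(X3), 1L)
  expect_equal(sum(X3), 1)  # only the all-non-reference subgroup
})

test_that("the worked two-covariate effect decomposition holds", {
  # male and young are the reference levels, so female carries beta[gender=F]
  frame <- frame_22()
  spec <- make_model("dixon_simon", frame)
  tau <- -0.25; b_f <- 0.3; b_old <- -0.1
  params <- numeric(spec$n_params)
  params[spec$layout$tau] <- tau
  params[spec$layout$beta] <- c(b_f, b_old)
  params[spec$layout$omega] <- 1
  th <- model_effects(spec, params)
  g_fy <- which(frame$subgroups$gender == "F" & frame$subgroups$age ==
                  "young")
  g_fo <- which(frame$subgroups$gender == "F" & frame$subgroups$age ==
                  "old")
  expect_equal(th[g_fy], tau + b_f)
  expect_equal(th[g_fo], tau + b_f + b_old)
})

test_that("parameter layouts match each model's structure", {
  frame <- frame_223()
  bs <- make_model("basic_shrinkage", frame)
  expect_equal(bs$n_params, 14L)  # 12 theta + tau + omega

  eds <- make_model("extended_dixon_simon", frame_222())
  expect_equal(length(eds$layout$beta), 3L)
  expect_equal(length(eds$layout$gamma), 3L)
  expect_equal(length(eds$layout$delta), 1L)
  # 7 = 2^3 - 1 coefficients plus tau and three scales
  expect_equal(eds$n_params, 1L + 7L + 3L)
  expect_true(all(c("omega1", "omega2", "omega3") %in% eds$param_names))

  pooled <- make_model("pooled", frame)
  expect_equal(model_effects(pooled, 0.4), rep(0.4, 12))

  expect_error(make_model("fancy", frame), "unknown model")
})

test_that("every slice of the layout covers the parameter vector once", {
  for (nm in c("pooled", "stratified", "basic_shrinkage",
               "basic_regression", "regression_plus_shrinkage",
               "dixon_simon", "extended_dixon_simon")) {
    spec <- make_model(nm, frame_222())
    idx <- sort(unlist(spec$layout))
    expect_equal(unname(idx), seq_len(spec$n_params), info = nm)
  }
})

test_that("regression effect maps equal explicit indicator sums", {
  frame <- frame_223()
  set.seed(44)
  for (nm in c("basic_regression", "dixon_simon")) {
    spec <- make_model(nm, frame)
    params <- stats::rnorm(spec$n_params)
    if (!is.null(spec$layout$omega)) params[spec$layout$omega] <- 0.5
    th <- model_effects(spec, params)
    # oracle: loop over subgroups and covariate levels
    beta <- params[spec$layout$beta]
    names(beta) <- colnames(spec$X)
    for (g in seq_len(frame$G)) {
      expected <- params[spec$layout$tau]
      for (cv in frame$covariates) {
        lvl <- frame$subgroups[[cv$name]][g]
        if (lvl != cv$levels[1])
          expected <- expected + beta[paste0(cv$name, "=", lvl)]
      }
      expect_equal(th[g], unname(expected), info = paste(nm, g))
    }
  }
})

test_that("extended model adds interaction terms order by order", {
  frame <- frame_222()
  spec <- make_model("extended_dixon_simon", frame)
  set.seed(45)
  params <- stats::rnorm(spec$n_params)
  params[unlist(spec$layout[c("omega1", "omega2", "omega3")])] <- 1
  th <- model_effects(spec, params)
  X1 <- design_matrix(frame, 1); X2 <- design_matrix(frame, 2)
  X3 <- design_matrix(frame, 3)
  manual <- params[spec$layout$tau] +
    drop(X1 %*% params[spec$layout$beta]) +
    drop(X2 %*% params[spec$layout$gamma]) +
    drop(X3 %*% params[spec$layout$delta])
  expect_equal(th, manual)
})

test_that("log posterior equals a term-by-term oracle", {
  frame <- frame_22()
  sim <- simulate_summary_data(frame, tau = -0.2, omega = 0.3,
                               se_profile = 0.2, seed = 50)
  data <- sim$summary
  pr <- prior_spec(sigma_tau2 = 100, sigma_omega2 = 4)
  set.seed(51)

  spec <- make_model("basic_shrinkage", frame, pr)
  params <- c(stats::rnorm(4), -0.1, 0.4)  # theta, tau, omega
  lp <- log_posterior(spec, params, data)
  oracle <- sum(stats::dnorm(data$theta_hat, params[1:4], data$se,
                             log = TRUE)) +
    sum(stats::dnorm(params[1:4], params[5], params[6], log = TRUE)) +
    stats::dnorm(params[5], 0, 10, log = TRUE) +
    log(2) + stats::dnorm(params[6], 0, 2, log = TRUE)
  expect_equal(lp, oracle, tolerance = 1e-12)

  spec2 <- make_model("dixon_simon", frame, pr)
  params2 <- c(-0.2, 0.25, -0.15, 0.3)  # tau, beta x2, omega
  th2 <- model_effects(spec2, params2)
  oracle2 <- sum(stats::dnorm(data$theta_hat, th2, data$se, log = TRUE)) +
    stats::dnorm(params2[1], 0, 10, log = TRUE) +
    sum(stats::dnorm(params2[2:3], 0, params2[4], log = TRUE)) +
    log(2) + stats::dnorm(params2[4], 0, 2, log = TRUE)
  expect_equal(log_posterior(spec2, params2, data), oracle2,
               tolerance = 1e-12)

  # out-of-support heterogeneity scale
  expect_identical(log_posterior(spec2, c(params2[1:3], -1), data), -Inf)
  expect_error(log_posterior(spec2, 1:3, data), "layout")
})

test_that("likelihood term is invariant to joint translation", {
  frame <- frame_22()
  sim <- simulate_summary_data(frame, tau = 0, omega = 0.3,
                               se_profile = 0.25, seed = 52)
  data <- sim$summary
  spec <- make_model("stratified", frame,
                     prior_spec(sigma_tau2 = 1e12))
  theta <- c(0.1, -0.2, 0.3, 0)
  shift <- 0.7
  data_shift <- subgroup_summary(frame, data$theta_hat + shift, data$se)
  lp1 <- log_posterior(spec, theta, data)
  lp2 <- log_posterior(spec, theta + shift, data_shift)
  # prior nearly flat, so the difference is the (tiny) prior change
  expect_equal(lp1, lp2, tolerance = 1e-6)
})

test_that("Dixon-Simon with one binary covariate matches basic shrinkage", {
  # on G = 2 the two models share the likelihood: theta = (tau, tau + beta);
  # log-posterior surfaces over (tau, beta) differ by an omega-only constant
  frame <- build_subgroup_frame(list(covariate_spec("v", c("A", "B"))))
  data <- subgroup_summary(frame, c(-0.5, 0.1), c(0.2, 0.3))
  pr <- prior_spec(sigma_tau2 = 50, sigma_omega2 = 1)
  ds <- make_model("dixon_simon", frame, pr)
  bs <- make_model("basic_shrinkage", frame, pr)
  omega <- 0.6
  grid <- expand.grid(tau = seq(-1, 1, by = 0.25),
                      beta = seq(-1, 1, by = 0.25))
  diffs <- apply(grid, 1, function(r) {
    log_posterior(ds, c(r["tau"], r["beta"], omega), data) -
      log_posterior(bs, c(r["tau"], r["tau"] + r["beta"], r["tau"], omega),
                    data)
  })
  expect_lt(diff(range(diffs)), 1e-10)
})
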