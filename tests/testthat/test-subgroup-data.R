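test_that("crossed covariates enumerate the full set of subgroups", {
  expect_equal(frame_223()$G, 12L)

  single <- build_subgroup_frame(list(covariate_spec("v", c("A", "B"))))
  expect_equal(single$G, 2L)
  expect_equal(single$subgroups$v, c("A", "B"))

  # brute-force cross-product count for arbitrary level vectors
  lvls <- list(c("A", "B"), c("x", "y", "z", "w"))
  frame <- build_subgroup_frame(list(covariate_spec("u", lvls[[1]]),
                                     covariate_spec("v", lvls[[2]])))
  expect_equal(frame$G, 8L)
  brute <- expand.grid(lvls[[2]], lvls[[1]], stringsAsFactors = FALSE)
  expect_equal(frame$G, nrow(unique(brute)))

  # deterministic lexicographic ordering: first covariate slowest
  expect_equal(frame$subgroups$u, rep(c("A", "B"), each = 4))
  expect_equal(frame$subgroups$v, rep(c("x", "y", "z", "w"), 2))
})

test_that("invalid covariate declarations are rejected", {
  expect_error(covariate_spec("v", "only"), "at least 2 levels")
  expect_error(covariate_spec("v", c("a", "a")), "duplicate")
  expect_error(build_subgroup_frame(list(covariate_spec("v", c("a", "b")),
                                         covariate_spec("v", c("x", "y")))),
               "duplicate covariate names")
  expect_error(build_subgroup_frame(list()), "at least one")
})

test_that("continuous summaries follow the two-sample formulas", {
  frame <- build_subgroup_frame(list(covariate_spec("v", c("A", "B"))))
  df <- data.frame(
    outcome = c(1, 3, 0, 2, 0, 2, 0, 2),
    treatment = c(1, 1, 0, 0, 1, 1, 0, 0),
    v = rep(c("A", "B"), each = 4))
  tab <- subject_table(df, "continuous", frame$covariates)
  s <- compute_subgroup_summaries(tab)
  # pooled two-sample oracle: sp2 = 2, se = sqrt(2 * (1/2 + 1/2))
  expect_equal(s$theta_hat[1], 1.0)
  expect_equal(s$se[1], sqrt(2))
  # zero-difference arm means
  expect_equal(s$theta_hat[2], 0.0)
  expect_equal(s$effect_scale, "mean_diff")
})

test_that("binary summaries give the log-odds ratio and its Woolf SE", {
  frame <- build_subgroup_frame(list(covariate_spec("v", c("A", "B"))))
  mk <- function(a, b, c_, d) {
    data.frame(outcome = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)),
               treatment = c(rep(1, a + b), rep(0, c_ + d)))
  }
  df <- rbind(cbind(mk(10, 10, 10, 10), v = "A"),
              cbind(mk(12, 4, 6, 8), v = "B"))
  s <- compute_subgroup_summaries(subject_table(df, "binary",
                                                frame$covariates))
  expect_equal(s$theta_hat[1], 0)
  expect_equal(s$se[1], sqrt(4 / 10))
  expect_equal(s$theta_hat[2], log(12 * 8 / (4 * 6)))
  expect_equal(s$se[2], sqrt(1 / 12 + 1 / 4 + 1 / 6 + 1 / 8))
  # zero cell raises rather than silently continuity-correcting
  df_zero <- rbind(cbind(mk(5, 0, 3, 3), v = "A"),
                   cbind(mk(3, 3, 3, 3), v = "B"))
  expect_error(compute_subgroup_summaries(
    subject_table(df_zero, "binary", frame$covariates)), "zero cell")
})

test_that("survival summaries reproduce the closed-form toy log-HR", {
  frame <- build_subgroup_frame(list(covariate_spec("v", c("A", "B"))))
  df <- data.frame(time = c(1, 2, 3, 1, 2, 3),
                   event = 1L,
                   treatment = c(1, 0, 1, 1, 0, 1),
                   v = rep(c("A", "B"), each = 3))
  s <- compute_subgroup_summaries(subject_table(df, "survival",
                                                frame$covariates))
  # score equation solution: exp(beta) = 1/sqrt(2)
  expect_equal(s$theta_hat[1], -log(2) / 2, tolerance = 1e-6)
  expect_equal(s$effect_scale, "log_hr")
})

test_that("estimability problems name the offending subgroup", {
  frame <- build_subgroup_frame(list(covariate_spec("v", c("A", "B"))))
  df <- data.frame(outcome = c(1, 2, 3, 4, 5, 6),
                   treatment = c(1, 1, 0, 0, 1, 1),
                   v = c("A", "A", "A", "A", "B", "B"))
  expect_error(compute_subgroup_summaries(
    subject_table(df, "continuous", frame$covariates)), "v=B")
})

test_that("summary-data generator honors its degenerate and seeded cases", {
  frame <- frame_223()
  sim0 <- simulate_summary_data(frame, tau = -0.3, omega = 0, se_profile = 0.1,
                                seed = 5)
  expect_equal(sim0$true_theta, rep(-0.3, 12))

  a <- simulate_summary_data(frame, tau = -0.3, omega = 0.2,
                             se_profile = 0.15, seed = 11)
  b <- simulate_summary_data(frame, tau = -0.3, omega = 0.2,
                             se_profile = 0.15, seed = 11)
  expect_identical(a$summary$theta_hat, b$summary$theta_hat)
  expect_identical(a$true_theta, b$true_theta)

  expect_error(simulate_summary_data(frame, 0, 0.1, se_profile = rep(1, 5),
                                     seed = 1), "se_profile length")
  expect_error(simulate_summary_data(frame, 0, -0.1, se_profile = 0.1,
                                     seed = 1), "omega")
})

test_that("summary-data generator matches its marginal moments at scale", {
  lv <- covariate_spec("g", as.character(seq_len(5000)))
  frame <- build_subgroup_frame(list(lv))
  sim <- simulate_summary_data(frame, tau = 0, omega = 1, se_profile = 0.01,
                               seed = 42)
  th <- sim$summary$theta_hat
  # marginal sd of theta_hat is sqrt(1 + 0.0001)
  expect_lt(abs(mean(th)), 3 * sd(th) / sqrt(5000))
  expect_lt(abs(sd(th) - sqrt(1 + 1e-4)) / sqrt(1 + 1e-4), 0.05)
})

test_that("subject-data generator respects arm structure and censoring", {
  frame <- frame_22()
  tiny <- simulate_subject_data(frame, effects = 0, outcome_kind =
                                  "continuous", n_per_arm = 1, seed = 2)
  expect_equal(nrow(tiny$data), 2L * frame$G)

  surv <- simulate_subject_data(frame, effects = -0.5, "survival",
                                n_per_arm = 30, censor_rate = 0, seed = 3)
  expect_true(all(surv$data$event == 1L))
  expect_true(all(surv$data$time > 0))

  cens <- simulate_subject_data(frame, effects = -0.5, "survival",
                                n_per_arm = 500, censor_rate = 0.3, seed = 3)
  expect_equal(mean(cens$data$event == 0L), 0.3, tolerance = 0.05)

  expect_error(simulate_subject_data(frame, 0, "survival", 10,
                                     censor_rate = 1, seed = 1),
               "censor_rate")
})

test_that("null subject data yield estimates consistent with zero", {
  frame <- frame_22()
  tab <- simulate_subject_data(frame, effects = 0, "continuous",
                               n_per_arm = 400, seed = 9)
  s <- compute_subgroup_summaries(tab)
  expect_gte(mean(abs(s$theta_hat) <= 4 * s$se), 0.95)
})

test_that("large-sample estimates recover the generating effects", {
  frame <- build_subgroup_frame(list(covariate_spec("v", c("A", "B"))))
  eff <- c(-0.4, 0.3)
  tab <- simulate_subject_data(frame, eff, "continuous", n_per_arm = 1e4,
                               seed = 21)
  s <- compute_subgroup_summaries(tab)
  expect_true(all(abs(s$theta_hat - eff) <= 3 * s$se))
})

test_that("summary tables round-trip through CSV exactly", {
  sim <- simulate_summary_data(frame_223(), tau = -0.3, omega = 0.2,
                               se_profile = 0.17, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_table(sim$summary, path)
  back <- read_summary_table(path, effect_scale = "log_hr")
  expect_identical(back$theta_hat, sim$summary$theta_hat)
  expect_identical(back$se, sim$summary$se)
  expect_equal(back$frame$G, 12L)
})

test_that("summary table validation names the offending column or row", {
  s <- fixture_summary()
  expect_equal(s$frame$G, 12L)

  path <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(system.file("extdata",
                                    "solvd_like_synthetic_summary.csv",
                                    package = "htebayes"))
  df$se[4] <- 0
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_summary_table(path), "row\\(s\\) 4")

  df$se <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_summary_table(path), "missing column 'se'")
})
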