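#' Simulate subgroup summary statistics with known truth
#'
#' Generates data from the two-stage normal model that underlies the
#' hierarchical shrinkage analysis: true subgroup effects
#' `theta[g] ~ Normal(tau, omega^2)` and observed estimates
#' `theta_hat[g] ~ Normal(theta[g], se[g]^2)`. Used as the package's
#' fixture generator; the returned truth allows recovery checks.
#'
#' @param frame A [build_subgroup_frame()] object.
#' @param tau Overall (mean) treatment effect.
#' @param omega Between-subgroup standard deviation of true effects
#'   (`omega = 0` gives a homogeneous effect).
#' @param se_profile Positive numeric vector of length `frame$G`: the
#'   per-subgroup standard errors (recycled if length 1).
#' @param effect_scale Effect scale label recorded on the summary.
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @return A list with `true_theta` (length-G vector) and `summary`
#'   (a [subgroup_summary()]).
#' @examples
#' frame <- build_subgroup_frame(list(covariate_spec("arm", c("a", "b"))))
#' sim <- simulate_summary_data(frame, tau = -0.3, omega = 0.2,
#'                              se_profile = 0.1, seed = 1)
#' @export
simulate_summary_data <- function(frame, tau, omega, se_profile,
                                  effect_scale = "log_hr", seed) {
  stopifnot(inherits(frame, "subgroup_frame"))
  if (omega < 0) stop("invalid spec: omega must be nonnegative")
  if (missing(seed)) stop("invalid spec: a seed is required")
  if (length(se_profile) == 1L) se_profile <- rep(se_profile, frame$G)
  if (length(se_profile) != frame$G)
    stop("invalid spec: se_profile length ", length(se_profile),
         " does not match G = ", frame$G)
  if (any(se_profile <= 0)) stop("invalid spec: se_profile must be positive")
  set.seed(seed)
  true_theta <- stats::rnorm(frame$G, tau, omega)
  theta_hat <- stats::rnorm(frame$G, true_theta, se_profile)
  list(true_theta = true_theta,
       summary = subgroup_summary(frame, theta_hat, se_profile,
                                  effect_scale = effect_scale))
}

#' Simulate subject-level data with subgroup-specific treatment effects
#'
#' Generates a [subject_table()] with `n_per_arm` subjects in each
#' subgroup-by-arm cell and a known treatment effect per subgroup:
#' a mean shift (continuous, unit residual SD), a log-odds ratio around a
#' baseline logit of 0 (binary), or a log-hazard ratio between exponential
#' event-time distributions with control rate 1 (survival). Censoring, if
#' requested, marks a `censor_rate` fraction of subjects (Bernoulli) as
#' censored at a uniform time before their event.
#'
#' @param frame A [build_subgroup_frame()] object.
#' @param effects Numeric vector of length `frame$G` (recycled if length
#'   1): the true per-subgroup treatment effect on the outcome's scale.
#' @param outcome_kind `"continuous"`, `"binary"` or `"survival"`.
#' @param n_per_arm Subjects per subgroup-arm cell (scalar or length G).
#' @param censor_rate Expected censoring fraction in `[0, 1)`
#'   (survival only).
#' @param seed Integer seed.
#' @return A [subject_table()].
#' @export
simulate_subject_data <- function(frame, effects,
                                  outcome_kind = c("continuous", "binary",
                                                   "survival"),
                                  n_per_arm, censor_rate = 0, seed) {
  stopifnot(inherits(frame, "subgroup_frame"))
  outcome_kind <- match.arg(outcome_kind)
  if (missing(seed)) stop("invalid spec: a seed is required")
  if (length(effects) == 1L) effects <- rep(effects, frame$G)
  if (length(effects) != frame$G)
    stop("invalid spec: effects must have length G = ", frame$G)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("invalid spec: censor_rate must be in [0, 1)")
  if (length(n_per_arm) == 1L) n_per_arm <- rep(n_per_arm, frame$G)
  if (any(n_per_arm < 1L)) stop("invalid spec: n_per_arm must be >= 1")
  set.seed(seed)
  out <- vector("list", frame$G)
  for (g in seq_len(frame$G)) {
    n <- n_per_arm[g]
    trt <- rep(c(0, 1), each = n)
    lv <- frame$subgroups[rep(g, 2L * n), , drop = FALSE]
    if (outcome_kind == "continuous") {
      y <- stats::rnorm(2L * n, mean = effects[g] * trt, sd = 1)
      rec <- data.frame(outcome = y, treatment = trt, lv)
    } else if (outcome_kind == "binary") {
      p <- stats::plogis(effects[g] * trt)
      rec <- data.frame(outcome = stats::rbinom(2L * n, 1L, p),
                        treatment = trt, lv)
    } else {
      t_ev <- stats::rexp(2L * n, rate = exp(effects[g] * trt))
      event <- rep(1L, 2L * n)
      if (censor_rate > 0) {
        cens <- stats::runif(2L * n) < censor_rate
        t_ev[cens] <- stats::runif(sum(cens), 0, t_ev[cens])
        event[cens] <- 0L
      }
      rec <- data.frame(time = t_ev, event = event, treatment = trt, lv)
    }
    out[[g]] <- rec
  }
  subject_table(do.call(rbind, out), outcome_kind, frame$covariates)
}
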