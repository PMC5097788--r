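# shared fixtures: a SOLVD-like (2,2,3) subgroup structure and small helpers

frame_223 <- function() {
  build_subgroup_frame(list(
    covariate_spec("gender", c("F", "M")),
    covariate_spec("age", c("<=65", ">65")),
    covariate_spec("ejecfrac", c("high", "medium", "low"))
  ))
}

frame_22 <- function() {
  build_subgroup_frame(list(
    covariate_spec("gender", c("M", "F")),
    covariate_spec("age", c("young", "old"))
  ))
}

frame_222 <- function() {
  build_subgroup_frame(list(
    covariate_spec("a", c("a0", "a1")),
    covariate_spec("b", c("b0", "b1")),
    covariate_spec("c", c("c0", "c1"))
  ))
}

# the bundled synthetic 12-subgroup summary table
fixture_summary <- function() {
  read_summary_table(
    system.file("extdata", "solvd_like_synthetic_summary.csv",
                package = "htebayes"),
    effect_scale = "log_hr")
}

# pooled draws of one named parameter, straight off the chain matrices
param_draws_for_test <- function(fit, name) {
  do.call(rbind, fit$draws)[, name]
}

# brute-force grid maximizer of the Breslow partial log-likelihood for a
# single covariate; independent of cox_fit's Newton path
grid_cox_beta <- function(times, events, x, lo = -3, hi = 3, step = 1e-4) {
  breslow_loglik <- function(beta) {
    ll <- 0
    for (t in unique(times[events == 1])) {
      dead <- which(times == t & events == 1)
      risk <- which(times >= t)
      ll <- ll + beta * sum(x[dead]) -
        length(dead) * log(sum(exp(beta * x[risk])))
    }
    ll
  }
  grid <- seq(lo, hi, by = step)
  grid[which.max(vapply(grid, breslow_loglik, numeric(1)))]
}
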