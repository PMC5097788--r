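#' Forest table of frequentist and Bayesian subgroup estimates
#'
#' Assembles, per subgroup, the frequentist estimate `theta_hat[g]` with
#' its 95 percent normal-approximation confidence interval
#' (`theta_hat[g] +/- 1.96 s[g]`) alongside the posterior mean and 95
#' percent credible interval of every fitted model, plus the overall
#' reference line: the posterior mean of `tau` for models that have one,
#' otherwise the precision-weighted mean of the `theta_hat[g]`.
#'
#' @param fits Named list of [run_mcmc()] fits of the same data (a single
#'   fit is also accepted).
#' @param data A [subgroup_summary()]; defaults to the first fit's data.
#' @return An object of class `hte_forest`: `table` (one row per subgroup
#'   with `freq_est`, `freq_lower`, `freq_upper` and
#'   `<model>_mean/lower/upper` column sets) and `overall` (named vector
#'   of reference lines per model).
#' @export
forest_data <- function(fits, data = NULL) {
  if (inherits(fits, "hte_fit")) fits <- list(fits)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, function(f) f$spec$name, character(1L))
  if (is.null(data)) data <- fits[[1L]]$data
  for (f in fits)
    if (!isTRUE(all.equal(f$data$theta_hat, data$theta_hat)) ||
        f$spec$G != data$frame$G)
      stop("invalid spec: fits were not all computed on the same ",
           "subgroup summary")
  tab <- data.frame(subgroup = data$frame$labels,
                    freq_est = data$theta_hat,
                    freq_lower = data$theta_hat - 1.96 * data$se,
                    freq_upper = data$theta_hat + 1.96 * data$se)
  overall <- numeric(length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    ef <- summarize_posterior(f)$effects
    nm <- names(fits)[i]
    tab[[paste0(nm, "_mean")]] <- ef$mean
    tab[[paste0(nm, "_lower")]] <- ef[["2.5%"]]
    tab[[paste0(nm, "_upper")]] <- ef[["97.5%"]]
    overall[i] <- if ("tau" %in% f$spec$param_names)
      mean(param_draws(f, "tau"))
    else sum(data$theta_hat / data$se^2) / sum(1 / data$se^2)
  }
  names(overall) <- names(fits)
  structure(list(table = tab, overall = overall), class = "hte_forest")
}

#' @export
print.hte_forest <- function(x, digits = 3, ...) {
  df <- x$table
  df[-1L] <- lapply(df[-1L], round, digits = digits)
  print(df)
  cat("overall reference line(s):",
      paste(names(x$overall), round(x$overall, digits), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Base-graphics forest plot
#'
#' Draws the frequentist intervals (black) and each model's credible
#' intervals (colored) per subgroup, with a vertical reference line at the
#' first model's overall effect. The canonical artifact is the
#' [forest_data()] table; the plot is a convenience view.
#'
#' @param x An `hte_forest` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hte_forest <- function(x, ...) {
  tab <- x$table
  G <- nrow(tab)
  models <- sub("_mean$", "", grep("_mean$", names(tab), value = TRUE))
  num <- unlist(tab[-1L])
  graphics::plot(range(num, na.rm = TRUE), c(0.5, G + 0.5), type = "n",
                 yaxt = "n", xlab = "treatment effect", ylab = "", ...)
  graphics::axis(2, at = rev(seq_len(G)), labels = tab$subgroup, las = 1,
                 cex.axis = 0.6)
  graphics::abline(v = x$overall[1L], lty = 1)
  graphics::abline(v = 0, lty = 3, col = "grey")
  off <- 0.18
  for (g in seq_len(G)) {
    ypos <- G - g + 1
    graphics::segments(tab$freq_lower[g], ypos + off, tab$freq_upper[g],
                       ypos + off)
    graphics::points(tab$freq_est[g], ypos + off, pch = 16)
    for (i in seq_along(models)) {
      col <- i + 1L
      y2 <- ypos + off - i * 2 * off / max(1, length(models))
      graphics::segments(tab[[paste0(models[i], "_lower")]][g], y2,
                         tab[[paste0(models[i], "_upper")]][g], y2,
                         col = col)
      graphics::points(tab[[paste0(models[i], "_mean")]][g], y2,
                       pch = 17, col = col)
    }
  }
  graphics::legend("topright", legend = c("frequentist", models),
                   col = seq_len(length(models) + 1L),
                   pch = c(16, rep(17, length(models))), cex = 0.7)
  invisible(x)
}

#' Posterior benefit probabilities per subgroup
#'
#' Direct probability statements of clinical interest: the posterior
#' probability that each subgroup's treatment effect is beyond a threshold
#' `c` in the benefit direction (e.g. `P(theta[g] < 0)` when lower
#' log-hazard ratios mean benefit), and the qualitative-interaction
#' probability `P(sign(theta[g]) != sign(tau) | y)` that the subgroup
#' effect points the opposite way from the overall effect. For models
#' without an explicit `tau`, the overall effect draw is the mean of the
#' subgroup effect draws.
#'
#' @param fit An [run_mcmc()] fit.
#' @param threshold Effect-scale threshold `c`.
#' @param direction `"less"` if benefit means `theta < c`, `"greater"`
#'   otherwise.
#' @return A data.frame with `subgroup`, `p_benefit` and
#'   `p_qualitative_interaction`.
#' @export
benefit_probabilities <- function(fit, threshold = 0,
                                  direction = c("less", "greater")) {
  stopifnot(inherits(fit, "hte_fit"))
  direction <- match.arg(direction)
  th <- theta_draws(fit)
  p_benefit <- if (direction == "less") colMeans(th < threshold) else
    colMeans(th > threshold)
  tau <- if ("tau" %in% fit$spec$param_names) param_draws(fit, "tau") else
    rowMeans(th)
  p_qual <- colMeans(sign(th) != sign(tau))
  data.frame(subgroup = fit$data$frame$labels,
             p_benefit = unname(p_benefit),
             p_qualitative_interaction = unname(p_qual))
}
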