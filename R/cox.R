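#' Cox proportional-hazards fit by Newton-Raphson
#'
#' Minimal proportional-hazards regression maximizing the Breslow-tie
#' partial likelihood. Subjects with observation time greater than or
#' equal to an event time are in that event's risk set (so a subject
#' censored exactly at an event time is still at risk there). Newton steps
#' are halved whenever the log partial likelihood decreases; convergence
#' is declared when the largest absolute score component falls below
#' `tol`. The covariance matrix is the inverse of the observed information
#' at the optimum.
#'
#' @param times Positive observation times.
#' @param events 0/1 event indicators (1 = event).
#' @param design Numeric matrix of covariates, one row per subject.
#' @param tol Score convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `cox_fit`: `coefficients`, `covariance`,
#'   `loglik` (log partial likelihood at the optimum), `n_events`,
#'   `converged`, `iterations`.
#' @examples
#' fit <- cox_fit(c(1, 2, 3), c(1, 1, 1), cbind(x = c(1, 0, 1)))
#' fit$coefficients  # -0.3466 = -log(2)/2
#' @export
cox_fit <- function(times, events, design, tol = 1e-8, max_iter = 50L) {
  times <- as.numeric(times)
  events <- as.integer(events)
  if (!is.matrix(design)) design <- as.matrix(design)
  storage.mode(design) <- "double"
  n <- length(times)
  stopifnot(length(events) == n, nrow(design) == n)
  if (any(times <= 0)) stop("times must be strictly positive")
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")
  n_events <- sum(events)
  if (n_events < 1L) stop("estimability error: no events")
  p <- ncol(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(p))
  # a covariate with no variation (or aliased columns) carries no partial-
  # likelihood information: require full rank after centering
  centered <- sweep(design, 2L, colMeans(design))
  if (qr(centered)$rank < p)
    stop("estimability error: design is rank deficient ",
         "(constant or aliased covariate)")

  # Breslow partial likelihood, score and information; risk set by time >=
  ord <- order(times)
  times_o <- times[ord]; events_o <- events[ord]
  X_o <- design[ord, , drop = FALSE]
  utimes <- unique(times_o[events_o == 1L])

  eval_all <- function(beta) {
    eta <- drop(X_o %*% beta)
    w <- exp(eta)
    ll <- 0; score <- numeric(p); info <- matrix(0, p, p)
    for (t in utimes) {
      at_risk <- times_o >= t
      dead <- which(times_o == t & events_o == 1L)
      d <- length(dead)
      S0 <- sum(w[at_risk])
      S1 <- colSums(X_o[at_risk, , drop = FALSE] * w[at_risk])
      Xr <- X_o[at_risk, , drop = FALSE]
      S2 <- crossprod(Xr * w[at_risk], Xr)
      ll <- ll + sum(eta[dead]) - d * log(S0)
      score <- score + colSums(X_o[dead, , drop = FALSE]) - d * S1 / S0
      info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
    }
    list(ll = ll, score = score, info = info)
  }

  beta <- numeric(p)
  ev <- eval_all(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(ev$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(ev$info, ev$score),
                     error = function(e) stop("numerical error: singular ",
                                              "information matrix"))
    # halve the step until the log partial likelihood does not decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ev_new <- eval_all(beta_new)
      if (ev_new$ll >= ev$ll - 1e-12 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- beta_new; ev <- ev_new
    if (any(abs(beta) > 15))
      stop("non-convergence: coefficient for '",
           colnames(design)[which.max(abs(beta))],
           "' is diverging (monotone likelihood)")
  }
  if (!converged && max(abs(ev$score)) < tol) converged <- TRUE
  covb <- solve(ev$info)
  dimnames(covb) <- list(colnames(design), colnames(design))
  structure(list(coefficients = stats::setNames(beta, colnames(design)),
                 covariance = covb, loglik = ev$ll, n_events = n_events,
                 converged = converged, iterations = iter),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit (Breslow ties):", x$n_events, "events,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(data.frame(coef = x$coefficients,
                   se = sqrt(diag(x$covariance))))
  invisible(x)
}

#' Wald test of a block of coefficients
#'
#' Chi-square Wald test that a set of coefficients is jointly zero:
#' `statistic = b' V^{-1} b` over the selected block, with degrees of
#' freedom equal to the block size.
#'
#' @param fit A fitted model with `coefficients` and `covariance`
#'   components (e.g. [cox_fit()]), or a list with those names.
#' @param block Integer indices (or coefficient names) of the block.
#' @return A `test_result`: list with `statistic`, `df`, `p`, `label`.
#' @export
wald_block_test <- function(fit, block) {
  beta <- fit$coefficients
  V <- fit$covariance
  if (is.character(block)) block <- match(block, names(beta))
  if (anyNA(block) || any(block < 1L) || any(block > length(beta)))
    stop("block indices outside the coefficient vector")
  b <- beta[block]
  Vb <- V[block, block, drop = FALSE]
  stat <- tryCatch(drop(crossprod(b, solve(Vb, b))),
                   error = function(e) stop("numerical error: singular ",
                                            "block covariance"))
  df <- length(block)
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 label = paste0("Wald[", paste(names(beta)[block],
                                               collapse = ","), "]")),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$label, ": chi-square = ", format(x$statistic, digits = 4),
      ", df = ", x$df, ", p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}
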