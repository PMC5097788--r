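#' Frequentist treatment-covariate interaction tests
#'
#' Comparators to the Bayesian suite. The univariate test examines one
#' covariate at a time: it fits a regression with a treatment main effect,
#' indicators for the non-reference levels of the covariate, and
#' treatment-by-level interaction terms, then Wald-tests the joint null
#' that all interaction coefficients are zero (df = K - 1). The
#' unstructured test includes all covariates at once and tests all
#' treatment-by-covariate interactions jointly (df = sum over covariates of
#' K_j - 1). Continuous outcomes are fitted by least squares, binary
#' outcomes by logistic regression (IRLS via [stats::glm()]), and survival
#' outcomes by the package's Cox partial-likelihood core [cox_fit()].
#'
#' @param data A [subject_table()].
#' @param covariate Covariate name (univariate test only).
#' @return A `test_result`: `statistic`, `df`, `p`, `label`.
#' @seealso [bonferroni_adjust()] for multiplicity adjustment across
#'   several univariate tests.
#' @export
univariate_interaction_test <- function(data, covariate) {
  stopifnot(inherits(data, "subject_table"))
  cv <- Filter(function(c) c$name == covariate, data$covariates)
  if (length(cv) != 1L) stop("unknown covariate: ", covariate)
  interaction_wald(data, cv, label = paste0("univariate[", covariate, "]"))
}

#' @rdname univariate_interaction_test
#' @export
unstructured_interaction_test <- function(data) {
  stopifnot(inherits(data, "subject_table"))
  interaction_wald(data, data$covariates, label = "unstructured")
}

# shared worker: build [trt | dummies | trt:dummies] design and Wald-test
# the interaction block
interaction_wald <- function(data, covariates, label) {
  df <- data$data
  dummies <- NULL
  for (cv in covariates) {
    x <- as.character(df[[cv$name]])
    for (k in seq_along(cv$levels)) {
      lvl <- cv$levels[k]
      if (!any(x == lvl & df$treatment == 1) ||
          !any(x == lvl & df$treatment == 0))
        stop("estimability error: level '", lvl, "' of '", cv$name,
             "' unobserved in one arm")
      if (k == 1L) next  # reference level gets no indicator
      dummies <- cbind(dummies, as.numeric(x == lvl))
      colnames(dummies)[ncol(dummies)] <- paste0(cv$name, "=", lvl)
    }
  }
  trt <- as.numeric(df$treatment)
  inter <- dummies * trt
  colnames(inter) <- paste0("trt:", colnames(dummies))
  X <- cbind(trt = trt, dummies, inter)
  block <- grep("^trt:", colnames(X))

  if (data$outcome_kind == "survival") {
    fit <- cox_fit(df$time, df$event, X)
  } else {
    Xi <- cbind(`(Intercept)` = 1, X)
    fam <- if (data$outcome_kind == "binary") stats::binomial() else
      stats::gaussian()
    gfit <- stats::glm.fit(Xi, df$outcome, family = fam)
    if (any(is.na(gfit$coefficients)))
      stop("estimability error: aliased column(s): ",
           paste(colnames(Xi)[is.na(gfit$coefficients)], collapse = ", "))
    # dispersion: 1 for binomial, residual MSE for gaussian
    qr_R <- qr.R(gfit$qr)
    Vub <- chol2inv(qr_R)
    disp <- if (data$outcome_kind == "binary") 1 else
      sum(gfit$residuals^2 * gfit$weights) / gfit$df.residual
    # glm.fit pivots columns; map the covariance back to input order
    piv <- gfit$qr$pivot
    V <- (Vub * disp)[order(piv), order(piv), drop = FALSE]
    dimnames(V) <- list(colnames(Xi), colnames(Xi))
    fit <- list(coefficients = gfit$coefficients, covariance = V)
    block <- block + 1L  # intercept prepended
  }
  res <- wald_block_test(fit, block)
  res$label <- label
  res
}

#' Bonferroni adjustment of p-values
#'
#' Multiplies each p-value by the number of tests and caps at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @examples
#' bonferroni_adjust(c(0.40, 0.034, 0.029))  # 1.000 0.102 0.087
#' @export
bonferroni_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("validation error: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}
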