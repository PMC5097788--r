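#' Per-subgroup treatment-effect summary statistics
#'
#' The container consumed by every Bayesian model in the package: one
#' treatment-effect estimate `theta_hat[g]` and its standard error `se[g]`
#' per subgroup. The effect scale is a mean difference, a log-odds ratio,
#' or a log-hazard ratio; the sampling model downstream is
#' `theta_hat[g] | theta[g] ~ Normal(theta[g], se[g]^2)`.
#'
#' @param frame A [build_subgroup_frame()] object.
#' @param theta_hat Numeric vector of length `frame$G`.
#' @param se Positive numeric vector of length `frame$G`.
#' @param effect_scale One of `"mean_diff"`, `"log_or"`, `"log_hr"`.
#' @param n_trt,n_ctl Optional per-subgroup arm sizes.
#' @return An object of class `subgroup_summary`.
#' @export
subgroup_summary <- function(frame, theta_hat, se,
                             effect_scale = c("mean_diff", "log_or", "log_hr"),
                             n_trt = NULL, n_ctl = NULL) {
  stopifnot(inherits(frame, "subgroup_frame"))
  effect_scale <- match.arg(effect_scale)
  theta_hat <- as.numeric(theta_hat)
  se <- as.numeric(se)
  if (length(theta_hat) != frame$G || length(se) != frame$G)
    stop("theta_hat and se must have length G = ", frame$G)
  if (anyNA(theta_hat) || anyNA(se))
    stop("theta_hat and se must not contain missing values")
  if (any(se <= 0))
    stop("validation error: non-positive standard error in row(s) ",
         paste(which(se <= 0), collapse = ", "))
  for (nm in c("n_trt", "n_ctl")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != frame$G || any(v < 0))
        stop(nm, " must be a nonnegative vector of length G")
    }
  }
  structure(list(frame = frame, theta_hat = theta_hat, se = se,
                 effect_scale = effect_scale, n_trt = n_trt, n_ctl = n_ctl),
            class = "subgroup_summary")
}

#' @export
print.subgroup_summary <- function(x, ...) {
  cat("subgroup summary (", x$effect_scale, "), G = ", x$frame$G, "\n",
      sep = "")
  print(data.frame(subgroup = x$frame$labels,
                   theta_hat = round(x$theta_hat, 4),
                   se = round(x$se, 4)))
  invisible(x)
}

#' Subject-level data table
#'
#' Wraps a data.frame of subject records with the outcome kind and the
#' covariate declarations needed to place each subject in a subgroup.
#' Continuous and binary outcomes use an `outcome` column; survival
#' outcomes use `time` (positive) and `event` (0/1) columns. `treatment`
#' is 0 (control) / 1 (treated). Rows with a missing covariate value are
#' dropped with a message reporting the count.
#'
#' @param data A data.frame of subject records.
#' @param outcome_kind One of `"continuous"`, `"binary"`, `"survival"`.
#' @param covariates List of [covariate_spec()] objects.
#' @return An object of class `subject_table`.
#' @export
subject_table <- function(data, outcome_kind = c("continuous", "binary",
                                                 "survival"),
                          covariates) {
  outcome_kind <- match.arg(outcome_kind)
  if (inherits(covariates, "covariate_spec")) covariates <- list(covariates)
  nms <- vapply(covariates, `[[`, character(1L), "name")
  need <- c(if (outcome_kind == "survival") c("time", "event") else "outcome",
            "treatment", nms)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[nms])
  if (!all(keep)) {
    message(sum(!keep), " row(s) dropped due to missing covariate values")
    data <- data[keep, , drop = FALSE]
  }
  if (!all(data$treatment %in% c(0, 1)))
    stop("treatment must be coded 0/1")
  if (outcome_kind == "survival") {
    if (!all(data$event %in% c(0, 1)))
      stop("event indicator must be 0/1")
    if (any(data$time <= 0))
      stop("survival times must be strictly positive")
  } else if (outcome_kind == "binary") {
    if (!all(data$outcome %in% c(0, 1)))
      stop("binary outcome must be 0/1")
  }
  frame <- build_subgroup_frame(covariates)
  for (cv in covariates) {
    bad <- setdiff(unique(as.character(data[[cv$name]])), cv$levels)
    if (length(bad))
      stop("unknown level(s) for covariate '", cv$name, "': ",
           paste(bad, collapse = ", "))
  }
  rownames(data) <- NULL
  structure(list(data = data, outcome_kind = outcome_kind,
                 covariates = covariates, frame = frame),
            class = "subject_table")
}

#' @export
print.subject_table <- function(x, ...) {
  cat("subject table:", nrow(x$data), "records,", x$outcome_kind,
      "outcome,", x$frame$G, "subgroups\n")
  invisible(x)
}

two_sample_stats <- function(y_trt, y_ctl) {
  n1 <- length(y_trt); n0 <- length(y_ctl)
  theta <- mean(y_trt) - mean(y_ctl)
  df <- n1 + n0 - 2L
  if (df < 1L)
    stop("estimability error: fewer than 3 subjects")
  sp2 <- ((n1 - 1) * stats::var(y_trt) + (n0 - 1) * stats::var(y_ctl)) / df
  if (!is.finite(sp2)) sp2 <- 0
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  list(theta = theta, se = se)
}

#' Compute per-subgroup summary statistics from subject-level data
#'
#' Reduces subject-level records to the `(theta_hat, se)` pair per subgroup
#' that the Bayesian models consume. Continuous outcomes give a difference
#' in arm means with the pooled two-sample standard error; binary outcomes
#' give the log-odds ratio with `sqrt(1/a + 1/b + 1/c + 1/d)`; survival
#' outcomes give the log-hazard ratio and standard error from a
#' single-covariate Cox proportional-hazards fit ([cox_fit()], Breslow
#' ties) within each subgroup.
#'
#' @param data A [subject_table()].
#' @param frame Optional [build_subgroup_frame()]; defaults to the frame
#'   implied by the table's covariates.
#' @return A [subgroup_summary()] with one row per subgroup.
#' @export
compute_subgroup_summaries <- function(data, frame = data$frame) {
  stopifnot(inherits(data, "subject_table"))
  idx <- match_subgroups(frame, data$data)
  G <- frame$G
  theta <- se <- numeric(G)
  n_trt <- n_ctl <- integer(G)
  for (g in seq_len(G)) {
    rows <- data$data[which(idx == g), , drop = FALSE]
    trt <- rows$treatment == 1
    n_trt[g] <- sum(trt); n_ctl[g] <- sum(!trt)
    if (n_trt[g] == 0L || n_ctl[g] == 0L)
      stop("estimability error: empty arm in subgroup ", frame$labels[g])
    if (data$outcome_kind == "continuous") {
      st <- two_sample_stats(rows$outcome[trt], rows$outcome[!trt])
      if (st$se <= 0)
        stop("estimability error: zero outcome variance in subgroup ",
             frame$labels[g])
      theta[g] <- st$theta; se[g] <- st$se
    } else if (data$outcome_kind == "binary") {
      a <- sum(rows$outcome[trt] == 1); b <- sum(rows$outcome[trt] == 0)
      c_ <- sum(rows$outcome[!trt] == 1); d <- sum(rows$outcome[!trt] == 0)
      if (min(a, b, c_, d) == 0L)
        stop("estimability error: zero cell in 2x2 table of subgroup ",
             frame$labels[g],
             " (no automatic continuity correction is applied)")
      theta[g] <- log(a * d / (b * c_))
      se[g] <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    } else {
      if (sum(rows$event) < 1L)
        stop("estimability error: no events in subgroup ", frame$labels[g])
      fit <- cox_fit(rows$time, rows$event,
                     matrix(as.numeric(rows$treatment), ncol = 1L,
                            dimnames = list(NULL, "treatment")))
      theta[g] <- fit$coefficients[1L]
      se[g] <- sqrt(fit$covariance[1L, 1L])
    }
  }
  scale <- switch(data$outcome_kind, continuous = "mean_diff",
                  binary = "log_or", survival = "log_hr")
  subgroup_summary(frame, theta, se, scale, n_trt = n_trt, n_ctl = n_ctl)
}

#' Read / write a subgroup summary table
#'
#' The on-disk format is a plain CSV with one row per subgroup: one column
#' per covariate (level labels), `theta_hat`, `se`, and optionally
#' `n_trt`, `n_ctl`. Numeric values are written with 17 significant digits
#' so a write/read round trip reproduces them exactly.
#'
#' @param path File path.
#' @param covariates List of [covariate_spec()] declaring the covariate
#'   columns and their level order; if `NULL`, the covariates are inferred
#'   from the file (columns before `theta_hat`, levels in order of first
#'   appearance).
#' @param effect_scale Effect scale recorded on the returned object.
#' @return `read_summary_table` returns a [subgroup_summary()];
#'   `write_summary_table` invisibly returns `path`.
#' @export
read_summary_table <- function(path, covariates = NULL,
                               effect_scale = c("mean_diff", "log_or",
                                                "log_hr")) {
  effect_scale <- match.arg(effect_scale)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("theta_hat", "se"))
    if (!col %in% names(df))
      stop("format error: missing column '", col, "' in ", path)
  if (is.null(covariates)) {
    cov_cols <- setdiff(names(df), c("theta_hat", "se", "n_trt", "n_ctl"))
    if (length(cov_cols) == 0L)
      stop("format error: no covariate columns in ", path)
    covariates <- lapply(cov_cols, function(nm)
      covariate_spec(nm, unique(as.character(df[[nm]]))))
  }
  frame <- build_subgroup_frame(covariates)
  if (nrow(df) != frame$G)
    stop("format error: expected ", frame$G, " rows, found ", nrow(df))
  if (any(!is.finite(df$se) | df$se <= 0))
    stop("validation error: non-positive se in row(s) ",
         paste(which(!is.finite(df$se) | df$se <= 0), collapse = ", "))
  idx <- match_subgroups(frame, df)
  if (anyDuplicated(idx) || anyNA(idx))
    stop("format error: rows do not form the full subgroup cross ",
         "classification")
  ord <- order(idx)
  subgroup_summary(frame,
                   theta_hat = df$theta_hat[ord], se = df$se[ord],
                   effect_scale = effect_scale,
                   n_trt = if ("n_trt" %in% names(df)) df$n_trt[ord],
                   n_ctl = if ("n_ctl" %in% names(df)) df$n_ctl[ord])
}

#' @rdname read_summary_table
#' @param x A [subgroup_summary()] to write.
#' @export
write_summary_table <- function(x, path) {
  stopifnot(inherits(x, "subgroup_summary"))
  df <- x$frame$subgroups
  df$theta_hat <- sprintf("%.17g", x$theta_hat)
  df$se <- sprintf("%.17g", x$se)
  if (!is.null(x$n_trt)) df$n_trt <- x$n_trt
  if (!is.null(x$n_ctl)) df$n_ctl <- x$n_ctl
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
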