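#' Declare a categorical baseline covariate
#'
#' A covariate is a named categorical patient characteristic with at least
#' two levels. The first level is the reference level: it receives no
#' indicator column in any design matrix, so regression coefficients are
#' interpreted as changes from this level.
#'
#' @param name Covariate name (single string).
#' @param levels Character vector of at least two unique level labels; the
#'   first is the reference level.
#' @return An object of class `covariate_spec` with elements `name`,
#'   `levels` and `K` (the number of levels).
#' @examples
#' covariate_spec("gender", c("F", "M"))
#' covariate_spec("ejecfrac", c("high", "medium", "low"))
#' @export
covariate_spec <- function(name, levels) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("invalid covariate spec: 'name' must be a single non-empty string")
  levels <- as.character(levels)
  if (length(levels) < 2L)
    stop("invalid covariate spec: covariate '", name,
         "' must have at least 2 levels")
  if (anyDuplicated(levels))
    stop("invalid covariate spec: duplicate levels in covariate '", name, "'")
  structure(list(name = name, levels = levels, K = length(levels)),
            class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat("covariate '", x$name, "': ", paste(x$levels, collapse = ", "),
      " (reference: ", x$levels[1L], ")\n", sep = "")
  invisible(x)
}

#' Enumerate all subgroups from crossed covariates
#'
#' Builds the full cross-classification of the supplied covariates into
#' G = prod(K_j) mutually exclusive subgroups. The ordering is
#' deterministic: lexicographic by covariate declaration order, then by
#' level order within each covariate (the first covariate varies slowest).
#' All model design matrices and posterior vectors index subgroups by this
#' ordering.
#'
#' @param covariates A list of [covariate_spec()] objects (a single
#'   `covariate_spec` is also accepted).
#' @return An object of class `subgroup_frame`: list with `covariates`,
#'   `subgroups` (a data.frame of level labels, one row per subgroup),
#'   `G` and `labels` (human-readable subgroup labels).
#' @examples
#' frame <- build_subgroup_frame(list(
#'   covariate_spec("gender", c("F", "M")),
#'   covariate_spec("age", c("<=65", ">65")),
#'   covariate_spec("ejecfrac", c("high", "medium", "low"))
#' ))
#' frame$G  # 12
#' @export
build_subgroup_frame <- function(covariates) {
  if (inherits(covariates, "covariate_spec")) covariates <- list(covariates)
  if (!is.list(covariates) || length(covariates) == 0L)
    stop("invalid covariate spec: need at least one covariate")
  if (!all(vapply(covariates, inherits, logical(1L), "covariate_spec")))
    stop("invalid covariate spec: all elements must be covariate_spec objects")
  nms <- vapply(covariates, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("invalid covariate spec: duplicate covariate names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  lvls <- lapply(covariates, `[[`, "levels")
  # first covariate slowest-varying: feed expand.grid reversed, then restore
  grid <- expand.grid(rev(lvls), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(lvls)), drop = FALSE]
  names(grid) <- nms
  rownames(grid) <- NULL
  labels <- apply(grid, 1L, function(r)
    paste(paste(nms, r, sep = "="), collapse = "/"))
  structure(list(covariates = covariates, subgroups = grid,
                 G = nrow(grid), labels = unname(labels)),
            class = "subgroup_frame")
}

#' @export
print.subgroup_frame <- function(x, ...) {
  cat("subgroup frame:", x$G, "subgroups from",
      length(x$covariates), "covariates\n")
  for (cv in x$covariates) print(cv)
  invisible(x)
}

# index of the subgroup each row of `df` (with covariate columns) falls in;
# errors on levels absent from the frame
match_subgroups <- function(frame, df) {
  nms <- vapply(frame$covariates, `[[`, character(1L), "name")
  missing_cols <- setdiff(nms, names(df))
  if (length(missing_cols))
    stop("format error: missing covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cv in frame$covariates) {
    bad <- setdiff(unique(as.character(df[[cv$name]])), cv$levels)
    if (length(bad))
      stop("unknown level(s) for covariate '", cv$name, "': ",
           paste(bad, collapse = ", "))
  }
  key_frame <- do.call(paste, c(frame$subgroups[nms], sep = "\r"))
  key_df <- do.call(paste, c(lapply(df[nms], as.character), sep = "\r"))
  match(key_df, key_frame)
}
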