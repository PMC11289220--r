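#' Population marginal targets for post-stratification
#'
#' Construct and validate a set of population marginal proportions, one row
#' per level of each stratification variable. Raking adjusts case weights so
#' that the weighted sample marginals of every listed variable match these
#' targets.
#'
#' @param x A data frame with columns `variable`, `level` and `proportion`,
#'   or a named list mapping each variable name to a named vector of level
#'   proportions, e.g. `list(sex = c(female = 0.49, male = 0.51))`.
#'
#' @details For every variable the proportions must be strictly positive and
#'   sum to 1 (tolerance 1e-9); `(variable, level)` pairs must be unique.
#'
#' @return An object of class `marginal_targets`: a data frame with columns
#'   `variable`, `level` (character) and `proportion` (numeric).
#' @examples
#' marginal_targets(list(
#'   sex       = c(female = 0.49, male = 0.51),
#'   migration = c(native = 0.70, `non-native` = 0.30)
#' ))
#' @export
marginal_targets <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(names(x)) || any(names(x) == ""))
      stop("list input must be named by variable")
    x <- do.call(rbind, lapply(names(x), function(v) {
      p <- x[[v]]
      if (is.null(names(p)) || any(names(p) == ""))
        stop("proportions for variable '", v, "' must be named by level")
      data.frame(variable = v, level = names(p), proportion = as.numeric(p),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.data.frame(x) ||
      !all(c("variable", "level", "proportion") %in% names(x)))
    stop("targets must have columns 'variable', 'level', 'proportion'")
  x <- data.frame(variable = as.character(x$variable),
                  level = as.character(x$level),
                  proportion = as.numeric(x$proportion),
                  stringsAsFactors = FALSE)
  if (anyNA(x$proportion) || any(x$proportion <= 0))
    stop("all target proportions must be strictly positive")
  if (anyDuplicated(x[c("variable", "level")]))
    stop("duplicated (variable, level) pair in targets")
  sums <- tapply(x$proportion, x$variable, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad))
    stop("proportions do not sum to 1 for variable(s): ",
         paste0(bad, " (sum = ", format(sums[bad], digits = 10), ")",
                collapse = ", "))
  rownames(x) <- NULL
  class(x) <- c("marginal_targets", "data.frame")
  x
}

#' @export
print.marginal_targets <- function(x, ...) {
  cat("Population marginal targets (",
      length(unique(x$variable)), " variable(s))\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

.target_variables <- function(targets) unique(targets$variable)

# weighted level proportions of one variable; levels as character
.weighted_props <- function(lev, w) {
  s <- rowsum(w, lev)
  setNames(as.numeric(s) / sum(w), rownames(s))
}

.check_sv_column <- function(data, variable) {
  if (!variable %in% names(data))
    stop("stratification variable '", variable, "' not found in data")
  lev <- as.character(data[[variable]])
  if (anyNA(lev) || any(lev == ""))
    stop("missing value in stratification variable '", variable,
         "' (case ", paste(utils::head(which(is.na(lev) | lev == ""), 3),
                           collapse = ", "),
         "); remove or recode these cases before weighting")
  lev
}

#' Adjust weights to match one variable's marginal distribution
#'
#' Performs a single raking step: each case weight is multiplied by the ratio
#' of the target proportion of its level to the current weighted sample
#' proportion of that level. Afterwards the weighted marginals of `variable`
#' equal the targets (to machine precision).
#'
#' @param data Data frame of cases containing the column `variable`.
#' @param weights Numeric vector of positive case weights (one per row).
#' @param variable Name of the stratification variable to adjust.
#' @param targets A [marginal_targets] object containing `variable`.
#' @return The adjusted weight vector.
#' @seealso [rake()] which iterates this step over several variables.
#' @examples
#' d <- data.frame(sex = rep(c("w", "m"), c(60, 40)))
#' tg <- marginal_targets(list(sex = c(w = 0.5, m = 0.5)))
#' w <- adjust_to_marginal(d, rep(1, 100), "sex", tg)
#' tapply(w, d$sex, sum) / sum(w)  # 0.5 / 0.5
#' @export
adjust_to_marginal <- function(data, weights, variable, targets) {
  stopifnot(length(weights) == nrow(data))
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  lev <- .check_sv_column(data, variable)
  tg <- targets[targets$variable == variable, ]
  if (!nrow(tg))
    stop("variable '", variable, "' not present in targets")
  unknown <- setdiff(unique(lev), tg$level)
  if (length(unknown))
    stop("level(s) of '", variable, "' missing from targets: ",
         paste(unknown, collapse = ", "))
  empty <- setdiff(tg$level, unique(lev))
  if (length(empty))
    stop("level(s) of '", variable, "' have a positive target but no ",
         "sample weight: ", paste(empty, collapse = ", "),
         ". Consider collapsing sparse levels.")
  props <- .weighted_props(lev, weights)
  factor <- setNames(tg$proportion, tg$level)[names(props)] / props
  weights * as.numeric(factor[lev])
}

#' Rake case weights by iterative proportional fitting
#'
#' Iteratively adjusts case weights, one stratification variable at a time,
#' until the weighted sample marginals of all variables match the population
#' targets. Weights are initialised to 1 (the unweighted sample). One
#' iteration (cycle) adjusts every variable once, in `order`; convergence is
#' declared when the largest absolute deviation of any weighted marginal from
#' its target falls below `tol`.
#'
#' Only marginal proportions are needed; the joint distribution of the
#' stratification variables in the population is not used. The fixed point is
#' independent of `order` whenever all targeted levels are populated, but
#' intermediate weights are not, so the order used is recorded in the report.
#'
#' @inheritParams adjust_to_marginal
#' @param order Character vector of variable names, a permutation of the
#'   variables in `targets`. Defaults to their order of appearance.
#' @param tol Convergence tolerance on the maximum absolute marginal
#'   deviation (a proportion). Default `1e-6`.
#' @param max_iter Maximum number of full cycles. Default 50; raking
#'   typically converges within the first 5-20 adjustment steps.
#' @return A list with components `weights` (numeric vector, one positive
#'   weight per case) and `report`, an object of class `raking_report` with
#'   fields `iterations`, `max_marginal_deviation` (one value per completed
#'   cycle), `converged`, `order` and `tol`. Non-convergence at `max_iter`
#'   sets `converged = FALSE` but does not raise an error.
#' @examples
#' d <- data.frame(sex = rep(c("w", "m"), c(5167, 4833)))
#' tg <- marginal_targets(list(sex = c(w = 0.48, m = 0.52)))
#' r <- rake(d, tg)
#' r$report
#' round(unique(r$weights), 4)
#' @export
rake <- function(data, targets, order = NULL, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(targets, "marginal_targets"))
  vars <- .target_variables(targets)
  if (is.null(order)) order <- vars
  if (!setequal(order, vars) || length(order) != length(vars))
    stop("'order' must be a permutation of the target variables: ",
         paste(vars, collapse = ", "))
  levs <- lapply(order, function(v) .check_sv_column(data, v))
  names(levs) <- order
  w <- rep(1, nrow(data))
  dev_hist <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (v in order) w <- adjust_to_marginal(data, w, v, targets)
    dev <- max(vapply(order, function(v) {
      tg <- targets[targets$variable == v, ]
      props <- .weighted_props(levs[[v]], w)
      max(abs(props[tg$level] - tg$proportion))
    }, numeric(1)))
    dev_hist <- c(dev_hist, dev)
    if (dev < tol) { converged <- TRUE; break }
  }
  report <- structure(
    list(iterations = iter, max_marginal_deviation = dev_hist,
         converged = converged, order = order, tol = tol),
    class = "raking_report")
  list(weights = w, report = report)
}

#' @export
print.raking_report <- function(x, ...) {
  cat("Raking report: ", x$iterations, " cycle(s) over [",
      paste(x$order, collapse = ", "), "], ",
      if (x$converged) "converged" else "NOT converged",
      " (tol = ", format(x$tol), ")\n", sep = "")
  cat("Max marginal deviation per cycle:",
      paste(format(x$max_marginal_deviation, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Standardize raking weights to a minimum of 1
#'
#' Divides all weights by the smallest weight, so that every standardized
#' weight is greater than or equal to 1 and pairwise ratios are preserved.
#' A standardized weight states how many times the case counts in the
#' weighted norming process.
#'
#' @param weights Numeric vector of strictly positive weights.
#' @return The standardized weight vector (`min(w) == 1`).
#' @examples
#' standardize_weights(c(0.5, 1, 2))  # 1 2 4
#' @export
standardize_weights <- function(weights) {
  if (!length(weights)) stop("empty weight vector")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  weights / min(weights)
}

#' Compute standardized raking weights for a normative sample
#'
#' Convenience wrapper chaining [rake()] and [standardize_weights()]: the
#' usual first step of the weighted norming workflow.
#'
#' @inheritParams rake
#' @return A list with `weights` (standardized: minimum exactly 1) and
#'   `report` as in [rake()].
#' @export
raking_weights <- function(data, targets, order = NULL, tol = 1e-6,
                           max_iter = 50) {
  r <- rake(data, targets, order = order, tol = tol, max_iter = max_iter)
  if (!r$report$converged)
    warning("raking did not converge within ", max_iter, " cycles")
  r$weights <- standardize_weights(r$weights)
  r
}

#' Compare sample composition against population targets
#'
#' Reports, for every targeted (variable, level) pair, the weighted (or
#' unweighted) sample proportion, the target proportion and the signed
#' deviation. Levels present in the data but absent from the targets are
#' reported with `NA` target rather than raised as errors.
#'
#' @inheritParams adjust_to_marginal
#' @param weights Optional case weights; omitted means unweighted
#'   proportions.
#' @return Data frame with columns `variable`, `level`,
#'   `sample_proportion`, `target_proportion`, `deviation`.
#' @export
check_representativeness <- function(data, targets, weights = NULL) {
  stopifnot(inherits(targets, "marginal_targets"))
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data))
  out <- lapply(.target_variables(targets), function(v) {
    lev <- .check_sv_column(data, v)
    props <- .weighted_props(lev, weights)
    tg <- targets[targets$variable == v, ]
    all_lev <- union(tg$level, names(props))
    sp <- ifelse(all_lev %in% names(props), props[all_lev], 0)
    tp <- setNames(tg$proportion, tg$level)[all_lev]
    data.frame(variable = v, level = all_lev,
               sample_proportion = as.numeric(sp),
               target_proportion = as.numeric(tp),
               deviation = as.numeric(sp) - as.numeric(tp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Kish effective sample size
#'
#' The effective number of cases of a weighted sample,
#' \eqn{(\sum w)^2 / \sum w^2}. It equals the case count for uniform weights
#' and decreases as weights become more variable; a strongly reduced
#' effective size signals precision loss from high raking weights (typically
#' caused by severely under-represented strata).
#'
#' @param weights Numeric vector of strictly positive weights.
#' @return A single number in `(0, length(weights)]`.
#' @examples
#' effective_sample_size(rep(1, 10))  # 10
#' effective_sample_size(c(1, 3))     # 1.6
#' @export
effective_sample_size <- function(weights) {
  if (!length(weights)) stop("empty weight vector")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  sum(weights)^2 / sum(weights^2)
}
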