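term_label <- function(i, j) {
  l <- if (i > 0) paste0("L", i) else ""
  a <- if (j > 0) paste0("A", j) else ""
  paste0(l, a)
}

#' Polynomial design matrix in person location and age
#'
#' Builds the full design matrix of the continuous norm model: one column
#' per term `l^i * a^j` with location power `i <= k` and age power
#' `j <= t`, all interactions included and the constant term `(0, 0)`
#' excluded (the intercept is handled separately by the fitting routines).
#' Columns are ordered lexicographically in `(i, j)`.
#'
#' @param l Numeric vector of person locations (manifest norm scores).
#' @param a Numeric vector of ages (or another continuous explanatory
#'   variable), same length as `l`.
#' @param k Maximum power of the location, `k >= 1`.
#' @param t Maximum power of age, `t >= 1`.
#' @return A numeric matrix with `(k + 1) * (t + 1) - 1` columns and a
#'   `"powers"` attribute: a two-column integer matrix of `(i, j)` pairs.
#' @examples
#' colnames(build_design(c(40, 50), c(3, 4), k = 1, t = 1))  # A1, L1, L1A1
#' @export
build_design <- function(l, a, k, t) {
  stopifnot(length(l) == length(a))
  if (k < 1 || t < 1) stop("k and t must be at least 1")
  pow <- expand.grid(j = 0:t, i = 0:k)[, c("i", "j")]
  pow <- as.matrix(pow[!(pow$i == 0 & pow$j == 0), , drop = FALSE])
  X <- matrix(NA_real_, length(l), nrow(pow))
  for (c in seq_len(nrow(pow)))
    X[, c] <- l^pow[c, "i"] * a^pow[c, "j"]
  colnames(X) <- unname(apply(pow, 1, function(p) term_label(p[1], p[2])))
  rownames(pow) <- colnames(X)
  attr(X, "powers") <- pow
  X
}

# Weighted cross-products and full-model statistics shared by the
# subset search and the fit indices.
.cross_products <- function(design, y, weights = NULL) {
  n <- length(y)
  stopifnot(nrow(design) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  Xa <- cbind(`(Intercept)` = 1, design)
  sw <- sqrt(weights)
  G <- crossprod(Xa * sw)
  g <- as.numeric(crossprod(Xa * sw, y * sw))
  # scale columns to unit weighted norm: leaves every subset's RSS (and
  # hence the search) unchanged but keeps the normal equations
  # well-conditioned for high polynomial powers
  col_scale <- sqrt(diag(G))
  col_scale[col_scale == 0] <- 1
  G <- G / tcrossprod(col_scale)
  g <- g / col_scale
  yty <- sum(weights * y^2)
  W <- sum(weights)
  TSS <- yty - sum(weights * y)^2 / W
  qf <- qr(Xa * sw)
  rss_full <- sum(qr.resid(qf, y * sw)^2)
  p <- ncol(design)
  sigma2_full <- if (W - p - 1 > 0) rss_full / (W - p - 1) else NA_real_
  list(G = G, g = g, yty = yty, W = W, n = n, TSS = TSS,
       rss_full = rss_full, sigma2_full = sigma2_full, p = p,
       col_scale = col_scale, powers = attr(design, "powers"),
       cols = colnames(design))
}

.fit_stats <- function(rss, cp, s) {
  W <- cp$W
  R2 <- 1 - rss / cp$TSS
  adjR2 <- 1 - (1 - R2) * (W - 1) / (W - s - 1)
  Cp <- if (is.na(cp$sigma2_full) || cp$sigma2_full <= 0) NA_real_
        else rss / cp$sigma2_full - W + 2 * (s + 1)
  BIC <- if (rss <= 0) -Inf else W * log(rss / W) + (s + 1) * log(W)
  list(R2 = R2, adjR2 = adjR2, Cp = Cp, BIC = BIC, rss = rss)
}

.make_norm_model <- function(res, cp, scale, k, t, raw_range, age_range,
                             weighted) {
  idx <- res$indices
  coefs <- unname(res$beta[-1] / cp$col_scale[idx + 1])
  intercept <- unname(res$beta[1] / cp$col_scale[1])
  names(coefs) <- cp$cols[idx]
  powers <- if (!is.null(cp$powers)) cp$powers[idx, , drop = FALSE] else NULL
  structure(
    list(scale = norm_scale(scale), k = k, t = t,
         terms = powers, coefficients = coefs, intercept = intercept,
         fit = .fit_stats(res$rss, cp, res$size),
         raw_range = raw_range, age_range = age_range, weighted = weighted),
    class = "norm_model")
}

#' @export
print.norm_model <- function(x, digits = 4, ...) {
  cat("Continuous norm model (", length(x$coefficients), " term(s), scale ",
      x$scale$name, ")\n", sep = "")
  if (!is.null(x$terms)) {
    form <- tolower(rownames(x$terms))
    form <- gsub("(?<=[la])1(?![0-9])", "", form, perl = TRUE)
    cat("  raw ~ ", paste(form, collapse = " + "), "\n", sep = "")
  }
  cat("  Intercept:", format(x$intercept, digits = digits), "\n")
  print(format(x$coefficients, digits = digits), quote = FALSE)
  cat("  R2 = ", format(x$fit$R2, digits = 6),
      ", adj. R2 = ", format(x$fit$adjR2, digits = 6),
      ", Cp = ", format(x$fit$Cp, digits = 4),
      ", BIC = ", format(x$fit$BIC, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Exact best-subset weighted regression
#'
#' For every model size `s = 1, ..., max_terms`, finds the subset of design
#' columns minimising the weighted residual sum of squares among all
#' size-`s` subsets, with the intercept always included. The search is
#' exhaustive (every subset is scored through the precomputed cross-product
#' matrix), so the returned models are exactly RSS-optimal per size.
#'
#' @param design Design matrix, typically from [build_design()].
#' @param y Numeric response (raw scores).
#' @param weights Optional positive case weights.
#' @param max_terms Largest model size; must not exceed `ncol(design)`.
#' @param scale,k,t,raw_range,age_range Metadata stored in the returned
#'   models (filled automatically by [fit_norm_model()]).
#' @return An object of class `norm_model_sequence`: a list of `norm_model`
#'   objects of sizes `1 .. max_terms`, each with fit indices `R2`, `adjR2`,
#'   Mallows `Cp` (relative to the full model's error variance) and `BIC`.
#' @seealso [select_model()], [fit_norm_model()]
#' @export
best_subset <- function(design, y, weights = NULL, max_terms = NULL,
                        scale = "T", k = NA, t = NA,
                        raw_range = range(y), age_range = c(NA, NA)) {
  p <- ncol(design)
  if (is.null(max_terms)) max_terms <- min(p, 10L)
  if (max_terms > p) stop("max_terms exceeds the number of design columns")
  cp <- .cross_products(design, y, weights)
  res <- best_subset_search(cp$G, cp$g, cp$yty, as.integer(seq_len(max_terms)))
  if (any(vapply(res, function(r) r$skipped, logical(1))))
    warning("some rank-deficient term subsets were dropped from the search")
  if (any(!vapply(res, function(r) r$ok, logical(1))))
    stop("all candidate subsets were rank-deficient")
  models <- lapply(res, .make_norm_model, cp = cp, scale = scale, k = k,
                   t = t, raw_range = raw_range, age_range = age_range,
                   weighted = !is.null(weights))
  structure(models, class = "norm_model_sequence")
}

#' @export
print.norm_model_sequence <- function(x, ...) {
  tab <- data.frame(
    terms = vapply(x, function(m) length(m$coefficients), integer(1)),
    R2 = vapply(x, function(m) m$fit$R2, numeric(1)),
    adjR2 = vapply(x, function(m) m$fit$adjR2, numeric(1)),
    Cp = vapply(x, function(m) m$fit$Cp, numeric(1)),
    BIC = vapply(x, function(m) m$fit$BIC, numeric(1)),
    model = vapply(x, function(m) paste(names(m$coefficients),
                                        collapse = " + "), character(1)))
  cat("Best-subset model sequence:\n")
  print(tab, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Select the most parsimonious sufficiently fitting model
#'
#' Returns the smallest model in a [best_subset()] sequence whose R-squared
#' exceeds `threshold` (default .99). If no model qualifies, the largest
#' model is returned with a warning.
#'
#' @param sequence A `norm_model_sequence`.
#' @param threshold R-squared threshold, default 0.99.
#' @return A single `norm_model`.
#' @export
select_model <- function(sequence, threshold = 0.99) {
  stopifnot(length(sequence) > 0)
  ord <- order(vapply(sequence, function(m) length(m$coefficients),
                      integer(1)))
  for (i in ord)
    if (sequence[[i]]$fit$R2 > threshold) return(sequence[[i]])
  warning("no model exceeded R2 > ", threshold,
          "; returning the largest model")
  sequence[[ord[length(ord)]]]
}

#' Fit indices of a norm model on given data
#'
#' Recomputes weighted R-squared, adjusted R-squared, Mallows Cp and BIC for
#' a fitted model against a design matrix and response. `Cp` needs the error
#' variance of the full model (all candidate terms); if `sigma2_full` is not
#' supplied it is estimated by fitting the full design. With `sigma2_full`
#' zero or unavailable, `Cp` is reported as `NA`.
#'
#' All indices use the total weight `W = sum(weights)` in place of the case
#' count: `Cp = RSS/sigma2_full - W + 2(s + 1)` and
#' `BIC = W log(RSS/W) + (s + 1) log(W)`, with `s` the number of
#' non-intercept terms.
#'
#' @param model A `norm_model`.
#' @param design Design matrix whose column names cover the model's terms.
#' @param y Numeric response.
#' @param weights Optional positive case weights.
#' @param sigma2_full Optional full-model error variance.
#' @return A list `R2`, `adjR2`, `Cp`, `BIC`, `rss`.
#' @export
fit_indices <- function(model, design, y, weights = NULL,
                        sigma2_full = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  miss <- setdiff(names(model$coefficients), colnames(design))
  if (length(miss))
    stop("design lacks model term(s): ", paste(miss, collapse = ", "))
  pred <- model$intercept +
    design[, names(model$coefficients), drop = FALSE] %*% model$coefficients
  rss <- sum(weights * (y - pred)^2)
  cp <- .cross_products(design, y, weights)
  if (!is.null(sigma2_full)) cp$sigma2_full <- sigma2_full
  .fit_stats(rss, cp, length(model$coefficients))
}

#' Check a norm model for percentile-curve consistency
#'
#' A valid norm model must predict strictly increasing raw scores as a
#' function of the norm score at every age — equivalently, its percentile
#' curves may not intersect. This check evaluates the model on an age by
#' norm grid and reports every grid interval on which the predicted raw
#' score fails to increase.
#'
#' @param model A `norm_model`.
#' @param ages Ages to check; defaults to 50 evenly spaced points over the
#'   model's observed age range.
#' @param norms Norm scores to check; defaults to mean +/- 2.5 SD of the
#'   model's scale in steps of 0.05 SD (T 25-75 by 0.5), covering the
#'   percentile band PR 0.6-99.4.
#' @param tol Increments below `-tol` count as violations. Default `1e-8`.
#' @return An object of class `consistency_report` with fields `violations`
#'   (data frame: `age`, `norm_lo`, `norm_hi`, `kind`), `clean`, and
#'   `message` (exactly `"No violations of model consistency found."` when
#'   clean).
#' @export
check_consistency <- function(model, ages = NULL, norms = NULL, tol = 1e-8) {
  sc <- model$scale
  if (is.null(norms))
    norms <- seq(sc$mean - 2.5 * sc$sd, sc$mean + 2.5 * sc$sd,
                 by = 0.05 * sc$sd)
  if (is.null(ages)) {
    if (is.null(model$age_range) || anyNA(model$age_range))
      stop("model carries no age range; supply 'ages'")
    ages <- seq(model$age_range[1], model$age_range[2], length.out = 50)
  }
  stopifnot(length(ages) > 0, length(norms) > 1,
            !is.unsorted(ages), !is.unsorted(norms))
  raw <- outer(norms, ages, function(n, a) predict_raw(model, n, a))
  inc <- diff(raw)  # along norms, per age
  bad <- which(inc <= -tol, arr.ind = TRUE)
  violations <- data.frame(
    age = ages[bad[, 2]],
    norm_lo = norms[bad[, 1]],
    norm_hi = norms[bad[, 1] + 1],
    kind = rep("non-monotone", nrow(bad)),
    stringsAsFactors = FALSE)
  violations <- violations[order(violations$age, violations$norm_lo), ]
  rownames(violations) <- NULL
  clean <- nrow(violations) == 0
  msg <- if (clean) "No violations of model consistency found." else
    paste0("Model consistency violated on ", nrow(violations),
           " grid interval(s); percentile curves intersect. ",
           "Consider a different number of terms or lower k/t.")
  structure(list(violations = violations, clean = clean, message = msg),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(x$message, "\n")
  if (!x$clean) print(utils::head(x$violations, 10))
  invisible(x)
}

#' Fit a continuous norm model to a normative sample
#'
#' Runs the complete weighted norming pipeline: group-wise (weighted)
#' ranking and inverse normal transformation ([norm_by_group()]), polynomial
#' design construction in location and age ([build_design()]), exact
#' best-subset weighted regression of the raw scores ([best_subset()]),
#' model selection at an R-squared threshold ([select_model()]) and a
#' percentile-curve consistency check ([check_consistency()]). When raking
#' weights are supplied they are used both in the ranking and as regression
#' weights.
#'
#' The model sequence is searched incrementally: sizes 1, 2, ... are fitted
#' until the threshold is reached (R-squared is non-decreasing in model
#' size, so this yields the same selection as searching all sizes first).
#'
#' @inheritParams norm_by_group
#' @param age Optional name of a continuous age column to use as the
#'   explanatory variable of the regression; by default the (numeric) group
#'   values — e.g. age-group midpoints from [age_to_group()] — are used.
#' @param k,t Maximum powers of location and age. `k = 5`, `t = 3` are
#'   usually sufficient; reduce them when the model overfits.
#' @param terms Optional fixed number of regression terms; overrides the
#'   threshold-based selection.
#' @param threshold R-squared selection threshold, default 0.99.
#' @param max_terms Largest model size tried, default `min(10, #columns)`.
#' @param min_group_n Group-size warning threshold, default 100.
#' @return An object of class `norm_fit`: a list with `model` (the selected
#'   `norm_model`), `data` (the input rows with `weight`, `percentile`,
#'   `norm` appended), `sequence` (all sizes tried), `consistency` (the
#'   report for the selected model) and `group_sizes`.
#' @examples
#' spec <- population_spec()
#' d <- generate_population(spec, n = 1200, seed = 7)
#' d$group <- age_to_group(d$age, n_groups = 6)
#' fit <- fit_norm_model(d, k = 3, t = 2, min_group_n = 50)
#' fit$model
#' @export
fit_norm_model <- function(data, raw = "raw", group = "group", age = NULL,
                           weights = NULL, k = 5, t = 3, method = "rankit",
                           scale = "T", terms = NULL, threshold = 0.99,
                           max_terms = NULL, total = c("weights", "count"),
                           min_group_n = 100) {
  total <- match.arg(total)
  for (col in c(raw, group, age))
    if (!col %in% names(data)) stop("column '", col, "' not found in data")
  gs <- table(data[[group]])
  small <- names(gs)[gs < min_group_n]
  if (length(small))
    warning("group(s) with fewer than ", min_group_n, " cases: ",
            paste(small, collapse = ", "),
            "; norms for these groups may be unstable")
  normed <- norm_by_group(data, raw = raw, group = group, weights = weights,
                          method = method, scale = scale, total = total)
  a <- if (is.null(age)) {
    av <- suppressWarnings(as.numeric(as.character(data[[group]])))
    if (anyNA(av))
      stop("group values are not numeric; supply a continuous 'age' column")
    av
  } else data[[age]]
  # degenerate groups (single distinct raw score) are normed but excluded
  # from the regression
  keep <- rep(TRUE, nrow(data))
  for (gv in names(gs)) {
    idx <- which(data[[group]] == gv)
    if (length(unique(data[[raw]][idx])) < 2) keep[idx] <- FALSE
  }
  if (!any(keep)) stop("no non-degenerate groups to fit")
  design <- build_design(normed$norm[keep], a[keep], k, t)
  y <- data[[raw]][keep]
  w <- normed$weight[keep]
  if (all(w == 1)) w <- NULL
  p <- ncol(design)
  if (is.null(max_terms)) max_terms <- min(p, 10L)
  raw_range <- range(data[[raw]])
  age_range <- range(a)
  cp <- .cross_products(design, y, w)
  sizes <- if (!is.null(terms)) as.integer(terms) else integer(0)
  models <- list()
  if (length(sizes)) {
    res <- best_subset_search(cp$G, cp$g, cp$yty, sizes)
    models <- lapply(res, .make_norm_model, cp = cp, scale = scale, k = k,
                     t = t, raw_range = raw_range, age_range = age_range,
                     weighted = !is.null(w))
    selected <- models[[length(models)]]
  } else {
    for (s in seq_len(max_terms)) {
      res <- best_subset_search(cp$G, cp$g, cp$yty, s)[[1]]
      if (!res$ok) stop("all size-", s, " subsets were rank-deficient")
      models[[s]] <- .make_norm_model(res, cp, scale, k, t, raw_range,
                                      age_range, weighted = !is.null(w))
      if (models[[s]]$fit$R2 > threshold) break
    }
    selected <- select_model(structure(models, class = "norm_model_sequence"),
                             threshold = threshold)
  }
  consistency <- check_consistency(selected)
  structure(list(model = selected, data = normed,
                 sequence = structure(models, class = "norm_model_sequence"),
                 consistency = consistency, group_sizes = gs),
            class = "norm_fit")
}

#' @export
print.norm_fit <- function(x, ...) {
  print(x$model)
  cat("Groups: ", length(x$group_sizes), " (n = ",
      min(x$group_sizes), "-", max(x$group_sizes), ")\n", sep = "")
  cat(x$consistency$message, "\n")
  invisible(x)
}
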