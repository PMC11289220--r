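#' Predicted raw score for a norm score and age
#'
#' Evaluates the fitted polynomial
#' `intercept + sum c_(i,j) * norm^i * age^j` of a continuous norm model.
#' Vectorised over `norm` and `age` (recycled to a common length).
#'
#' @param model A `norm_model`.
#' @param norm Norm score(s) on the model's scale (person location).
#' @param age Age(s).
#' @return Predicted raw score(s).
#' @export
predict_raw <- function(model, norm, age) {
  n <- max(length(norm), length(age))
  norm <- rep_len(norm, n)
  age <- rep_len(age, n)
  out <- rep(model$intercept, n)
  pw <- model$terms
  cf <- model$coefficients
  for (r in seq_along(cf))
    out <- out + cf[r] * norm^pw[r, 1] * age^pw[r, 2]
  unname(out)
}

.monotone_at_age <- function(model, age, bounds, tol = 1e-8) {
  norms <- seq(bounds[1], bounds[2], length.out = 200)
  raw <- predict_raw(model, norms, age)
  all(diff(raw) > -tol)
}

#' Norm score for a raw score at a given age
#'
#' Inverts the fitted raw-score polynomial at a fixed age by bisection: the
#' returned norm score `n` satisfies `predict_raw(model, n, age) == raw` to
#' within `1e-8` (in the norm metric). Requires the model to be monotone in
#' the norm score over `bounds` at this age; a non-monotone model raises an
#' error pointing to [check_consistency()]. Raw scores outside the
#' attainable range at this age are clamped to the boundary norm and
#' flagged.
#'
#' @param model A `norm_model`.
#' @param raw Raw score(s).
#' @param age A single age.
#' @param bounds Search interval for the norm score; default scale
#'   mean +/- 5 SD.
#' @return Norm score(s), with a logical attribute `clamped` marking raw
#'   scores outside the attainable range.
#' @examples
#' m <- identity_model()
#' predict_norm(m, raw = 42, age = 10)  # 42
#' @export
predict_norm <- function(model, raw, age, bounds = NULL) {
  sc <- model$scale
  if (is.null(bounds)) bounds <- sc$mean + c(-5, 5) * sc$sd
  stopifnot(length(age) == 1, length(bounds) == 2, bounds[1] < bounds[2])
  if (!.monotone_at_age(model, age, bounds))
    stop("model is not monotone in the norm score at age ", age,
         " within [", bounds[1], ", ", bounds[2], "]; ",
         "see check_consistency() for the violating region")
  lo_raw <- predict_raw(model, bounds[1], age)
  hi_raw <- predict_raw(model, bounds[2], age)
  out <- numeric(length(raw))
  clamped <- logical(length(raw))
  for (i in seq_along(raw)) {
    if (raw[i] <= lo_raw) {
      out[i] <- bounds[1]; clamped[i] <- raw[i] < lo_raw
    } else if (raw[i] >= hi_raw) {
      out[i] <- bounds[2]; clamped[i] <- raw[i] > hi_raw
    } else {
      lo <- bounds[1]; hi <- bounds[2]
      while (hi - lo > 1e-8) {
        mid <- (lo + hi) / 2
        if (predict_raw(model, mid, age) < raw[i]) lo <- mid else hi <- mid
      }
      out[i] <- (lo + hi) / 2
    }
  }
  attr(out, "clamped") <- clamped
  out
}

#' @export
predict.norm_model <- function(object, raw, age, ...) {
  predict_norm(object, raw = raw, age = age, ...)
}

#' Norm table at a fixed age
#'
#' Tabulates the raw-to-norm mapping of a continuous norm model at one age,
#' either over a grid of raw scores (`raw_step`, supporting the integer raw
#' scores of discrete tests) or over a grid of norm scores (`norm_step`).
#' Each integer raw score maps to the norm of its exact value (no
#' continuity correction). Ages outside the model's fitted range are
#' allowed (the polynomial extrapolates) but flagged.
#'
#' @param model A `norm_model`.
#' @param age A single age.
#' @param raw_step Step of the raw-score grid over the model's observed raw
#'   range. Default 1.
#' @param norm_step If given, tabulate at norm scores
#'   `seq(mean - 2.5 sd, mean + 2.5 sd, by = norm_step)` instead.
#' @param bounds Norm search interval, see [predict_norm()].
#' @return An object of class `norm_table`: a data frame with columns
#'   `raw`, `norm`, `percentile` and `clamped`, sorted by raw score, with
#'   attributes `age`, `scale` and `extrapolated`.
#' @export
norm_table <- function(model, age, raw_step = 1, norm_step = NULL,
                       bounds = NULL) {
  sc <- model$scale
  extrapolated <- !anyNA(model$age_range) &&
    (age < model$age_range[1] || age > model$age_range[2])
  if (!is.null(norm_step)) {
    norms <- seq(sc$mean - 2.5 * sc$sd, sc$mean + 2.5 * sc$sd,
                 by = norm_step)
    if (!.monotone_at_age(model, age,
                          c(norms[1], norms[length(norms)])))
      stop("model is not monotone at age ", age,
           "; see check_consistency()")
    tab <- data.frame(raw = predict_raw(model, norms, age), norm = norms,
                      clamped = FALSE)
  } else {
    raws <- seq(model$raw_range[1], model$raw_range[2], by = raw_step)
    norms <- predict_norm(model, raws, age, bounds = bounds)
    tab <- data.frame(raw = raws, norm = as.numeric(norms),
                      clamped = attr(norms, "clamped"))
  }
  tab$percentile <- pnorm((tab$norm - sc$mean) / sc$sd)
  tab <- tab[order(tab$raw), c("raw", "norm", "percentile", "clamped")]
  rownames(tab) <- NULL
  structure(tab, class = c("norm_table", "data.frame"),
            age = age, scale = sc, extrapolated = extrapolated)
}

#' @export
print.norm_table <- function(x, ...) {
  sc <- attr(x, "scale")
  cat("Norm table at age ", attr(x, "age"), " (scale ", sc$name, ")",
      if (isTRUE(attr(x, "extrapolated"))) " [extrapolated]", "\n",
      sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Percentile curves of a norm model
#'
#' Evaluates the raw score corresponding to each requested percentile over
#' an age grid: `raw(age) = predict_raw(model, mean + sd * qnorm(p), age)`.
#' The default percentile set \{2.5, 10, 25, 50, 75, 90, 97.5\}% spans the
#' band conventionally plotted for norm models.
#'
#' @param model A `norm_model`.
#' @param percentiles Fractions in (0, 1).
#' @param ages Age grid; defaults to 50 evenly spaced points over the
#'   model's fitted age range.
#' @return A long-format data frame with columns `age`, `percentile`,
#'   `norm`, `raw`, suitable for plotting or CSV export.
#' @export
percentile_curves <- function(model,
                              percentiles = c(0.025, 0.1, 0.25, 0.5,
                                              0.75, 0.9, 0.975),
                              ages = NULL) {
  stopifnot(all(percentiles > 0 & percentiles < 1))
  if (is.null(ages)) {
    if (is.null(model$age_range) || anyNA(model$age_range))
      stop("model carries no age range; supply 'ages'")
    ages <- seq(model$age_range[1], model$age_range[2], length.out = 50)
  }
  sc <- model$scale
  out <- expand.grid(age = ages, percentile = percentiles,
                     KEEP.OUT.ATTRS = FALSE)
  out$norm <- sc$mean + sc$sd * qnorm(out$percentile)
  out$raw <- predict_raw(model, out$norm, out$age)
  out[order(out$percentile, out$age), ]
}

#' Construct a norm model from explicit terms and coefficients
#'
#' Builds a `norm_model` directly from `(i, j)` power pairs and
#' coefficients, without fitting. Used for ground-truth models in
#' simulations and for degenerate reference models in examples and tests.
#'
#' @param terms Two-column matrix (or list of pairs) of location/age powers.
#' @param coefficients Numeric vector, one per term.
#' @param intercept Intercept, default 0.
#' @param scale Norm scale, default T.
#' @param raw_range,age_range Ranges stored on the model.
#' @return A `norm_model`.
#' @examples
#' # raw = 28.32 + 3.797 a + 0.05 l a + 2e-5 l^2 a^2 - 1.6e-8 l^3 a^3
#' make_norm_model(rbind(c(0, 1), c(1, 1), c(2, 2), c(3, 3)),
#'                 c(3.797, 0.05, 2e-5, -1.6e-8), intercept = 28.32)
#' @export
make_norm_model <- function(terms, coefficients, intercept = 0, scale = "T",
                            raw_range = c(-Inf, Inf),
                            age_range = c(NA, NA)) {
  if (is.list(terms)) terms <- do.call(rbind, terms)
  terms <- matrix(as.integer(terms), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  stopifnot(nrow(terms) == length(coefficients))
  rownames(terms) <- apply(terms, 1, function(p) term_label(p[1], p[2]))
  names(coefficients) <- rownames(terms)
  k <- max(terms[, 1], 1)
  t <- max(terms[, 2], 1)
  structure(
    list(scale = norm_scale(scale), k = k, t = t, terms = terms,
         coefficients = coefficients, intercept = intercept,
         fit = list(R2 = NA_real_, adjR2 = NA_real_, Cp = NA_real_,
                    BIC = NA_real_, rss = NA_real_),
         raw_range = raw_range, age_range = age_range, weighted = FALSE),
    class = "norm_model")
}

#' The identity norm model (raw = norm)
#'
#' A degenerate reference model whose predicted raw score equals the norm
#' score at every age. Useful for verifying table generation, inversion and
#' consistency checking.
#'
#' @inheritParams make_norm_model
#' @return A `norm_model` with the single term `(1, 0)` and coefficient 1.
#' @export
identity_model <- function(scale = "T", raw_range = c(0, 100),
                           age_range = c(2, 18)) {
  make_norm_model(rbind(c(1, 0)), 1, intercept = 0, scale = scale,
                  raw_range = raw_range, age_range = age_range)
}
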