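#' Norm score scales
#'
#' A norm scale is a linear transformation of the standard normal score:
#' `norm = mean + sd * qnorm(percentile)`. The conventional scales are
#' T scores (M = 50, SD = 10, the default throughout the package), z scores
#' (0, 1) and IQ scores (100, 15); any custom `c(mean, sd)` with positive
#' `sd` is accepted.
#'
#' @param scale `"T"`, `"z"`, `"IQ"`, a numeric `c(mean, sd)`, or an
#'   existing `norm_scale` object.
#' @return An object of class `norm_scale` with fields `name`, `mean`, `sd`.
#' @examples
#' norm_scale("IQ")
#' norm_scale(c(5, 2))  # e.g. Wechsler subtest scaled scores
#' @export
norm_scale <- function(scale = "T") {
  if (inherits(scale, "norm_scale")) return(scale)
  if (is.character(scale)) {
    known <- list(T = c(50, 10), z = c(0, 1), IQ = c(100, 15))
    key <- names(known)[match(tolower(scale[1]), tolower(names(known)))]
    if (is.na(key)) stop("unknown scale '", scale, "'; use T, z, IQ or c(mean, sd)")
    out <- list(name = key, mean = known[[key]][1], sd = known[[key]][2])
  } else if (is.numeric(scale) && length(scale) == 2) {
    if (scale[2] <= 0) stop("scale sd must be positive")
    out <- list(name = paste0("custom(", scale[1], ", ", scale[2], ")"),
                mean = scale[1], sd = scale[2])
  } else stop("invalid scale specification")
  structure(out, class = "norm_scale")
}

#' @export
print.norm_scale <- function(x, ...) {
  cat("Norm scale ", x$name, " (M = ", x$mean, ", SD = ", x$sd, ")\n",
      sep = "")
  invisible(x)
}

#' Weighted fractional ranks with midrank tie handling
#'
#' Generalises midranks to weighted samples: instead of counting cases, the
#' case weights are summed. A case with value `v` receives rank
#' `S + (T + 1) / 2`, where `S` is the total weight of cases with values
#' below `v` and `T` the total weight of cases tied at `v`. With unit
#' weights this reduces to ordinary average (mid-) ranks, and an integer
#' weight `w` acts exactly like `w` replicated cases.
#'
#' @param x Numeric vector of raw scores (no NA/NaN).
#' @param weights Optional positive weights, defaults to unit weights.
#' @return Numeric vector of ranks, aligned with `x`.
#' @examples
#' weighted_rank(c(5, 7, 7))                       # 1.0 2.5 2.5
#' weighted_rank(c(5, 7, 7), weights = c(2, 1, 1)) # 1.5 3.5 3.5
#' @export
weighted_rank <- function(x, weights = NULL) {
  if (anyNA(x) || any(!is.finite(x))) stop("raw scores must be finite")
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x))
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite")
  ux <- sort(unique(x))
  sw <- as.numeric(rowsum(weights, factor(x, levels = ux)))
  below <- cumsum(sw) - sw
  r <- below + (sw + 1) / 2
  r[match(x, ux)]
}

.rank_methods <- c(rankit = 0.5, blom = 3 / 8, tukey = 1 / 3,
                   vanderwaerden = NA_real_)

.match_rank_method <- function(method) {
  key <- gsub("[^a-z]", "", tolower(method[1]))
  m <- match(key, names(.rank_methods))
  if (is.na(m))
    stop("unknown ranking method '", method, "'; available: ",
         paste(names(.rank_methods), collapse = ", "))
  names(.rank_methods)[m]
}

#' Convert (weighted) ranks to percentiles
#'
#' Applies a standard rank-based percentile estimator with total (weighted)
#' sample size `W`: methods Rankit (c = 1/2, the default), Blom (c = 3/8)
#' and Tukey (c = 1/3) use `(r - c) / (W + 1 - 2c)`; van der Waerden uses
#' `r / (W + 1)`. Results are clamped to `(1e-10, 1 - 1e-10)` so that the
#' subsequent inverse normal transformation stays finite.
#'
#' @param rank Numeric vector of ranks, `0 < rank <= W`.
#' @param W Total weight (sum of case weights; equals n when unweighted).
#' @param method One of `"rankit"`, `"blom"`, `"tukey"`, `"vanderwaerden"`
#'   (case and punctuation insensitive).
#' @return Percentiles as fractions in (0, 1).
#' @examples
#' rank_to_percentile(1.5, 4)                           # 0.25
#' rank_to_percentile(2, 3, method = "vanderwaerden")   # 0.5
#' @export
rank_to_percentile <- function(rank, W, method = "rankit") {
  if (!is.numeric(W) || length(W) != 1 || !is.finite(W) || W <= 0)
    stop("W must be a positive number")
  if (any(rank <= 0 | rank > W + 1e-9))
    stop("ranks must lie in (0, W]")
  key <- .match_rank_method(method)
  p <- if (key == "vanderwaerden") rank / (W + 1) else {
    cc <- .rank_methods[[key]]
    (rank - cc) / (W + 1 - 2 * cc)
  }
  eps <- 1e-10
  pmin(pmax(p, eps), 1 - eps)
}

#' Inverse normal transformation
#'
#' Maps a percentile to a norm score on the given scale:
#' `mean + sd * qnorm(p)`.
#'
#' @param p Percentiles in (0, 1).
#' @param scale Norm scale (see [norm_scale()]); default T scores.
#' @return Norm scores.
#' @examples
#' int_transform(0.5)                  # 50
#' int_transform(pnorm(1), "IQ")       # 115
#' @export
int_transform <- function(p, scale = "T") {
  if (any(!is.finite(p)) || any(p <= 0 | p >= 1))
    stop("percentiles must lie strictly in (0, 1)")
  sc <- norm_scale(scale)
  sc$mean + sc$sd * qnorm(p)
}

#' Conventional weighted norming per group
#'
#' Ranks raw scores group-wise with [weighted_rank()], converts ranks to
#' percentiles with a rank-based estimator, and applies the inverse normal
#' transformation — independently within every group, typically an age
#' group. This is conventional norming; the resulting manifest norm scores
#' also serve as the person-location variable of the continuous model
#' ([fit_norm_model()]).
#'
#' @param data Data frame with at least the raw-score and grouping columns.
#' @param raw Name of the raw score column. Default `"raw"`.
#' @param group Name of the grouping column. Default `"group"`.
#' @param weights Optional positive case weights (e.g. from
#'   [raking_weights()]); defaults to unit weights.
#' @param method Percentile estimator, see [rank_to_percentile()].
#' @param scale Norm scale, see [norm_scale()].
#' @param total Denominator used in the percentile formula: `"weights"`
#'   (default) uses the summed weights of the group, `"count"` uses the
#'   case count. The two differ only through the small rank offset `c`;
#'   the choice is exposed because standardized weights inflate the summed
#'   total.
#' @return `data` with columns `weight`, `percentile` and `norm` appended,
#'   in the original row order.
#' @examples
#' d <- data.frame(raw = c(1, 2, 3, 4, 5), group = 1)
#' norm_by_group(d)$norm  # symmetric around T = 50
#' @export
norm_by_group <- function(data, raw = "raw", group = "group", weights = NULL,
                          method = "rankit", scale = "T",
                          total = c("weights", "count")) {
  total <- match.arg(total)
  for (col in c(raw, group))
    if (!col %in% names(data)) stop("column '", col, "' not found in data")
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data))
  g <- data[[group]]
  if (anyNA(g)) stop("missing group values")
  x <- data[[raw]]
  sc <- norm_scale(scale)
  perc <- numeric(nrow(data))
  for (gv in unique(g)) {
    idx <- which(g == gv)
    if (!length(idx)) stop("empty group '", gv, "'")
    if (length(unique(x[idx])) < 2)
      warning("group '", gv, "' has a single distinct raw score; ",
              "its norms are degenerate")
    r <- weighted_rank(x[idx], weights[idx])
    W <- if (total == "weights") sum(weights[idx]) else length(idx)
    perc[idx] <- rank_to_percentile(r, W, method = method)
  }
  data$weight <- weights
  data$percentile <- perc
  data$norm <- int_transform(perc, sc)
  data
}

#' Segment a continuous age variable into equal-width groups
#'
#' Bins ages into `n_groups` equal-width intervals over `age_range`
#' (left-closed, right-open, except the last interval which is closed) and
#' labels each case with the numeric midpoint of its interval. Midpoint
#' labels can be used directly as the explanatory variable of the
#' continuous norm model.
#'
#' @param age Numeric vector of ages.
#' @param n_groups Number of groups.
#' @param age_range Numeric `c(min, max)`; defaults to the observed range.
#' @return Numeric vector of interval midpoints, one per case.
#' @examples
#' age_to_group(c(2.6, 10, 17), n_groups = 15, age_range = c(2.6, 17))
#' @export
age_to_group <- function(age, n_groups, age_range = range(age)) {
  stopifnot(n_groups >= 1, length(age_range) == 2,
            age_range[1] < age_range[2])
  if (any(!is.finite(age))) stop("ages must be finite")
  out_of_range <- which(age < age_range[1] | age > age_range[2])
  if (length(out_of_range))
    stop("age outside [", age_range[1], ", ", age_range[2], "] for case(s) ",
         paste(utils::head(out_of_range, 5), collapse = ", "))
  width <- diff(age_range) / n_groups
  bin <- pmin(floor((age - age_range[1]) / width), n_groups - 1)
  age_range[1] + (bin + 0.5) * width
}
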