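# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths.

# textbook unweighted norming: midranks -> rank-based percentile -> INT
naive_norming <- function(x, method = "rankit", mean = 50, sd = 10) {
  r <- rank(x, ties.method = "average")
  n <- length(x)
  p <- switch(method,
    rankit = (r - 0.5) / n,
    blom = (r - 3 / 8) / (n + 0.25),
    tukey = (r - 1 / 3) / (n + 1 / 3),
    vanderwaerden = r / (n + 1))
  list(rank = r, percentile = p, norm = mean + sd * qnorm(p))
}

# exhaustive per-size best subsets via repeated lm fits
enumerate_best_subset <- function(X, y, w = NULL, size) {
  combs <- combn(ncol(X), size)
  best <- NULL
  best_rss <- Inf
  for (c in seq_len(ncol(combs))) {
    idx <- combs[, c]
    df <- data.frame(y = y, X[, idx, drop = FALSE])
    f <- if (is.null(w)) lm(y ~ ., data = df) else
      lm(y ~ ., data = df, weights = w)
    rss <- if (is.null(w)) sum(resid(f)^2) else sum(w * resid(f)^2)
    if (rss < best_rss) {
      best_rss <- rss
      best <- list(indices = sort(idx), rss = rss,
                   coef = coef(f))
    }
  }
  best
}

# dense brute-force scan for non-monotone intervals of a norm model
brute_force_violations <- function(model, ages, norms) {
  out <- NULL
  for (a in ages) {
    raw <- predict_raw(model, norms, a)
    bad <- which(diff(raw) <= -1e-8)
    if (length(bad))
      out <- rbind(out, data.frame(age = a, norm_lo = norms[bad],
                                   norm_hi = norms[bad + 1]))
  }
  out
}

# location quantile of a two-component normal stratum mixture
mixture_quantile <- function(p, props, means, sd) {
  uniroot(function(l) sum(props * pnorm(l, means, sd)) - p,
          c(min(means) - 8 * sd, max(means) + 8 * sd), tol = 1e-10)$root
}

# population spec without performance differences between strata
homogeneous_spec <- function(...) {
  population_spec(strata = data.frame(sex = c("male", "female"),
                                      proportion = c(0.51, 0.49),
                                      shift = c(0, 0)), ...)
}
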