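test_that("the design matrix enumerates location/age power products", {
  X <- build_design(c(40, 50), c(3, 4), k = 1, t = 1)
  expect_identical(colnames(X), c("A1", "L1", "L1A1"))
  expect_equal(X[, "L1A1"], c(120, 200))
  X2 <- build_design(rnorm(5), rnorm(5), k = 5, t = 3)
  expect_identical(ncol(X2), 23L)
  X3 <- build_design(rep(0, 3), c(1, 2, 3), k = 2, t = 1)
  pw <- attr(X3, "powers")
  expect_true(all(X3[, pw[, "i"] >= 1] == 0))
  expect_error(build_design(1, 1, k = 0, t = 1), "at least 1")
})

test_that("a noiseless single-term response is recovered exactly", {
  set.seed(4)
  l <- rnorm(100, 50, 10); a <- runif(100, 2, 17)
  y <- 2 + 3 * l * a
  X <- build_design(l, a, k = 2, t = 2)
  seqm <- best_subset(X, y, max_terms = 1)
  m <- seqm[[1]]
  expect_identical(rownames(m$terms), "L1A1")
  expect_equal(m$fit$R2, 1, tolerance = 1e-10)
  expect_equal(unname(m$coefficients), 3, tolerance = 1e-8)
  expect_equal(m$intercept, 2, tolerance = 1e-6)
})

test_that("best subsets match exhaustive least-squares enumeration", {
  set.seed(12)
  n <- 60
  l <- rnorm(n, 50, 10); a <- runif(n, 2, 17)
  X <- build_design(l, a, k = 2, t = 1)  # 5 columns
  y <- 5 + 0.4 * a + 0.02 * l * a + 1e-4 * l^2 * a + rnorm(n, 0, 2)
  for (w in list(NULL, runif(n, 0.5, 3))) {
    seqm <- best_subset(X, y, weights = w, max_terms = 4)
    for (s in 1:4) {
      oracle <- enumerate_best_subset(X, y, w, s)
      got <- sort(match(names(seqm[[s]]$coefficients), colnames(X)))
      expect_identical(got, oracle$indices)
      expect_equal(seqm[[s]]$fit$rss, oracle$rss, tolerance = 1e-8)
    }
  }
})

test_that("rescaling all weights leaves coefficients and R2 unchanged", {
  set.seed(8)
  n <- 80
  l <- rnorm(n, 50, 10); a <- runif(n, 2, 17)
  X <- build_design(l, a, k = 2, t = 1)
  y <- 1 + 0.5 * a + 0.03 * l * a + rnorm(n)
  w <- runif(n, 0.5, 2)
  s1 <- best_subset(X, y, weights = w, max_terms = 3)
  s2 <- best_subset(X, y, weights = 2 * w, max_terms = 3)
  for (s in 1:3) {
    expect_equal(s1[[s]]$coefficients, s2[[s]]$coefficients,
                 tolerance = 1e-10)
    expect_equal(s1[[s]]$fit$R2, s2[[s]]$fit$R2, tolerance = 1e-12)
  }
})

test_that("integer-weighted regression equals the replicated-sample fit", {
  set.seed(19)
  n <- 50
  l <- rnorm(n, 50, 10); a <- runif(n, 2, 17)
  y <- 3 + 0.4 * a + 0.02 * l * a + rnorm(n)
  w <- sample(1:4, n, replace = TRUE)
  X <- build_design(l, a, k = 2, t = 1)
  idx <- rep(seq_len(n), w)
  Xr <- build_design(l[idx], a[idx], k = 2, t = 1)
  s1 <- best_subset(X, y, weights = w, max_terms = 3)
  s2 <- best_subset(Xr, y[idx], max_terms = 3)
  for (s in 1:3) {
    expect_identical(names(s1[[s]]$coefficients),
                     names(s2[[s]]$coefficients))
    expect_equal(s1[[s]]$coefficients, s2[[s]]$coefficients,
                 tolerance = 1e-10)
  }
})

test_that("R2 is non-decreasing in model size", {
  set.seed(3)
  n <- 120
  l <- rnorm(n, 50, 10); a <- runif(n, 2, 17)
  y <- 10 + a + 0.05 * l * a + 2e-5 * l^2 * a^2 + rnorm(n, 0, 3)
  X <- build_design(l, a, k = 3, t = 2)
  seqm <- best_subset(X, y, max_terms = 6)
  r2 <- vapply(seqm, function(m) m$fit$R2, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("model selection takes the smallest model above the threshold", {
  fake <- function(r2, s) {
    m <- identity_model()
    m$coefficients <- setNames(rep(1, s), paste0("L", seq_len(s)))
    m$fit$R2 <- r2
    m
  }
  seqm <- structure(list(fake(0.95, 1), fake(0.992, 2), fake(0.995, 3)),
                    class = "norm_model_sequence")
  expect_equal(select_model(seqm)$fit$R2, 0.992)
  expect_warning(sel <- select_model(seqm, threshold = 1),
                 "largest")
  expect_equal(sel$fit$R2, 0.995)
})

test_that("fit indices match standard formulas on a small fixture", {
  set.seed(6)
  n <- 10
  l <- rnorm(n, 50, 10); a <- runif(n, 2, 17)
  X <- build_design(l, a, k = 2, t = 1)
  y <- 2 + 0.3 * a + 0.01 * l * a + rnorm(n)
  seqm <- best_subset(X, y, max_terms = 5)
  p <- ncol(X)
  sigma2_full <- sum(resid(lm(y ~ X))^2) / (n - p - 1)
  for (s in c(2, 3)) {
    m <- seqm[[s]]
    f <- lm(y ~ X[, names(m$coefficients)])
    rss <- sum(resid(f)^2)
    expect_equal(m$fit$R2, summary(f)$r.squared, tolerance = 1e-8)
    expect_equal(m$fit$adjR2, summary(f)$adj.r.squared, tolerance = 1e-8)
    expect_equal(m$fit$Cp, rss / sigma2_full - n + 2 * (s + 1),
                 tolerance = 1e-6)
    expect_equal(m$fit$BIC, n * log(rss / n) + (s + 1) * log(n),
                 tolerance = 1e-6)
    # recomputation from the stored model agrees
    fi <- fit_indices(m, X, y, sigma2_full = sigma2_full)
    expect_equal(fi$R2, m$fit$R2, tolerance = 1e-10)
    expect_equal(fi$Cp, m$fit$Cp, tolerance = 1e-6)
  }
  # algebraic identity: the full model has Cp = s + 1
  expect_equal(seqm[[p]]$fit$Cp, p + 1, tolerance = 1e-6)
})

test_that("the consistency check accepts monotone and locates non-monotone models", {
  clean <- check_consistency(identity_model())
  expect_true(clean$clean)
  expect_identical(clean$message,
                   "No violations of model consistency found.")
  # raw = -l decreases everywhere
  dec <- make_norm_model(rbind(c(1, 0)), -1, age_range = c(2, 18))
  rep_dec <- check_consistency(dec)
  expect_false(rep_dec$clean)
  expect_equal(length(unique(rep_dec$violations$age)), 50)
  # raw = l + c l^2 a turns non-monotone only at large ages
  # (derivative 1 + 2 c l a < 0 once l * a > 625)
  m <- make_norm_model(rbind(c(1, 0), c(2, 1)), c(1, -8e-4),
                       age_range = c(2, 18))
  ages <- seq(2, 18, length.out = 40)
  norms <- seq(25, 75, by = 0.5)
  got <- check_consistency(m, ages = ages, norms = norms)
  want <- brute_force_violations(m, ages, norms)
  expect_false(got$clean)
  expect_equal(nrow(got$violations), nrow(want))
  expect_equal(sort(unique(got$violations$age)), sort(unique(want$age)))
  expect_gt(min(got$violations$age), 8)  # only large ages affected
})

test_that("unit weights and no weights give identical fits", {
  spec <- homogeneous_spec()
  d <- generate_population(spec, n = 1500, seed = 5)
  d$group <- age_to_group(d$age, 8, spec$age_range)
  f1 <- suppressWarnings(fit_norm_model(d, k = 3, t = 2))
  f2 <- suppressWarnings(fit_norm_model(d, weights = rep(1, nrow(d)),
                                        k = 3, t = 2))
  expect_equal(f1$model$coefficients, f2$model$coefficients)
  expect_equal(f1$model$intercept, f2$model$intercept)
})

test_that("the fitted pipeline recovers a generating model's curves", {
  spec <- homogeneous_spec()
  d <- generate_population(spec, n = 3000, seed = 21)
  d$group <- age_to_group(d$age, 12, spec$age_range)
  fit <- suppressWarnings(fit_norm_model(d))
  g <- expand.grid(a = seq(2.6, 17, length.out = 30),
                   T = c(30, 40, 50, 60, 70))
  err <- predict_raw(fit$model, g$T, g$a) -
    predict_raw(spec$truth, g$T, g$a)
  expect_lt(sqrt(mean(err^2)), spec$noise_sd)
  expect_true(fit$consistency$clean)
})

test_that("small groups trigger a warning and fixed term counts are honoured", {
  spec <- homogeneous_spec()
  d <- generate_population(spec, n = 400, seed = 13)
  d$group <- age_to_group(d$age, 5, spec$age_range)
  expect_warning(fit_norm_model(d, k = 2, t = 1, terms = 2),
                 "fewer than 100")
  fit <- suppressWarnings(fit_norm_model(d, k = 3, t = 2, terms = 4))
  expect_identical(length(fit$model$coefficients), 4L)
})

test_that("the four-term vocabulary-style model form is representable and selectable", {
  spec <- homogeneous_spec()
  d <- generate_population(spec, n = 3000, seed = 33)
  d$group <- age_to_group(d$age, 12, spec$age_range)
  fit <- suppressWarnings(fit_norm_model(d, terms = 4))
  expect_identical(length(fit$model$coefficients), 4L)
  # the generating terms a, la, l^2a^2, l^3a^3 are all within k=5, t=3
  expect_true(all(rownames(spec$truth$terms) %in%
                    colnames(build_design(1, 1, 5, 3))))
})
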