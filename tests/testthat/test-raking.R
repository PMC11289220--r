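test_that("marginal targets are validated", {
  tg <- marginal_targets(list(sex = c(w = 0.4, m = 0.6)))
  expect_s3_class(tg, "marginal_targets")
  expect_error(marginal_targets(list(sex = c(w = 0.4, m = 0.5))),
               "sum to 1")
  expect_error(marginal_targets(list(sex = c(w = 1.2, m = -0.2))),
               "positive")
  expect_error(marginal_targets(
    data.frame(variable = "sex", level = c("w", "w"),
               proportion = c(0.5, 0.5))), "duplicated")
})

test_that("a single marginal adjustment reproduces the worked-example sex step", {
  d <- worked_example_cases()
  w <- adjust_to_marginal(d, rep(1, nrow(d)), "sex", worked_example_targets())
  by_sex <- tapply(w, d$sex, unique)
  expect_equal(round(by_sex[["women"]], 4), 0.9290)
  expect_equal(round(by_sex[["men"]], 4), 1.0759)
  # afterwards the sex marginals match the targets to machine precision
  expect_equal(sum(w[d$sex == "women"]) / sum(w), 0.48, tolerance = 1e-12)
})

test_that("adjustment factors are ratios of target to sample proportion", {
  d <- data.frame(g = rep(c("a", "b"), each = 50))
  tg <- marginal_targets(list(g = c(a = 0.6, b = 0.4)))
  w <- adjust_to_marginal(d, rep(1, 100), "g", tg)
  expect_equal(unique(w[d$g == "a"]), 1.2)
  expect_equal(unique(w[d$g == "b"]), 0.8)
  # already matching -> unchanged
  tg2 <- marginal_targets(list(g = c(a = 0.5, b = 0.5)))
  expect_equal(adjust_to_marginal(d, rep(1, 100), "g", tg2), rep(1, 100))
})

test_that("adjustment errors name missing or empty levels", {
  d <- data.frame(g = c("a", "b", "c"))
  tg <- marginal_targets(list(g = c(a = 0.5, b = 0.5)))
  expect_error(adjust_to_marginal(d, rep(1, 3), "g", tg), "c")
  d2 <- data.frame(g = c("a", "a"))
  expect_error(adjust_to_marginal(d2, rep(1, 2), "g", tg), "collapsing")
  expect_error(adjust_to_marginal(d, c(1, -1, 1), "g", tg), "positive")
  d3 <- data.frame(g = c("a", NA))
  expect_error(adjust_to_marginal(d3, rep(1, 2), "g", tg), "missing")
})

test_that("raking converges to the worked-example cell weights", {
  d <- worked_example_cases()
  res <- rake(d, worked_example_targets(), order = c("sex", "education"))
  expect_true(res$report$converged)
  cells <- tapply(res$weights, paste(d$sex, d$education), unique)
  printed <- c(`women low` = 1.0516, `women medium` = 0.8347,
               `women high` = 0.9249, `men low` = 1.1938,
               `men medium` = 0.9475, `men high` = 1.0499)
  expect_equal(cells[names(printed)], printed, tolerance = 3e-4,
               ignore_attr = TRUE)
})

test_that("an already representative sample gets unit weights in one cycle", {
  d <- data.frame(g = rep(c("a", "b"), c(60, 40)))
  tg <- marginal_targets(list(g = c(a = 0.6, b = 0.4)))
  res <- rake(d, tg)
  expect_equal(res$weights, rep(1, 100))
  expect_identical(res$report$iterations, 1L)
})

test_that("raking matches a direct numerical solve of the margin equations", {
  # 2x2 joint table: the IPF fixed point factorizes as w_ij = r_i * c_j
  set.seed(31)
  for (rep in 1:5) {
    counts <- matrix(sample(20:120, 4), 2,
                     dimnames = list(A = c("a1", "a2"), B = c("b1", "b2")))
    pa <- runif(1, 0.3, 0.7)
    pb <- runif(1, 0.3, 0.7)
    tg <- marginal_targets(list(A = c(a1 = pa, a2 = 1 - pa),
                                B = c(b1 = pb, b2 = 1 - pb)))
    d <- expand.grid(A = rownames(counts), B = colnames(counts),
                     stringsAsFactors = FALSE)
    d <- d[rep(seq_len(4), as.vector(counts)), ]
    N <- sum(counts)
    # oracle: solve the margin equations for log row/col factors
    obj <- function(th) {
      r <- exp(c(th[1], th[2])); cc <- exp(c(th[3], th[4]))
      W <- counts * outer(r, cc)
      sum((rowSums(W) / sum(W) - c(pa, 1 - pa))^2 +
            (colSums(W) / sum(W) - c(pb, 1 - pb))^2)
    }
    th <- optim(rep(0, 4), obj, method = "BFGS",
                control = list(reltol = 1e-16, maxit = 1000))$par
    Wcell <- counts * outer(exp(th[1:2]), exp(th[3:4]))
    Wcell <- Wcell * N / sum(Wcell)
    res <- rake(d, tg, tol = 1e-10)
    got <- tapply(res$weights, paste(d$A, d$B), unique)
    want <- as.vector(Wcell / counts)
    names(want) <- as.vector(outer(rownames(counts), colnames(counts), paste))
    expect_equal(got[names(want)], want, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("the raking fixed point does not depend on the adjustment order", {
  d <- worked_example_cases(10000)
  tg <- worked_example_targets()
  r1 <- rake(d, tg, order = c("sex", "education"), tol = 1e-10)
  r2 <- rake(d, tg, order = c("education", "sex"), tol = 1e-10)
  expect_equal(r1$weights, r2$weights, tolerance = 1e-6)
})

test_that("non-convergence is flagged, not raised", {
  d <- worked_example_cases()
  res <- rake(d, worked_example_targets(), max_iter = 1)
  expect_false(res$report$converged)
  expect_identical(res$report$iterations, 1L)
  expect_warning(raking_weights(d, worked_example_targets(), max_iter = 1),
                 "did not converge")
})

test_that("standardization divides by the minimum weight", {
  expect_equal(standardize_weights(c(2, 4)), c(1, 2))
  expect_equal(standardize_weights(c(0.7, 0.7)), c(1, 1))
  expect_equal(standardize_weights(c(0.5, 1, 2)), c(1, 2, 4))
  expect_error(standardize_weights(c(1, 0)), "positive")
  expect_error(standardize_weights(numeric(0)), "empty")
})

test_that("representativeness deviations are signed sample minus target", {
  d <- data.frame(lang = rep(c("english", "french", "other"),
                             c(70, 10, 20)))
  tg <- marginal_targets(list(lang = c(english = 0.55, french = 0.21,
                                       other = 0.24)))
  rep_tab <- check_representativeness(d, tg)
  eng <- rep_tab[rep_tab$level == "english", ]
  expect_equal(eng$deviation, 0.15)
  # matching sample -> zero deviations
  d2 <- data.frame(lang = rep(c("english", "french", "other"),
                              c(55, 21, 24)))
  expect_equal(check_representativeness(d2, tg)$deviation, rep(0, 3))
  # after raking, deviations are below the tolerance
  res <- rake(d, tg)
  post <- check_representativeness(d, tg, res$weights)
  expect_lt(max(abs(post$deviation)), 1e-6)
  # unknown levels are reported with NA target, not raised
  d3 <- data.frame(lang = c(rep("english", 5), "german"))
  rep3 <- check_representativeness(d3, tg)
  expect_true(is.na(rep3$target_proportion[rep3$level == "german"]))
})

test_that("effective sample size follows the Kish formula", {
  expect_equal(effective_sample_size(rep(1, 10)), 10)
  expect_equal(effective_sample_size(c(1, 3)), 1.6)
  set.seed(5)
  for (i in 1:10) {
    w <- runif(sample(2:50, 1), 0.2, 5)
    expect_lte(effective_sample_size(w), length(w) + 1e-12)
  }
  expect_error(effective_sample_size(numeric(0)), "empty")
})

test_that("weighted marginals match targets exactly after each adjustment", {
  set.seed(17)
  for (i in 1:10) {
    n <- 200
    d <- data.frame(A = sample(letters[1:3], n, replace = TRUE),
                    B = sample(c("x", "y"), n, replace = TRUE))
    pa <- runif(3); pa <- pa / sum(pa)
    tg <- marginal_targets(list(A = c(a = pa[1], b = pa[2], c = pa[3])))
    w <- runif(n, 0.5, 2)
    w2 <- adjust_to_marginal(d, w, "A", tg)
    props <- tapply(w2, d$A, sum) / sum(w2)
    expect_equal(as.numeric(props[c("a", "b", "c")]), pa,
                 tolerance = 1e-12)
    expect_equal(length(w2), n)
  }
})
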