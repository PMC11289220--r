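#' Default ground-truth norm model for simulations
#'
#' A fixed monotone model of the form
#' `raw = 28.32 + 3.797 a + 0.05 l a + 2e-5 l^2 a^2 - 1.6e-8 l^3 a^3`
#' (location `l` in T scores, age `a` in years): the four-term structure
#' `a + la + l^2 a^2 + l^3 a^3` that continuous norming typically selects
#' for vocabulary-type scales. The median curve rises concavely from raw 45
#' at age 2.6 to raw 140 at age 17, the between-person spread grows roughly
#' linearly with age (about 0.5 raw points per T-score point at age 10),
#' and the negative cubic term adds a mild ceiling. The model is strictly
#' increasing in `l` over T 20-80 at every age in range, and all simulated
#' scores stay well inside the 0-228 raw-score bounds of the emulated
#' scale.
#'
#' @return A `norm_model`.
#' @export
truth_model <- function() {
  make_norm_model(rbind(c(0, 1), c(1, 1), c(2, 2), c(3, 3)),
                  c(3.797, 0.05, 2e-5, -1.6e-8), intercept = 28.32,
                  scale = "T", raw_range = c(0, 228),
                  age_range = c(2.6, 17))
}

#' Specification of a synthetic reference population
#'
#' Describes a population from which normative samples can be simulated
#' with known ground truth: a generating norm model, strata defined by
#' stratification variables with population proportions and mean
#' performance shifts, an age distribution and a raw-score noise level.
#'
#' The default emulates a vocabulary-development normative study: N-scale
#' raw scores 0-228 over ages 2.6-17.0 (uniform), stratification by sex
#' (51% male / 49% female, no performance difference) and migration
#' background (70% native / 30% non-native, with a -0.5 SD location shift
#' for non-native speakers, a typical receptive-vocabulary disadvantage),
#' and residual raw-score noise with SD 2.
#'
#' @param truth Generating `norm_model`; must be strictly increasing in the
#'   location over T 20-80 at all ages in `age_range`.
#' @param strata Data frame of stratification-variable columns plus
#'   `proportion` (summing to 1) and `shift` (location shift in scale SD
#'   units).
#' @param age_range Numeric `c(min, max)` in years.
#' @param age_shape Beta-distribution shape parameters `c(a, b)` for the
#'   (rescaled) age distribution; `c(1, 1)` is uniform.
#' @param noise_sd SD of the additive raw-score noise, in raw points.
#' @param raw_range Attainable raw scores; simulated scores are clipped.
#' @param round_raw Round simulated raw scores to integers (discrete test
#'   scores). Default `TRUE`.
#' @param location_sd SD of the true person locations around their stratum
#'   mean, in scale units; defaults to the scale SD. Zero gives a
#'   degenerate population whose cases all sit exactly on their stratum's
#'   curve (useful for exactness checks).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(truth = truth_model(),
                            strata = NULL,
                            age_range = c(2.6, 17),
                            age_shape = c(1, 1),
                            noise_sd = 2,
                            raw_range = c(0, 228),
                            round_raw = TRUE,
                            location_sd = NULL) {
  if (is.null(strata)) {
    strata <- expand.grid(sex = c("male", "female"),
                          migration = c("native", "non-native"),
                          stringsAsFactors = FALSE)
    strata$proportion <- c(0.51, 0.49, 0.51, 0.49) *
      c(0.70, 0.70, 0.30, 0.30)
    strata$shift <- c(0, 0, -0.5, -0.5)
  }
  stopifnot(is.data.frame(strata),
            all(c("proportion", "shift") %in% names(strata)))
  if (abs(sum(strata$proportion) - 1) > 1e-9)
    stop("strata proportions must sum to 1")
  if (any(strata$proportion <= 0)) stop("strata proportions must be > 0")
  sc <- truth$scale
  cons <- check_consistency(
    truth, ages = seq(age_range[1], age_range[2], length.out = 60),
    norms = seq(sc$mean - 3 * sc$sd, sc$mean + 3 * sc$sd, by = 0.05 * sc$sd))
  if (!cons$clean)
    stop("generating model is not monotone in the location over the ",
         "simulated range; choose different coefficients")
  if (is.null(location_sd)) location_sd <- sc$sd
  stopifnot(location_sd >= 0)
  structure(list(truth = truth, strata = strata, age_range = age_range,
                 age_shape = age_shape, noise_sd = noise_sd,
                 raw_range = raw_range, round_raw = round_raw,
                 location_sd = location_sd),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Synthetic population: ages ", x$age_range[1], "-", x$age_range[2],
      ", raw ", x$raw_range[1], "-", x$raw_range[2],
      ", noise SD ", x$noise_sd, "\n", sep = "")
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Simulate a population of test cases with known ground truth
#'
#' Draws `n` cases from a [population_spec()]: an age from the (beta-shaped)
#' age distribution, a stratum by its population proportion, a true person
#' location `~ Normal(mean + shift * sd, sd)` on the model's scale, and a
#' raw score `predict_raw(truth, location, age)` plus Gaussian noise,
#' rounded and clipped to the raw range. The hidden column `true_location`
#' is included for evaluation only and is not used by any norming routine.
#'
#' @param spec A `population_spec`.
#' @param n Number of cases.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   table exactly.
#' @return Data frame with the stratification-variable columns of the spec,
#'   plus `age`, `true_location`, `raw` and `stratum` (row index into
#'   `spec$strata`).
#' @export
generate_population <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sc <- spec$truth$scale
  age <- spec$age_range[1] + diff(spec$age_range) *
    rbeta(n, spec$age_shape[1], spec$age_shape[2])
  stratum <- sample.int(nrow(spec$strata), n, replace = TRUE,
                        prob = spec$strata$proportion)
  shift <- spec$strata$shift[stratum]
  loc <- rnorm(n, mean = sc$mean + shift * sc$sd, sd = spec$location_sd)
  raw <- predict_raw(spec$truth, loc, age) +
    rnorm(n, 0, spec$noise_sd)
  if (spec$round_raw) raw <- round(raw)
  raw <- pmin(pmax(raw, spec$raw_range[1]), spec$raw_range[2])
  sv <- spec$strata[stratum,
                    setdiff(names(spec$strata), c("proportion", "shift")),
                    drop = FALSE]
  rownames(sv) <- NULL
  cbind(sv, data.frame(age = age, true_location = loc, raw = raw,
                       stratum = stratum))
}

#' Draw a non-representative sample from a simulated population
#'
#' Samples `n` cases without replacement with inclusion probabilities
#' proportional to a per-level factor of one stratification variable,
#' emulating field conditions in which some strata (e.g. non-native
#' speakers) are systematically harder to recruit. Levels with inclusion 1
#' are sampled at the base rate; a level with inclusion 0.5 is
#' under-included roughly 2:1.
#'
#' @param population Data frame from [generate_population()].
#' @param inclusion Named numeric vector of strictly positive relative
#'   inclusion probabilities, named by the levels of `by`.
#' @param n Sample size; must not exceed the population size.
#' @param by Name of the stratification column the inclusion factors refer
#'   to. Default `"migration"`.
#' @param seed Optional integer seed.
#' @return A data frame of `n` sampled rows.
#' @export
biased_sample <- function(population, inclusion, n, by = "migration",
                          seed = NULL) {
  if (!by %in% names(population))
    stop("column '", by, "' not found in population")
  if (n > nrow(population))
    stop("sample size exceeds population size")
  lev <- as.character(population[[by]])
  missing_lev <- setdiff(unique(lev), names(inclusion))
  if (length(missing_lev))
    stop("no inclusion probability for level(s): ",
         paste(missing_lev, collapse = ", "))
  if (any(inclusion <= 0)) stop("inclusion probabilities must be > 0")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(population), n,
                    prob = as.numeric(inclusion[lev]))
  population[idx, , drop = FALSE]
}

# Joint sample composition (percent) of the two-variable worked example:
# education (rows low/medium/high) by sex (columns women/men).  The
# medium/men cell is 15.83, the unique value consistent with the marginal
# sums (35.00 medium, 48.33 men).
.worked_example_pct <- matrix(
  c(15.33, 20.00,
    19.17, 15.83,
    17.17, 12.50) / 100,
  nrow = 3, byrow = TRUE,
  dimnames = list(c("low", "medium", "high"), c("women", "men")))

#' Two-variable worked-example normative sample
#'
#' Emits a case table whose joint composition over sex (women/men) and
#' parental education (low/medium/high) realises the classic raking
#' illustration: sample marginals 51.67% women / 48.33% men and 35.33% /
#' 35.00% / 29.67% education, to be raked to population targets
#' 48% / 52% and 40% / 31% / 29%.
#'
#' @param N Number of cases; every joint cell percentage times `N` must be
#'   an integer (the default 10000 gives cells 1533, 2000, 1917, 1583,
#'   1717, 1250).
#' @return Data frame with character columns `sex` and `education`.
#' @export
worked_example_cases <- function(N = 10000) {
  cells <- .worked_example_pct * N
  if (any(abs(cells - round(cells)) > 1e-6))
    stop("N = ", N, " yields non-integer cell counts; ",
         "use a multiple of 10000")
  cells <- round(cells)
  out <- do.call(rbind, lapply(rownames(cells), function(ed)
    do.call(rbind, lapply(colnames(cells), function(sx)
      if (cells[ed, sx] > 0)
        data.frame(sex = rep(sx, cells[ed, sx]), education = ed,
                   stringsAsFactors = FALSE)))))
  rownames(out) <- NULL
  out
}

#' Marginal targets of the worked example
#'
#' The population marginals paired with [worked_example_cases()]:
#' sex 48% women / 52% men, parental education 40% low / 31% medium /
#' 29% high.
#'
#' @return A [marginal_targets] object.
#' @export
worked_example_targets <- function() {
  marginal_targets(list(
    sex = c(women = 0.48, men = 0.52),
    education = c(low = 0.40, medium = 0.31, high = 0.29)))
}
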