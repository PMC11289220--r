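#' Read population marginals from a JSON or YAML file
#'
#' The file maps each stratification variable to its level proportions,
#' e.g. `{"sex": {"female": 0.49, "male": 0.51}}`. The result is validated
#' against the [marginal_targets()] invariants (positive proportions
#' summing to 1 per variable).
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A [marginal_targets] object.
#' @export
read_marginals <- function(path) {
  if (!file.exists(path)) stop("marginals file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("package 'yaml' is required to read YAML marginals")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  marginal_targets(lapply(x, unlist))
}

#' Read case-level normative data from a delimited text file
#'
#' Reads a CSV (or TSV, by extension) with a header row; stratification
#' variables are kept as character strings verbatim, numbers are parsed
#' with a `.` decimal point regardless of locale.
#'
#' @param path Path to the file.
#' @return A data frame.
#' @export
read_cases <- function(path) {
  if (!file.exists(path)) stop("cases file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  d <- read.csv(path, sep = sep, colClasses = "character",
                check.names = FALSE, fileEncoding = "UTF-8")
  # convert unambiguously numeric columns; everything else stays verbatim
  num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"
  for (col in names(d)) {
    v <- d[[col]]
    ok <- v == "" | (grepl(num_re, v) & !grepl("^[+-]?0[0-9]", v))
    if (all(ok) && any(v != ""))
      d[[col]] <- as.numeric(ifelse(v == "", NA, v))
  }
  d
}

#' Serialize a norm model to JSON
#'
#' Writes every component needed to reconstruct the model exactly: scale,
#' power parameters, selected terms as `(i, j)` pairs, coefficients,
#' intercept, fit indices, raw and age ranges, and whether weights were
#' used in the fit. [read_norm_model()] round-trips the file.
#'
#' @param model A `norm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_norm_model <- function(model, path) {
  obj <- list(
    scale = list(name = model$scale$name, mean = model$scale$mean,
                 sd = model$scale$sd),
    k = model$k, t = model$t,
    terms = lapply(seq_len(nrow(model$terms)),
                   function(r) as.integer(model$terms[r, ])),
    coefficients = as.numeric(model$coefficients),
    intercept = model$intercept,
    fit = model$fit,
    raw_range = model$raw_range,
    age_range = model$age_range,
    weighted = isTRUE(model$weighted))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a norm model from JSON
#'
#' @param path Path written by [write_norm_model()].
#' @return A `norm_model`.
#' @export
read_norm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  m <- make_norm_model(
    terms = lapply(obj$terms, function(p) c(p[[1]], p[[2]])),
    coefficients = vapply(obj$coefficients, as.numeric, numeric(1)),
    intercept = obj$intercept,
    scale = c(obj$scale$mean, obj$scale$sd),
    raw_range = vapply(obj$raw_range, as.numeric, numeric(1)),
    age_range = vapply(obj$age_range,
                       function(x) if (is.null(x)) NA_real_ else as.numeric(x),
                       numeric(1)))
  m$scale$name <- obj$scale$name
  m$k <- obj$k
  m$t <- obj$t
  m$fit <- lapply(obj$fit, function(x) if (is.null(x)) NA_real_ else x)
  m$weighted <- isTRUE(obj$weighted)
  m
}

#' Validate a normative sample before weighting and norming
#'
#' Emits the recommended plausibility warnings: age groups with fewer than
#' `min_group_n` cases (norms per group become unstable), and targeted
#' strata whose population or sample share falls below `min_share`
#' (severely under-represented strata lead to high raking weights; sparse
#' levels should be collapsed).
#'
#' @param data Case data frame.
#' @param group Optional grouping column name.
#' @param targets Optional [marginal_targets].
#' @param weights Optional case weights for the sample shares.
#' @param min_group_n Group-size threshold, default 100.
#' @param min_share Stratum-share threshold, default 0.05.
#' @return Invisibly, a list with `group_sizes` and `representativeness`
#'   (from [check_representativeness()], or `NULL`).
#' @export
validate_norm_sample <- function(data, group = NULL, targets = NULL,
                                 weights = NULL, min_group_n = 100,
                                 min_share = 0.05) {
  group_sizes <- NULL
  if (!is.null(group)) {
    group_sizes <- table(data[[group]])
    small <- names(group_sizes)[group_sizes < min_group_n]
    if (length(small))
      warning("group(s) with fewer than ", min_group_n, " cases: ",
              paste(small, collapse = ", "), call. = FALSE)
  }
  rep_tab <- NULL
  if (!is.null(targets)) {
    rep_tab <- check_representativeness(data, targets, weights)
    sparse <- rep_tab[!is.na(rep_tab$target_proportion) &
                        (rep_tab$target_proportion < min_share |
                           rep_tab$sample_proportion < min_share), ]
    if (nrow(sparse))
      warning("stratum share below ", min_share * 100, "%: ",
              paste0(sparse$variable, "=", sparse$level, collapse = ", "),
              "; consider collapsing sparse levels", call. = FALSE)
  }
  invisible(list(group_sizes = group_sizes, representativeness = rep_tab))
}

.write_manifest <- function(outdir, config, inputs) {
  inputs <- inputs[vapply(inputs, function(f)
    is.character(f) && file.exists(f), logical(1))]
  hashes <- lapply(inputs, function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(
    list(package = "rakenorm",
         version = as.character(utils::packageVersion("rakenorm")),
         config = config, input_md5 = hashes),
    file.path(outdir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
}

.csv_write <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Command: compute raking weights for a cases file
#'
#' File-level entry point for the weighting step: reads cases and
#' marginals, rakes, standardizes, and writes `weighted_cases.csv` (the
#' input plus a `weight` column), `raking_report.json` and a run manifest
#' into `outdir`.
#'
#' @param input Path to the cases CSV/TSV.
#' @param marginals Path to the marginals JSON/YAML.
#' @param outdir Output directory (created if needed).
#' @param order,tol,max_iter Passed to [rake()].
#' @return Exit status, invisibly: 0 on convergence, 3 on non-convergence.
#' @export
cli_rake <- function(input, marginals, outdir = ".", order = NULL,
                     tol = 1e-6, max_iter = 50) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cases <- read_cases(input)
  targets <- read_marginals(marginals)
  validate_norm_sample(cases, targets = targets)
  res <- raking_weights(cases, targets, order = order, tol = tol,
                        max_iter = max_iter)
  cases$weight <- res$weights
  .csv_write(cases, file.path(outdir, "weighted_cases.csv"))
  jsonlite::write_json(unclass(res$report),
                       file.path(outdir, "raking_report.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(outdir, list(command = "rake", input = input,
                               marginals = marginals, order = order,
                               tol = tol, max_iter = max_iter),
                  list(input = input, marginals = marginals))
  message("Raking ", if (res$report$converged) "converged" else
    "did NOT converge", " after ", res$report$iterations, " cycle(s); ",
    "effective sample size ",
    format(effective_sample_size(res$weights), digits = 6),
    " of ", nrow(cases))
  invisible(if (res$report$converged) 0L else 3L)
}

#' Command: fit a continuous norm model from a cases file
#'
#' File-level entry point for conventional plus regression-based norming:
#' reads cases (using a `weight` column when present), fits the model,
#' and writes `normed_cases.csv`, `model.json`, `consistency.json`,
#' `percentile_curves.csv` and a run manifest into `outdir`.
#'
#' @param input Path to the cases CSV/TSV (columns: raw score, group,
#'   optionally age and `weight`).
#' @param outdir Output directory.
#' @param raw,group,age,k,t,method,scale,terms,threshold Passed to
#'   [fit_norm_model()].
#' @return Exit status, invisibly: 0 on success, 3 when the selected model
#'   has consistency violations (outputs are still written).
#' @export
cli_norm <- function(input, outdir = ".", raw = "raw", group = "group",
                     age = NULL, k = 5, t = 3, method = "rankit",
                     scale = "T", terms = NULL, threshold = 0.99) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cases <- read_cases(input)
  weights <- if ("weight" %in% names(cases)) cases$weight else NULL
  fit <- fit_norm_model(cases, raw = raw, group = group, age = age,
                        weights = weights, k = k, t = t, method = method,
                        scale = scale, terms = terms, threshold = threshold)
  .csv_write(fit$data, file.path(outdir, "normed_cases.csv"))
  write_norm_model(fit$model, file.path(outdir, "model.json"))
  jsonlite::write_json(
    list(clean = fit$consistency$clean, message = fit$consistency$message,
         violations = fit$consistency$violations),
    file.path(outdir, "consistency.json"), auto_unbox = TRUE, digits = NA)
  .csv_write(percentile_curves(fit$model),
             file.path(outdir, "percentile_curves.csv"))
  .write_manifest(outdir, list(command = "norm", input = input, raw = raw,
                               group = group, age = age, k = k, t = t,
                               method = method, scale = scale,
                               terms = terms, threshold = threshold),
                  list(input = input))
  message(fit$consistency$message)
  invisible(if (fit$consistency$clean) 0L else 3L)
}

#' Command: generate a norm table from a model file
#'
#' Reads a model JSON and writes `norm_table_age<age>.csv` with columns
#' `raw`, `norm`, `percentile`, `clamped` and `extrapolated` (flagging ages
#' outside the model's fitted range).
#'
#' @param model_path Path to a model JSON from [write_norm_model()].
#' @param age Age at which to tabulate.
#' @param outdir Output directory.
#' @param raw_step Raw-score step, default 1.
#' @return Exit status 0, invisibly.
#' @export
cli_table <- function(model_path, age, outdir = ".", raw_step = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  model <- read_norm_model(model_path)
  tab <- norm_table(model, age = age, raw_step = raw_step)
  out <- as.data.frame(tab)
  out$extrapolated <- attr(tab, "extrapolated")
  .csv_write(out, file.path(outdir,
                            paste0("norm_table_age", age, ".csv")))
  .write_manifest(outdir, list(command = "table", model = model_path,
                               age = age, raw_step = raw_step),
                  list(model = model_path))
  invisible(0L)
}

#' Command: simulate a synthetic normative sample
#'
#' Generates a population from the default [population_spec()], writes
#' `cases.csv` (the columns the norming pipeline consumes, including a
#' `group` column from [age_to_group()]) and `truth.csv` (the per-case true
#' location sidecar, for evaluation only).
#'
#' @param n Number of cases.
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param n_groups Number of age groups, default 15.
#' @return Exit status 0, invisibly.
#' @export
cli_simulate <- function(n, outdir = ".", seed = 1, n_groups = 15) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- population_spec()
  pop <- generate_population(spec, n = n, seed = seed)
  pop$group <- age_to_group(pop$age, n_groups = n_groups,
                            age_range = spec$age_range)
  keep <- setdiff(names(pop), "true_location")
  .csv_write(pop[keep], file.path(outdir, "cases.csv"))
  .csv_write(pop[c("age", "group", "true_location")],
             file.path(outdir, "truth.csv"))
  .write_manifest(outdir, list(command = "simulate", n = n, seed = seed,
                               n_groups = n_groups), list())
  invisible(0L)
}
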