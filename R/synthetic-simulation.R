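#' Simulation-study populations with two protected classes
#'
#' Generates the misspecification testbed used by the simulation studies: a
#' population with covariates `X1`...`X9`, a continuous outcome, and two
#' distinct but partially overlapping protected classes `A1` and `A2` that
#' are functions of the covariates. Three outcome forms are available:
#'
#' * `"complex"` - nonlinear and interacted: main effects plus a squared
#'   term in `X1`, an `X1:X4` interaction, and heteroscedastic noise.
#'   Paired with an estimator covariate set that omits `X1` (the main driver
#'   of the `A1` tail) this is scenario 1: strong functional-form
#'   misspecification with an omitted variable.
#' * `"simple"` - near-linear: main effects plus a mild hinge in `X1`
#'   (`3 max(X1 - 1, 0)`) and homoscedastic noise. With the full covariate
#'   set including the pure-noise columns `X6`...`X9` this is scenario 2:
#'   no omitted variables, mild misspecification, extra noise regressors.
#' * `"linear"` - purely linear in `X1`...`X5`; with `noise_sd = 0` OLS on
#'   the full covariate set recovers the coefficients exactly (a
#'   well-specified control, useful in tests).
#'
#' Class membership: `A1 = 1\{X4 = 1 or X1 > 1.2\}` and
#' `A2 = 1\{X4 = 1 or X2 > 1.2\}` - overlapping through `X4` and the joint
#' tails, distinct through the different tails. Under the scenario covariate
#' sets the unmodelled outcome terms concentrate in the `A1` tail, so OLS
#' undercompensates `A1` (positive residual covariance), the precondition
#' for the covariance-constrained estimator.
#'
#' @param config A [scenario_config()] list.
#' @return A tibble with columns `person_id`, `X1`...`X9`, `A1`, `A2`, `y`,
#'   with the configuration in `attr(, "config")`.
#' @export
generate_simulation_population <- function(config = scenario_config()) {
  n <- config$n_population
  set.seed(config$seed)
  X <- tibble(
    X1 = rnorm(n), X2 = rnorm(n), X3 = rnorm(n),
    X4 = rbinom(n, 1, 0.10), X5 = rbinom(n, 1, 0.25),
    X6 = rnorm(n), X7 = rbinom(n, 1, 0.30),
    X8 = rnorm(n), X9 = rnorm(n)
  )
  A1 <- as.integer(X$X4 == 1 | X$X1 > 1.2)
  A2 <- as.integer(X$X4 == 1 | X$X2 > 1.2)
  if (sum(A1) == 0 || sum(A2) == 0 || sum(A1) == n || sum(A2) == n) {
    abort("Degenerate protected-class rule: a class is empty (or everyone).")
  }

  eps <- rnorm(n)
  y <- switch(
    config$outcome,
    complex = 10 + 6 * X$X1 + 3 * X$X1^2 + 5 * X$X1 * X$X4 +
      8 * X$X2 + 2 * X$X3 + 8 * X$X4 + 3 * X$X5 +
      config$noise_sd * (1 + abs(X$X3)) * eps,
    simple = 10 + 5 * X$X1 + 4 * X$X2 + 2 * X$X3 + 6 * X$X4 + 3 * X$X5 +
      3 * pmax(X$X1 - 1, 0) + config$noise_sd * eps,
    linear = 10 + 5 * X$X1 + 4 * X$X2 + 2 * X$X3 + 6 * X$X4 + 3 * X$X5 +
      config$noise_sd * eps,
    abort("`outcome` must be one of 'complex', 'simple', 'linear'.")
  )

  out <- dplyr::bind_cols(tibble(person_id = seq_len(n)), X,
                          tibble(A1 = A1, A2 = A2, y = y))
  attr(out, "config") <- config
  out
}

#' Simulation scenario recipe
#'
#' Bundles the population size, outcome form, estimator covariate set
#' (the misspecification), replicate sampling plan and seed for one
#' simulation scenario.
#'
#' Scenario 1 pairs the `"complex"` outcome with estimator covariates
#' `X2`...`X7` (omitting `X1`, which drives both the outcome's nonlinear
#' terms and the `A1` tail). Scenario 2 pairs the `"simple"` outcome with
#' all nine covariates, so nothing is omitted but `X6`...`X9` are pure noise
#' and the hinge term is unmodelled.
#'
#' @param scenario 1 or 2 to load the preset recipes, or `NULL` with
#'   explicit arguments.
#' @param n_population Population size (default 100 000).
#' @param outcome Outcome form (`"complex"`, `"simple"`, `"linear"`).
#' @param estimator_covariates Covariate names handed to the estimators.
#' @param noise_sd Noise scale multiplier (default 2).
#' @param n_sample Per-replicate sample size (default 1000).
#' @param replicates Number of replicate samples (default 500).
#' @param protected Protected class evaluated by the estimators
#'   (`"A1"` or `"A2"`).
#' @param seed Integer seed.
#' @return A named list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = 1, n_population = 100000,
                            outcome = NULL, estimator_covariates = NULL,
                            noise_sd = 2, n_sample = 1000, replicates = 500,
                            protected = "A1", seed = 1) {
  if (!is.null(scenario)) {
    stopifnot(scenario %in% c(1, 2))
    if (is.null(outcome)) {
      outcome <- if (scenario == 1) "complex" else "simple"
    }
    if (is.null(estimator_covariates)) {
      estimator_covariates <- if (scenario == 1) {
        paste0("X", 2:7)
      } else {
        paste0("X", 1:9)
      }
    }
  }
  if (is.null(outcome) || is.null(estimator_covariates)) {
    abort("Provide `outcome` and `estimator_covariates` (or pick a preset `scenario`).")
  }
  structure(
    list(scenario = scenario, n_population = n_population, outcome = outcome,
         estimator_covariates = estimator_covariates, noise_sd = noise_sd,
         n_sample = n_sample, replicates = replicates, protected = protected,
         seed = seed),
    class = "scenario_config"
  )
}

#' Draw replicate samples from a simulated population
#'
#' Samples `n_sample` people without replacement, `replicates` times.
#' Replicate `r` is reproducible in isolation: its RNG stream is derived
#' from `(seed, r)`, so `draw_replicate(pop, n, seed, r)` returns the same
#' rows whether or not the other replicates are generated.
#'
#' @param population Population tibble (any one-row-per-person data frame).
#' @param n_sample Sample size per replicate.
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @param r Replicate index (1-based).
#' @return `draw_replicates()`: a list of tibbles; `draw_replicate()`: one
#'   tibble with a `replicate` attribute.
#' @export
draw_replicates <- function(population, n_sample, replicates, seed = 1) {
  purrr::map(seq_len(replicates),
             function(r) draw_replicate(population, n_sample, seed, r))
}

#' @rdname draw_replicates
#' @export
draw_replicate <- function(population, n_sample, seed, r) {
  n <- nrow(population)
  if (n_sample > n) abort("`n_sample` must not exceed the population size.")
  set.seed((seed %% 1000003L) * 2017L + r)
  out <- population[sample.int(n, n_sample), , drop = FALSE]
  attr(out, "replicate") <- r
  out
}

#' Run a simulation scenario over replicate samples
#'
#' For each replicate sample, runs the cross-validated evaluation of every
#' configuration in `grid` against the scenario's protected class using only
#' the scenario's estimator covariates, then summarises the replicate-level
#' metrics (mean and spread per configuration) and applies the
#' fairness-frontier filter - relative cross-validated R2 loss at most
#' `max_r2_loss` with improved group fairness - to the summary.
#'
#' @param config A [scenario_config()].
#' @param grid Estimator grid (default: one representative configuration per
#'   method, with `lambda = n_sample / 10`).
#' @param n_folds CV folds per replicate (default 5).
#' @param max_r2_loss Frontier ceiling on relative R2 loss (default 0.10).
#' @return A `fair_scenario` object: `replicates` (per-replicate metric
#'   rows), `summary` (per-configuration means/SDs with `on_frontier`),
#'   `config`, `grid`.
#' @examples
#' cfg <- scenario_config(1, n_population = 5000, n_sample = 500,
#'                        replicates = 3, seed = 2)
#' run_scenario(cfg)
#' @export
run_scenario <- function(config, grid = NULL, n_folds = 5,
                         max_r2_loss = 0.10) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(grid)) {
    ns <- config$n_sample
    grid <- bind_rows(
      tibble(method = "ols", param = NA_character_, value = NA_real_),
      tibble(method = "avg_constrained", param = NA_character_,
             value = NA_real_),
      tibble(method = "cov_constrained", param = "m", value = 0.2),
      tibble(method = "wavg_constrained", param = "alpha", value = 0.2),
      tibble(method = "mrd_penalized", param = "lambda", value = ns / 10),
      tibble(method = "netcomp_penalized", param = "lambda",
             value = c(ns / 100, ns / 10))
    )
  }
  population <- generate_simulation_population(config)

  reps <- purrr::map(seq_len(config$replicates), function(r) {
    sample_r <- draw_replicate(population, config$n_sample, config$seed, r)
    cv <- cross_validate(sample_r, outcome = "y", group = config$protected,
                         features = config$estimator_covariates,
                         grid = grid, n_folds = n_folds,
                         seed = config$seed + r)
    mutate(cv$metrics, replicate = r)
  }) |> list_rbind()

  summary <- reps |>
    group_by(.data$configuration, .data$method, .data$param, .data$value) |>
    summarise(dplyr::across(c("R2", "PR_g", "PR_gc", "NC_g", "NC_gc",
                              "MRD", "FairCov"),
                            list(mean = mean, sd = sd)),
              .groups = "drop") |>
    dplyr::rename_with(~ sub("_mean$", "", .x)) |>
    frontier_filter(max_r2_loss) |>
    arrange(desc(.data$NC_g))

  structure(
    list(replicates = reps, summary = summary, config = config, grid = grid,
         max_r2_loss = max_r2_loss),
    class = "fair_scenario"
  )
}

#' @export
print.fair_scenario <- function(x, ...) {
  cat("<fair_scenario> outcome = ", x$config$outcome,
      ", protected = ", x$config$protected,
      ", ", x$config$replicates, " replicate(s) of n = ",
      x$config$n_sample, "\n", sep = "")
  print(x$summary |>
          select("configuration", "R2", "PR_g", "NC_g",
                 "r2_rel_loss", "on_frontier"),
        n = nrow(x$summary))
  invisible(x)
}

#' @method tidy fair_scenario
#' @export
tidy.fair_scenario <- function(x, ...) x$summary

#' @method glance fair_scenario
#' @export
glance.fair_scenario <- function(x, ...) {
  tibble(outcome = x$config$outcome, protected = x$config$protected,
         n_population = x$config$n_population, n_sample = x$config$n_sample,
         replicates = x$config$replicates,
         n_configurations = nrow(x$grid),
         n_on_frontier = sum(x$summary$on_frontier))
}
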