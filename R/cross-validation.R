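#' Balanced (optionally stratified) cross-validation folds
#'
#' `make_folds()` partitions `n` people into `k` folds whose sizes differ by
#' at most one, deterministically for a given `seed`. `make_folds_stratified()`
#' balances within each level of a stratum (typically the protected-group
#' indicator) so every training split contains both groups - a prerequisite
#' for fitting group-constrained estimators on every fold.
#'
#' @param n Number of people.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param strata Vector of stratum labels, length `n`.
#' @return Integer vector of fold labels in `1:k`, length `n`.
#' @export
make_folds <- function(n, k = 5, seed = 1) {
  if (k > n) abort("`k` must not exceed `n`.")
  if (k < 2) abort("Need at least two folds.")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' @rdname make_folds
#' @export
make_folds_stratified <- function(strata, k = 5, seed = 1) {
  n <- length(strata)
  if (k > n) abort("`k` must not exceed `n`.")
  set.seed(seed)
  folds <- integer(n)
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Default estimator/hyperparameter grid
#'
#' Mirrors the hyperparameter ranges used in the application study:
#' `m` and `alpha` in \{0.2, 0.4, 0.6, 0.8\} and penalty weights
#' `lambda` in \{N/100, N/10, N/5, 3N/10\} (the `N/10` rule of thumb sits
#' inside the range), plus the OLS reference and the average-constrained fit.
#'
#' @param n Sample size the lambda grid should scale with.
#' @param methods Methods to include (default: all six).
#' @return A tibble with columns `method`, `param` and `value` (`NA` for the
#'   parameter-free methods), one row per configuration.
#' @export
default_estimator_grid <- function(n,
                                   methods = c("ols", "avg_constrained",
                                               "wavg_constrained",
                                               "cov_constrained",
                                               "mrd_penalized",
                                               "netcomp_penalized")) {
  lam <- c(n / 100, n / 10, n / 5, 3 * n / 10)
  grids <- list(
    ols = tibble(method = "ols", param = NA_character_, value = NA_real_),
    avg_constrained = tibble(method = "avg_constrained",
                             param = NA_character_, value = NA_real_),
    wavg_constrained = tibble(method = "wavg_constrained", param = "alpha",
                              value = c(0.2, 0.4, 0.6, 0.8)),
    cov_constrained = tibble(method = "cov_constrained", param = "m",
                             value = c(0.2, 0.4, 0.6, 0.8)),
    mrd_penalized = tibble(method = "mrd_penalized", param = "lambda",
                           value = lam),
    netcomp_penalized = tibble(method = "netcomp_penalized", param = "lambda",
                               value = lam),
    netcomp_constrained = tibble(method = "netcomp_constrained", param = "z",
                                 value = NA_real_)
  )
  unknown <- setdiff(methods, names(grids))
  if (length(unknown) > 0) {
    abort(paste0("Unknown method(s): ", paste(unknown, collapse = ", "),
                 ". Valid methods: ", paste(names(grids), collapse = ", ")))
  }
  bind_rows(grids[methods])
}

config_label <- function(method, param, value) {
  ifelse(is.na(param), method,
         paste0(method, " (", param, " = ", format(value, trim = TRUE), ")"))
}

# Dispatch one grid row onto the matching fit function.
fit_config <- function(method, param, value, data, outcome, group, features,
                       intercept) {
  args <- list(data = data, outcome = outcome, group = group,
               features = features, intercept = intercept)
  switch(
    method,
    ols = do.call(fit_ols, args),
    avg_constrained = do.call(fit_average_constrained, args),
    wavg_constrained = do.call(fit_weighted_average_constrained,
                               c(args, list(alpha = value))),
    cov_constrained = do.call(fit_covariance_constrained,
                              c(args, list(m = value))),
    mrd_penalized = do.call(fit_mrd_penalized, c(args, list(lambda = value))),
    netcomp_penalized = do.call(fit_netcomp_penalized,
                                c(args, list(lambda = value))),
    netcomp_constrained = do.call(fit_netcomp_constrained,
                                  c(args, list(z = value))),
    abort(paste0("Unknown method `", method, "`. Valid methods: ",
                 "ols, avg_constrained, wavg_constrained, cov_constrained, ",
                 "mrd_penalized, netcomp_penalized, netcomp_constrained"))
  )
}

#' Cross-validated evaluation of fair-regression configurations
#'
#' The evaluation protocol used throughout: for every estimator configuration
#' in `grid`, fit on each training split, predict the held-out fold, pool the
#' held-out predictions over all people, and compute one [fairness_report()]
#' per configuration from the pooled predictions. OLS is always included as
#' the reference configuration; its pooled residual covariance with the group
#' indicator supplies the `c_star` reference for the scaled fair covariance.
#' Folds are stratified by group membership by default so every training
#' split contains both groups.
#'
#' @param data Data frame with one row per person.
#' @param outcome,group Column names of the outcome and the 0/1
#'   protected-group indicator.
#' @param features Design columns (default: everything else).
#' @param grid Configuration tibble as from [default_estimator_grid()]
#'   (columns `method`, `param`, `value`). Default: the full grid for
#'   `nrow(data)`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @param stratify Stratify folds by the group indicator (default `TRUE`).
#' @param intercept Include an intercept column (default `TRUE`).
#' @return A `fair_cv` object: `metrics` (one fairness report row per
#'   configuration, sorted on net compensation for g, descending),
#'   `predictions` (pooled held-out predictions, one column per
#'   configuration), `models` (per-fold fits), `folds`,
#'   `c_star_reference`, and the call settings. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' pop <- generate_spending_population(n = 1500, seed = 3)
#' grid <- default_estimator_grid(nrow(pop),
#'                                methods = c("ols", "avg_constrained"))
#' cv <- cross_validate(pop, outcome = "y", group = "group",
#'                      grid = grid, seed = 42)
#' tidy(cv)
#' @export
cross_validate <- function(data, outcome = "y", group = "group",
                           features = NULL, grid = NULL, n_folds = 5,
                           seed = 1, stratify = TRUE, intercept = TRUE) {
  n <- nrow(data)
  if (is.null(grid)) grid <- default_estimator_grid(n)
  if (nrow(grid) == 0) abort("`grid` must contain at least one configuration.")
  if (!all(c("method", "param", "value") %in% names(grid))) {
    abort("`grid` needs columns `method`, `param`, `value`.")
  }
  if (!"ols" %in% grid$method) {
    grid <- bind_rows(tibble(method = "ols", param = NA_character_,
                             value = NA_real_), grid)
  }
  grid <- mutate(grid, configuration = make.unique(
    config_label(.data$method, .data$param, .data$value)))

  a <- as.numeric(data[[group]])
  folds <- if (stratify) {
    make_folds_stratified(a, k = n_folds, seed = seed)
  } else {
    make_folds(n, k = n_folds, seed = seed)
  }
  for (f in seq_len(n_folds)) {
    a_train <- a[folds != f]
    if (length(unique(a_train)) < 2) {
      abort(paste0("Training split for fold ", f, " lacks one of the groups; ",
                   "use stratified folds (stratify = TRUE)."))
    }
  }

  models <- vector("list", nrow(grid))
  predictions <- matrix(NA_real_, nrow = n, ncol = nrow(grid))
  colnames(predictions) <- grid$configuration
  for (i in seq_len(nrow(grid))) {
    fold_fits <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      train <- data[folds != f, , drop = FALSE]
      test <- data[folds == f, , drop = FALSE]
      fit <- fit_config(grid$method[i], grid$param[i], grid$value[i],
                        train, outcome, group, features, intercept)
      predictions[folds == f, i] <- predict(fit, test)
      fold_fits[[f]] <- fit
    }
    models[[i]] <- fold_fits
  }

  y <- as.numeric(data[[outcome]])
  ols_col <- match(config_label("ols", NA, NA), grid$configuration)
  c_star_reference <- fair_covariance(y, predictions[, ols_col], a)

  metrics <- purrr::map(seq_len(nrow(grid)), function(i) {
    rep <- fairness_report(y, predictions[, i], a,
                           c_star = if (c_star_reference != 0)
                             c_star_reference else NULL)
    dplyr::bind_cols(grid[i, c("configuration", "method", "param", "value")],
                     rep)
  }) |>
    list_rbind() |>
    arrange(desc(.data$NC_g))

  structure(
    list(
      metrics = metrics,
      predictions = as_tibble(as.data.frame(predictions, check.names = FALSE)),
      models = setNames(models, grid$configuration),
      folds = folds,
      c_star_reference = c_star_reference,
      grid = grid,
      outcome = outcome,
      group = group,
      n_folds = n_folds,
      seed = seed,
      stratify = stratify,
      n = n
    ),
    class = "fair_cv"
  )
}

#' @export
print.fair_cv <- function(x, ...) {
  cat("<fair_cv> ", nrow(x$grid), " configuration(s), ", x$n_folds,
      "-fold CV, n = ", x$n, "\n", sep = "")
  print(format_metric_table(x$metrics), n = nrow(x$metrics))
  invisible(x)
}

#' @method tidy fair_cv
#' @export
tidy.fair_cv <- function(x, ...) x$metrics

#' @method glance fair_cv
#' @export
glance.fair_cv <- function(x, ...) {
  tibble(n = x$n, n_folds = x$n_folds, n_configurations = nrow(x$grid),
         c_star_reference = x$c_star_reference, seed = x$seed,
         stratified = x$stratify)
}

#' Fit-versus-fairness frontier table
#'
#' Condenses a cross-validated run into the columns plotted on a
#' fit-versus-fairness frontier: configuration, cross-validated R2 and the
#' group predictive ratio, with net compensation kept for sorting (rows are
#' sorted on `NC_g`, descending, so the fairest configurations come first).
#' The OLS reference row is always present.
#'
#' @param result A `fair_cv` object.
#' @return A tibble with columns `configuration`, `method`, `R2`, `PR_g`,
#'   `NC_g`.
#' @export
frontier_table <- function(result) {
  stopifnot(inherits(result, "fair_cv"))
  result$metrics |>
    select("configuration", "method", "R2", "PR_g", "NC_g") |>
    arrange(desc(.data$NC_g))
}

#' Flag configurations on the fairness frontier
#'
#' A configuration is kept when it improves group fairness over OLS (smaller
#' absolute net compensation for g) at a relative cross-validated R2 loss of
#' at most `max_r2_loss` (default 10%). OLS itself is always kept as the
#' reference.
#'
#' @param metrics Metric tibble as in `fair_cv$metrics` (needs columns
#'   `method`, `R2`, `NC_g`).
#' @param max_r2_loss Maximum tolerated relative R2 loss (default 0.10).
#' @return The tibble with logical columns `improves_fairness`,
#'   `r2_rel_loss` and `on_frontier` added.
#' @export
frontier_filter <- function(metrics, max_r2_loss = 0.10) {
  ols_row <- metrics[metrics$method == "ols", ]
  if (nrow(ols_row) != 1) abort("`metrics` must contain exactly one OLS row.")
  metrics |>
    mutate(
      improves_fairness = abs(.data$NC_g) < abs(ols_row$NC_g),
      r2_rel_loss = (ols_row$R2 - .data$R2) / abs(ols_row$R2),
      on_frontier = .data$method == "ols" |
        (.data$improves_fairness & .data$r2_rel_loss <= max_r2_loss)
    )
}

#' Select a hyperparameter configuration under an R2-loss ceiling
#'
#' Implements the selection rule used when reporting a single "best"
#' configuration per method: among configurations whose relative
#' cross-validated R2 loss does not exceed `max_r2_loss`, pick the one with
#' the highest group predictive ratio (not exceeding parity preference:
#' ties broken toward smaller |NC_g|).
#'
#' @param result A `fair_cv` object.
#' @param max_r2_loss Maximum tolerated relative R2 loss (default 0.10).
#' @return One row per method from the metric table.
#' @export
select_configuration <- function(result, max_r2_loss = 0.10) {
  stopifnot(inherits(result, "fair_cv"))
  frontier_filter(result$metrics, max_r2_loss) |>
    filter(.data$r2_rel_loss <= max_r2_loss) |>
    group_by(.data$method) |>
    arrange(desc(.data$PR_g), abs(.data$NC_g), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
}

# Presentation rounding: whole dollars for currency, 3 decimals for ratios,
# 1 decimal for R2. Computation everywhere else stays at full precision.
format_metric_table <- function(metrics) {
  metrics |>
    mutate(
      R2 = round(.data$R2, 1),
      PR_g = round(.data$PR_g, 3),
      PR_gc = round(.data$PR_gc, 3),
      NC_g = round(.data$NC_g),
      NC_gc = round(.data$NC_gc),
      MRD = round(.data$MRD),
      FairCov = round(.data$FairCov),
      ScaledFairCov = round(.data$ScaledFairCov, 3)
    )
}
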