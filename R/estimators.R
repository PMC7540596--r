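#' Fair least-squares estimators for risk adjustment
#'
#' Six linear-regression estimators of spending share a data-frame-first
#' interface: plain OLS and five variants that build a group-fairness
#' requirement for a protected group `g` into the least-squares problem,
#' either as a hard constraint or as a penalty term. All of them predict a
#' continuous outcome (annual spending) from demographic and condition
#' indicator columns; the group indicator itself is *not* a regressor.
#'
#' * `fit_ols()` - unconstrained least squares, the risk-adjustment baseline.
#' * `fit_average_constrained()` - least squares subject to the group's mean
#'   predicted spending equalling its mean observed spending, so in-sample
#'   net compensation for `g` is exactly zero.
#' * `fit_weighted_average_constrained()` - relaxes the target to a convex
#'   combination (weight `alpha`) of the group's observed mean and its OLS
#'   predicted mean; `alpha = 1` reproduces OLS, `alpha = 0` the
#'   average-constrained fit.
#' * `fit_covariance_constrained()` - least squares subject to a one-sided
#'   bound on the covariance between the group indicator and the residual
#'   \eqn{Y - \hat Y}: covariance \eqn{\le m \cdot c^*}, where \eqn{c^*} is
#'   the covariance under OLS on the same training data and
#'   `m` in \[0, 1\] is the tightening factor (`m = 1` keeps OLS).
#' * `fit_mrd_penalized()` - adds `lambda` times the *squared* mean residual
#'   difference between `g` and its complement to the sum of squared errors.
#' * `fit_netcomp_penalized()` - adds `lambda` times the summed group
#'   residual \eqn{\sum_{i \in g}(Y_i - \hat Y_i)} to the sum of squared
#'   errors. The penalty is linear, so large `lambda` pushes the group past
#'   parity into overcompensation (and the fair covariance negative); the
#'   `lambda = N/10` rule of thumb is a reasonable starting point.
#' * `fit_netcomp_constrained()` - the constrained counterpart: least squares
#'   subject to the group *mean* residual \eqn{\le z} (`z > 0`, currency).
#'   When the constraint binds its KKT multiplier links it one-to-one to a
#'   `lambda` of the penalized form.
#'
#' All constrained/penalized fits compute any internal OLS quantities
#' (\eqn{\theta_{OLS}}, \eqn{c^*}) on the same training data they are given.
#'
#' @param data Data frame with one row per person.
#' @param outcome,group,features,intercept Column selection, see
#'   [cross_validate()]; `features = NULL` uses all remaining columns.
#' @param solver `"closed_form"` (analytic KKT solution, default) or `"qp"`
#'   (independent generic KKT/active-set route). Both give the same
#'   coefficients to solver tolerance.
#' @param alpha Weight in \[0, 1\] mixing the observed group mean
#'   (`alpha = 0`) with the OLS-predicted group mean (`alpha = 1`).
#' @param m Multiplicative tightening factor in \[0, 1\] for the covariance
#'   bound `c = m * c_star`.
#' @param lambda Non-negative penalty weight.
#' @param z Positive bound (currency) on the group mean residual.
#' @param two_sided Also enforce the lower bound `>= -c` on the covariance
#'   (the one-sided form is the default; with `c_star > 0` the optimum is
#'   identical).
#'
#' @return An object of class `fair_fit`: coefficients (`theta`), `method`,
#'   `hyperparameter`, solver diagnostics (`solver_status`,
#'   `constraint` residuals), in-sample `sse`/`objective_value`/`r_squared`,
#'   and the training `c_star` where applicable. Supports [predict()],
#'   [tidy()], [glance()].
#'
#' @examples
#' pop <- generate_spending_population(n = 2000, seed = 7)
#' ols <- fit_ols(pop, outcome = "y", group = "group")
#' fair <- fit_average_constrained(pop, outcome = "y", group = "group")
#' glance(ols); glance(fair)
#' @name fair-estimators
NULL

new_fair_fit <- function(ds, theta, method, hyperparameter = NULL,
                         solver, solver_status, constraint = NULL,
                         penalty_value = 0, c_star = NULL) {
  theta <- as.numeric(theta)
  names(theta) <- colnames(ds$X)
  fitted <- as.numeric(ds$X %*% theta)
  sse <- sum((ds$y - fitted)^2)
  structure(
    list(
      theta = theta,
      method = method,
      hyperparameter = hyperparameter,
      solver = solver,
      solver_status = solver_status,
      sse = sse,
      objective_value = sse + penalty_value,
      r_squared = r_squared(ds$y, fitted),
      constraint = constraint,
      c_star = c_star,
      n = length(ds$y),
      n_g = sum(ds$a == 1),
      outcome = ds$outcome,
      group = ds$group,
      features = ds$features,
      intercept = ds$intercept,
      fitted = fitted
    ),
    class = "fair_fit"
  )
}

# Shared sufficient statistics for the training data.
fit_context <- function(ds) {
  XtX <- crossprod(ds$X)
  Xty <- drop(crossprod(ds$X, ds$y))
  R <- chol(XtX)
  theta_ols <- drop(chol_solve(R, Xty))
  list(XtX = XtX, Xty = Xty, R = R, theta_ols = theta_ols,
       sd_y = sd(ds$y))
}

# Constraint bookkeeping: achieved vs target, and the solver status rule
# (optimal when the constraint residual is below 1e-6 x sd(y)).
constraint_record <- function(type, target, achieved, sd_y, solver) {
  residual <- abs(achieved - target)
  status <- if (solver == "closed_form") {
    "closed_form"
  } else if (residual < 1e-6 * max(sd_y, 1)) {
    "solver_optimal"
  } else {
    "solver_inaccurate"
  }
  list(record = list(type = type, target = target, achieved = achieved,
                     residual = residual),
       status = status)
}

#' @rdname fair-estimators
#' @export
fit_ols <- function(data, outcome = "y", group = "group", features = NULL,
                    intercept = TRUE, solver = c("closed_form", "qp")) {
  solver <- match.arg(solver)
  ds <- build_design(data, outcome, group, features, intercept)
  if (solver == "closed_form") {
    theta <- lm.fit(ds$X, ds$y)$coefficients
    status <- "closed_form"
  } else {
    ctx <- fit_context(ds)
    theta <- qp_solve(ctx$XtX, ctx$Xty)$theta
    status <- "solver_optimal"
  }
  fit <- new_fair_fit(ds, theta, "ols", NULL, solver, status)
  fit$c_star <- fair_covariance(ds$y, fit$fitted, ds$a)
  fit
}

# Equality-constrained family: minimise SSE subject to d'theta = b.
fit_group_mean_constrained <- function(ds, d, b, method, hyperparameter,
                                       solver, type) {
  ctx <- fit_context(ds)
  if (solver == "closed_form") {
    theta <- equality_constrained_ls(ctx$theta_ols, ctx$R, d, b)$theta
  } else {
    if (all(d == 0)) abort("Constraint vector is the zero vector; the group-mean constraint is infeasible.")
    theta <- qp_solve(ctx$XtX, ctx$Xty, Aeq = matrix(d, nrow = 1), beq = b)$theta
  }
  cr <- constraint_record(type, b, sum(d * theta), ctx$sd_y, solver)
  fit <- new_fair_fit(ds, theta, method, hyperparameter, solver, cr$status,
                      constraint = cr$record)
  fit$c_star <- fair_covariance(ds$y, ds$X %*% ctx$theta_ols, ds$a)
  fit
}

#' @rdname fair-estimators
#' @export
fit_average_constrained <- function(data, outcome = "y", group = "group",
                                    features = NULL, intercept = TRUE,
                                    solver = c("closed_form", "qp")) {
  solver <- match.arg(solver)
  ds <- build_design(data, outcome, group, features, intercept)
  d <- colMeans(ds$X[ds$a == 1, , drop = FALSE])
  b <- mean(ds$y[ds$a == 1])
  fit_group_mean_constrained(ds, d, b, "avg_constrained", NULL, solver,
                             "group_mean_prediction")
}

#' @rdname fair-estimators
#' @export
fit_weighted_average_constrained <- function(data, alpha,
                                             outcome = "y", group = "group",
                                             features = NULL, intercept = TRUE,
                                             solver = c("closed_form", "qp")) {
  solver <- match.arg(solver)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1].")
  }
  ds <- build_design(data, outcome, group, features, intercept)
  ctx <- fit_context(ds)
  d <- colMeans(ds$X[ds$a == 1, , drop = FALSE])
  b <- (1 - alpha) * mean(ds$y[ds$a == 1]) + alpha * sum(d * ctx$theta_ols)
  fit_group_mean_constrained(ds, d, b, "wavg_constrained",
                             list(alpha = alpha), solver,
                             "group_mean_prediction")
}

#' @rdname fair-estimators
#' @export
fit_covariance_constrained <- function(data, m,
                                       outcome = "y", group = "group",
                                       features = NULL, intercept = TRUE,
                                       solver = c("closed_form", "qp"),
                                       two_sided = FALSE) {
  solver <- match.arg(solver)
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0 || m > 1) {
    abort("`m` must be a single number in [0, 1].")
  }
  ds <- build_design(data, outcome, group, features, intercept)
  ctx <- fit_context(ds)
  n <- length(ds$y)
  p_a <- mean(ds$a)
  # residual covariance is linear in theta: cov(theta) = q0 - w'theta
  w <- drop(crossprod(ds$X, ds$a - p_a)) / n
  q0 <- sum((ds$a - p_a) * ds$y) / n
  c_star <- q0 - sum(w * ctx$theta_ols)
  if (c_star <= 0) {
    abort(paste0(
      "OLS residual covariance with the group indicator is not positive ",
      "(c* = ", format(c_star), "): group g is not undercompensated under OLS ",
      "and the one-sided covariance constraint is not meaningful."
    ))
  }
  cc <- m * c_star

  if (solver == "closed_form") {
    # OLS attains cov = c* > c for m < 1, so the bound binds unless m = 1.
    if (c_star <= cc) {
      theta <- ctx$theta_ols
    } else {
      theta <- equality_constrained_ls(ctx$theta_ols, ctx$R, w, q0 - cc)$theta
    }
  } else {
    theta <- qp_solve(ctx$XtX, ctx$Xty,
                      ain = -w, bin = cc - q0)$theta
  }
  achieved <- q0 - sum(w * theta)
  if (two_sided && achieved < -cc - 1e-9 * max(1, abs(cc))) {
    abort("Two-sided covariance bound violated at the optimum; this cannot happen with c* > 0.")
  }
  cr <- constraint_record(
    if (two_sided) "residual_covariance_two_sided" else "residual_covariance",
    cc, achieved, ctx$sd_y, solver
  )
  if (achieved <= cc) cr$record$residual <- 0  # slack counts as satisfied
  if (solver != "closed_form" && cr$record$residual == 0) {
    cr$status <- "solver_optimal"
  }
  new_fair_fit(ds, theta, "cov_constrained", list(m = m), solver, cr$status,
               constraint = cr$record, c_star = c_star)
}

#' @rdname fair-estimators
#' @export
fit_mrd_penalized <- function(data, lambda,
                              outcome = "y", group = "group",
                              features = NULL, intercept = TRUE,
                              solver = c("closed_form", "qp")) {
  solver <- match.arg(solver)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0) {
    abort("`lambda` must be a single non-negative number.")
  }
  ds <- build_design(data, outcome, group, features, intercept)
  ctx <- fit_context(ds)
  g <- ds$a == 1
  v <- colMeans(ds$X[g, , drop = FALSE]) - colMeans(ds$X[!g, , drop = FALSE])
  t0 <- mean(ds$y[g]) - mean(ds$y[!g])

  if (solver == "closed_form") {
    # Sherman-Morrison update of (X'X + lambda v v')^{-1} (X'y + lambda t v)
    rhs <- ctx$Xty + lambda * t0 * v
    Krhs <- chol_solve(ctx$R, rhs)
    Kv <- chol_solve(ctx$R, v)
    theta <- Krhs - Kv * (lambda * sum(v * Krhs) / (1 + lambda * sum(v * Kv)))
  } else {
    theta <- drop(solve(ctx$XtX + lambda * tcrossprod(v),
                        ctx$Xty + lambda * t0 * v))
  }
  u <- t0 - sum(v * theta)  # in-sample mean residual difference (Y - Yhat)
  status <- if (solver == "closed_form") "closed_form" else "solver_optimal"
  fit <- new_fair_fit(ds, theta, "mrd_penalized", list(lambda = lambda),
                      solver, status, penalty_value = lambda * u^2)
  fit$c_star <- fair_covariance(ds$y, ds$X %*% ctx$theta_ols, ds$a)
  fit
}

#' @rdname fair-estimators
#' @export
fit_netcomp_penalized <- function(data, lambda,
                                  outcome = "y", group = "group",
                                  features = NULL, intercept = TRUE,
                                  solver = c("closed_form", "qp")) {
  solver <- match.arg(solver)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda < 0) {
    abort("`lambda` must be a single non-negative number.")
  }
  ds <- build_design(data, outcome, group, features, intercept)
  ctx <- fit_context(ds)
  sg <- colSums(ds$X[ds$a == 1, , drop = FALSE])

  if (solver == "closed_form") {
    theta <- ctx$theta_ols + (lambda / 2) * chol_solve(ctx$R, sg)
  } else {
    theta <- qp_solve(ctx$XtX, ctx$Xty, lin = (lambda / 2) * sg)$theta
  }
  pen <- lambda * (sum(ds$y[ds$a == 1]) - sum(sg * theta))
  status <- if (solver == "closed_form") "closed_form" else "solver_optimal"
  fit <- new_fair_fit(ds, theta, "netcomp_penalized", list(lambda = lambda),
                      solver, status, penalty_value = pen)
  fit$c_star <- fair_covariance(ds$y, ds$X %*% ctx$theta_ols, ds$a)
  fit
}

#' @rdname fair-estimators
#' @export
fit_netcomp_constrained <- function(data, z,
                                    outcome = "y", group = "group",
                                    features = NULL, intercept = TRUE,
                                    solver = c("closed_form", "qp")) {
  solver <- match.arg(solver)
  if (!is.numeric(z) || length(z) != 1 || is.na(z) || z <= 0) {
    abort("`z` must be a single positive number.")
  }
  ds <- build_design(data, outcome, group, features, intercept)
  ctx <- fit_context(ds)
  d <- colMeans(ds$X[ds$a == 1, , drop = FALSE])
  b <- mean(ds$y[ds$a == 1])

  if (solver == "closed_form") {
    ols_resid_g <- b - sum(d * ctx$theta_ols)
    if (ols_resid_g <= z) {
      theta <- ctx$theta_ols
      nu <- 0
    } else {
      sol <- equality_constrained_ls(ctx$theta_ols, ctx$R, -d, z - b)
      theta <- sol$theta
      nu <- sol$nu
    }
  } else {
    out <- qp_solve(ctx$XtX, ctx$Xty, ain = -d, bin = z - b)
    theta <- out$theta
    nu <- if (isTRUE(out$active)) out$mult else 0
  }
  achieved <- b - sum(d * theta)
  cr <- constraint_record("group_mean_residual", z, achieved, ctx$sd_y, solver)
  if (achieved <= z) cr$record$residual <- 0
  if (solver != "closed_form" && cr$record$residual == 0) {
    cr$status <- "solver_optimal"
  }
  fit <- new_fair_fit(ds, theta, "netcomp_constrained", list(z = z),
                      solver, cr$status, constraint = cr$record)
  fit$constraint$multiplier <- nu
  fit$c_star <- fair_covariance(ds$y, ds$X %*% ctx$theta_ols, ds$a)
  fit
}

#' Predict spending from a fitted fair-regression model
#'
#' @param object A `fair_fit` object.
#' @param newdata Data frame containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions (currency units).
#' @export
predict.fair_fit <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("`newdata` is missing design columns: ",
                 paste(missing_cols, collapse = ", "),
                 ". Expected: ", paste(object$features, collapse = ", ")))
  }
  X <- feature_matrix(newdata, object$features)
  if (object$intercept) X <- cbind(1, X)
  if (ncol(X) != length(object$theta)) {
    abort("Column count of `newdata` design does not match the coefficient vector.")
  }
  drop(X %*% object$theta)
}

#' @export
print.fair_fit <- function(x, ...) {
  hp <- if (is.null(x$hyperparameter)) "" else
    paste0(" (", paste(names(x$hyperparameter), unlist(x$hyperparameter),
                       sep = " = ", collapse = ", "), ")")
  cat("<fair_fit> ", x$method, hp, "\n", sep = "")
  cat("  n = ", x$n, ", group size = ", x$n_g,
      ", terms = ", length(x$theta), "\n", sep = "")
  cat("  in-sample R2 = ", format(round(x$r_squared, 1), nsmall = 1),
      "%, solver: ", x$solver_status, "\n", sep = "")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes method, hyperparameter, column names, coefficients and solver
#' diagnostics; round-trips with [read_fair_fit()].
#'
#' @param fit A `fair_fit` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_fair_fit <- function(fit, path) {
  payload <- list(
    method = fit$method,
    hyperparameter = fit$hyperparameter,
    columns = names(fit$theta),
    theta = unname(fit$theta),
    solver = fit$solver,
    solver_status = fit$solver_status,
    objective_value = fit$objective_value,
    sse = fit$sse,
    r_squared = fit$r_squared,
    constraint = fit$constraint,
    c_star = fit$c_star,
    n = fit$n,
    n_g = fit$n_g,
    outcome = fit$outcome,
    group = fit$group,
    features = fit$features,
    intercept = fit$intercept
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fair_fit
#' @export
read_fair_fit <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- setNames(as.numeric(payload$theta), payload$columns)
  fit <- payload
  fit$theta <- theta
  fit$features <- as.character(payload$features)
  class(fit) <- "fair_fit"
  fit
}
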