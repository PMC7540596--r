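#' Tidy a fitted fair-regression model
#'
#' @param x A `fair_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model term (`term`, `estimate`).
#' @method tidy fair_fit
#' @export
tidy.fair_fit <- function(x, ...) {
  tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' Glance at a fitted fair-regression model
#'
#' @param x A `fair_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the method, hyperparameter, in-sample fit
#'   and solver diagnostics.
#' @method glance fair_fit
#' @export
glance.fair_fit <- function(x, ...) {
  tibble(
    method = x$method,
    hyperparameter = hyperparameter_label(x$hyperparameter),
    r.squared = x$r_squared,
    sse = x$sse,
    objective_value = x$objective_value,
    solver_status = x$solver_status,
    n = x$n,
    n_g = x$n_g,
    n_terms = length(x$theta)
  )
}

hyperparameter_label <- function(hp) {
  if (is.null(hp) || length(hp) == 0) return(NA_character_)
  paste(names(hp), format(unlist(hp), trim = TRUE), sep = " = ", collapse = ", ")
}

#' Coefficient-change report between two fitted models
#'
#' Compares the coefficients of a fairness-aware fit against a reference
#' (typically OLS), ranks terms by absolute dollar change, annotates the
#' relative percent change, and flags the largest `top_n` increases and
#' decreases - the standard way to communicate how a fairness requirement
#' reshapes condition-category payments.
#'
#' @param fit,reference `fair_fit` objects sharing the same design columns.
#' @param top_n How many increases and decreases to flag (default 5).
#' @return A tibble with columns `term`, `estimate`, `reference`, `change`
#'   (currency), `rel_change_pct`, `direction` and `top_change` (logical),
#'   sorted by absolute change.
#' @export
coefficient_change <- function(fit, reference, top_n = 5) {
  if (!identical(names(fit$theta), names(reference$theta))) {
    abort("`fit` and `reference` must share the same design columns.")
  }
  theta_ref <- reference$theta
  out <- tibble(
    term = names(fit$theta),
    estimate = unname(fit$theta),
    reference = unname(theta_ref),
    change = unname(fit$theta - theta_ref)
  ) |>
    mutate(
      rel_change_pct = ifelse(.data$reference == 0, NA_real_,
                              100 * .data$change / abs(.data$reference)),
      direction = dplyr::case_when(
        .data$change > 0 ~ "increase",
        .data$change < 0 ~ "decrease",
        TRUE ~ "unchanged"
      )
    ) |>
    arrange(desc(abs(.data$change)))
  flag <- function(dir) {
    idx <- which(out$direction == dir)
    head(idx, top_n)
  }
  out$top_change <- FALSE
  out$top_change[c(flag("increase"), flag("decrease"))] <- TRUE
  out
}
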