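#' Assemble an outcome / design-matrix / group triple from a data frame
#'
#' Internal workhorse shared by every estimator. Validates the (Y, X, A)
#' triple of a risk-adjustment problem: equal lengths, finite values, a binary
#' group indicator with both groups non-empty, and a full-column-rank design.
#'
#' @param data Data frame with one row per person.
#' @param outcome Name of the continuous outcome column (annual spending).
#' @param group Name of the binary protected-group indicator column.
#' @param features Character vector of design columns. Default (`NULL`) uses
#'   every column except `outcome`, `group` and `person_id`/`replicate`
#'   bookkeeping columns.
#' @param intercept Should an intercept column be prepended? Default `TRUE`.
#' @noRd
build_design <- function(data, outcome = "y", group = "group", features = NULL,
                         intercept = TRUE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(outcome, group)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` not found in `data`.", col))
    }
  }
  if (is.null(features)) {
    features <- setdiff(names(data), c(outcome, group, "person_id", "replicate"))
  }
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Design columns not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (outcome %in% features || group %in% features) {
    abort("`features` must not contain the outcome or the group column.")
  }

  y <- as.numeric(data[[outcome]])
  a <- as.numeric(data[[group]])
  X <- feature_matrix(data, features)
  if (intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  if (ncol(X) == 0) abort("Design has no columns; add features or an intercept.")

  n <- length(y)
  if (n < 2) abort("Need at least two observations.")
  if (nrow(X) != n || length(a) != n) abort("Row counts of y, X and a differ.")
  if (anyNA(y) || anyNA(a) || anyNA(X)) abort("Missing values are not allowed.")
  if (!all(is.finite(X))) abort("Design matrix contains non-finite values.")
  if (!all(a %in% c(0, 1))) abort("Group indicator must contain only 0/1.")
  n_g <- sum(a == 1)
  if (n_g == 0) abort("Protected group g is empty.")
  if (n_g == n) abort("Complement group gc is empty.")

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(paste0(
      "Design matrix is rank-deficient; coefficients would not be unique. ",
      "Offending columns: ", paste(bad, collapse = ", ")
    ))
  }

  list(y = y, X = X, a = a, qr = qx,
       outcome = outcome, group = group,
       features = features, intercept = intercept)
}

feature_matrix <- function(data, features) {
  if (length(features) == 0) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  X <- as.matrix(as.data.frame(lapply(data[features], as.numeric)))
  colnames(X) <- features
  X
}
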