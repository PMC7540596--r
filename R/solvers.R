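# Internal quadratic solvers.
#
# Every estimator in this package minimises a positive-definite quadratic in
# theta subject to at most one linear equality and one linear inequality, so
# exact solutions are available from the KKT conditions. Two independent
# routes are kept: the method-specific closed forms in estimators.R
# (solver = "closed_form") and the generic KKT route below (solver = "qp").
# Fits from the two routes must agree and the test suite enforces that.

chol_solve <- function(R, v) {
  # solve (X'X) x = v given R = chol(X'X)
  backsolve(R, backsolve(R, v, transpose = TRUE))
}

# Least squares with a single linear equality d'theta = b, via the analytic
# KKT downdate of the unconstrained solution. Returns the solution and the
# Lagrange multiplier nu of the constraint (objective written as SSE).
equality_constrained_ls <- function(theta_ols, R, d, b) {
  if (all(d == 0)) {
    abort("Constraint vector is the zero vector; the group-mean constraint is infeasible.")
  }
  Kd <- chol_solve(R, d)
  denom <- sum(d * Kd)
  gap <- sum(d * theta_ols) - b
  nu <- 2 * gap / denom
  list(theta = theta_ols - Kd * (gap / denom), nu = nu)
}

# Generic KKT route: minimise theta' XtX theta - 2 Xty' theta (+ linear term)
# subject to optional equality rows Aeq theta = beq and at most one
# inequality row ain' theta <= bin. Solves the stationarity system directly;
# for the inequality it runs the two-case active-set analysis.
qp_solve <- function(XtX, Xty, Aeq = NULL, beq = NULL,
                     ain = NULL, bin = NULL, lin = NULL) {
  p <- ncol(XtX)
  f <- Xty + (lin %||% 0)  # extra linear term: objective - 2 f' theta

  solve_sys <- function(Aact, bact) {
    k <- if (is.null(Aact)) 0L else nrow(Aact)
    if (k == 0L) {
      list(theta = solve(XtX, f), mult = numeric(0))
    } else {
      M <- rbind(cbind(2 * XtX, t(Aact)),
                 cbind(Aact, matrix(0, k, k)))
      sol <- solve(M, c(2 * f, bact))
      list(theta = sol[seq_len(p)], mult = sol[-seq_len(p)])
    }
  }

  if (is.null(ain)) {
    out <- solve_sys(Aeq, beq)
    return(list(theta = out$theta, active = FALSE))
  }

  # case 1: inequality inactive
  out <- solve_sys(Aeq, beq)
  if (sum(ain * out$theta) <= bin + 1e-9 * max(1, abs(bin))) {
    return(list(theta = out$theta, active = FALSE))
  }
  # case 2: inequality active at the boundary
  Aact <- rbind(Aeq, matrix(ain, nrow = 1))
  bact <- c(beq, bin)
  out <- solve_sys(Aact, bact)
  list(theta = out$theta, active = TRUE,
       mult = out$mult[length(out$mult)])
}
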