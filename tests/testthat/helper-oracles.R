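# Shared fixtures and independent oracles.
#
# The oracles here deliberately do NOT reuse the package's solution paths:
# estimator solutions are recomputed either with quadprog::solve.QP
# (Goldfarb-Idnani active-set QP) or with textbook formulas written out
# directly from the optimization problems, so implementation and oracle can
# disagree if either is wrong.

# Small random risk-adjustment instance. The outcome carries a group effect
# that the design does not (fully) capture, so OLS undercompensates the
# group and c* > 0 with overwhelming probability.
make_instance <- function(n = 120, p = 4, seed = 1, group_shift = 3,
                          group_in_design = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  a <- rbinom(n, 1, 0.3)
  # guarantee both groups are present
  a[1] <- 1L
  a[2] <- 0L
  y <- 1 + X %*% rnorm(p) + group_shift * a + rnorm(n)
  dat <- tibble::as_tibble(as.data.frame(X))
  if (group_in_design) dat$ga <- a
  dat$group <- a
  dat$y <- as.numeric(y)
  dat
}

instance_features <- function(data) setdiff(names(data), c("y", "group"))

# Build the same design matrix the fit functions use (intercept first).
oracle_design <- function(data, intercept = TRUE) {
  X <- as.matrix(data[instance_features(data)])
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

# --- quadprog-based oracles ---------------------------------------------
# minimise ||y - X theta||^2 (+ optional penalty terms), subject to
# equality rows (meq) and inequality rows A theta >= b.

qp_oracle <- function(X, y, Amat = NULL, bvec = NULL, meq = 0,
                      Dextra = NULL, dextra = NULL) {
  D <- 2 * crossprod(X) + (if (is.null(Dextra)) 0 else Dextra)
  dv <- as.vector(2 * crossprod(X, y)) + (if (is.null(dextra)) 0 else dextra)
  if (is.null(Amat)) {
    Amat <- matrix(0, ncol(X), 0)
    bvec <- numeric(0)
  }
  quadprog::solve.QP(D, dv, Amat, bvec, meq = meq)$solution
}

oracle_ols <- function(data) {
  X <- oracle_design(data)
  qp_oracle(X, data$y)
}

oracle_avg_constrained <- function(data) {
  X <- oracle_design(data)
  g <- data$group == 1
  d <- colMeans(X[g, , drop = FALSE])
  qp_oracle(X, data$y, Amat = matrix(d, ncol = 1), bvec = mean(data$y[g]),
            meq = 1)
}

oracle_wavg_constrained <- function(data, alpha) {
  X <- oracle_design(data)
  g <- data$group == 1
  d <- colMeans(X[g, , drop = FALSE])
  theta_ols <- qr.solve(X, data$y)
  b <- (1 - alpha) * mean(data$y[g]) + alpha * sum(d * theta_ols)
  qp_oracle(X, data$y, Amat = matrix(d, ncol = 1), bvec = b, meq = 1)
}

oracle_cov_constrained <- function(data, m) {
  X <- oracle_design(data)
  y <- data$y
  a <- data$group
  n <- length(y)
  p_a <- mean(a)
  w <- as.vector(crossprod(X, a - p_a)) / n
  q0 <- sum((a - p_a) * y) / n
  theta_ols <- qr.solve(X, y)
  c_star <- q0 - sum(w * theta_ols)
  stopifnot(c_star > 0)
  # cov <= m c*  <=>  w' theta >= q0 - m c*
  qp_oracle(X, y, Amat = matrix(w, ncol = 1), bvec = q0 - m * c_star)
}

oracle_mrd_penalized <- function(data, lambda) {
  # SSE + lambda * (t - v' theta)^2, expanded into the quadratic form
  X <- oracle_design(data)
  g <- data$group == 1
  v <- colMeans(X[g, , drop = FALSE]) - colMeans(X[!g, , drop = FALSE])
  t0 <- mean(data$y[g]) - mean(data$y[!g])
  qp_oracle(X, data$y,
            Dextra = 2 * lambda * tcrossprod(v),
            dextra = 2 * lambda * t0 * v)
}

oracle_netcomp_penalized <- function(data, lambda) {
  # SSE + lambda * sum_{i in g} (y_i - x_i' theta): linear term only
  X <- oracle_design(data)
  g <- data$group == 1
  sg <- colSums(X[g, , drop = FALSE])
  qp_oracle(X, data$y, dextra = lambda * sg)
}

oracle_netcomp_constrained <- function(data, z) {
  X <- oracle_design(data)
  g <- data$group == 1
  d <- colMeans(X[g, , drop = FALSE])
  # mean_g(y) - d' theta <= z  <=>  d' theta >= mean_g(y) - z
  qp_oracle(X, data$y, Amat = matrix(d, ncol = 1),
            bvec = mean(data$y[g]) - z)
}

# Relative max-abs coefficient difference, the agreement measure used in
# the oracle-equivalence tests.
rel_diff <- function(theta, oracle) {
  max(abs(theta - oracle)) / max(1, max(abs(oracle)))
}
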