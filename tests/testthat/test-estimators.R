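test_that("OLS matches the normal equations and honors exact structure", {
  dat <- make_instance(n = 50, p = 4, seed = 21)
  fit <- fit_ols(dat, outcome = "y", group = "group")
  X <- oracle_design(dat)
  theta_ne <- solve(crossprod(X), crossprod(X, dat$y))  # textbook oracle
  expect_lt(rel_diff(fit$theta, as.vector(theta_ne)), 1e-8)
  # residual orthogonality to every design column
  expect_lt(max(abs(crossprod(X, dat$y - fit$fitted))), 1e-6)

  # y exactly linear in X -> perfect fit
  lin <- dat
  lin$y <- 2 + 3 * lin$x1 - lin$x2
  fit_lin <- fit_ols(lin, outcome = "y", group = "group")
  expect_equal(fit_lin$r_squared, 100, tolerance = 1e-10)

  # intercept-only design -> theta is the outcome mean
  io <- tibble::tibble(y = c(1, 5, 9, 10), group = c(1, 0, 0, 1))
  fit_io <- fit_ols(io, outcome = "y", group = "group", features = character(0))
  expect_equal(unname(fit_io$theta), mean(io$y))
})

test_that("rank-deficient designs are refused with the offending column named", {
  dat <- make_instance(n = 60, p = 3, seed = 22)
  dat$dup <- dat$x1  # exact copy
  expect_error(fit_ols(dat, outcome = "y", group = "group"),
               "rank-deficient.*dup")
})

test_that("average constrained regression zeroes in-sample group net compensation", {
  dat <- make_instance(n = 200, p = 5, seed = 23)
  fit <- fit_average_constrained(dat, outcome = "y", group = "group")
  expect_lt(abs(net_compensation(dat$y, fit$fitted, dat$group, "g")),
            1e-6 * sd(dat$y))

  # textbook KKT closed form, written out independently
  X <- oracle_design(dat)
  g <- dat$group == 1
  d <- colMeans(X[g, , drop = FALSE])
  b <- mean(dat$y[g])
  K <- solve(crossprod(X))
  theta_ols <- K %*% crossprod(X, dat$y)
  Kd <- K %*% d
  theta_kkt <- theta_ols - Kd %*% solve(t(d) %*% Kd) %*% (t(d) %*% theta_ols - b)
  expect_lt(rel_diff(fit$theta, as.vector(theta_kkt)), 1e-6)

  # constraint inactive when OLS already satisfies it (group indicator in X)
  dat2 <- make_instance(n = 150, p = 3, seed = 24, group_in_design = TRUE)
  ols2 <- fit_ols(dat2, outcome = "y", group = "group")
  avg2 <- fit_average_constrained(dat2, outcome = "y", group = "group")
  expect_lt(rel_diff(avg2$theta, ols2$theta), 1e-6)
})

test_that("weighted average constrained regression interpolates OLS and average constrained", {
  dat <- make_instance(n = 150, p = 4, seed = 25)
  ols <- fit_ols(dat, outcome = "y", group = "group")
  avg <- fit_average_constrained(dat, outcome = "y", group = "group")

  w1 <- fit_weighted_average_constrained(dat, alpha = 1, outcome = "y",
                                         group = "group")
  expect_lt(rel_diff(w1$theta, ols$theta), 1e-6)
  w0 <- fit_weighted_average_constrained(dat, alpha = 0, outcome = "y",
                                         group = "group")
  expect_lt(rel_diff(w0$theta, avg$theta), 1e-6)

  wh <- fit_weighted_average_constrained(dat, alpha = 0.5, outcome = "y",
                                         group = "group")
  expect_lt(rel_diff(wh$theta, oracle_wavg_constrained(dat, 0.5)), 1e-6)
  # the group's predicted mean hits the interpolated target
  X <- oracle_design(dat)
  g <- dat$group == 1
  target <- 0.5 * mean(dat$y[g]) +
    0.5 * mean((X %*% qr.solve(X, dat$y))[g])
  expect_equal(mean(wh$fitted[g]), target, tolerance = 1e-8)

  expect_error(fit_weighted_average_constrained(dat, alpha = 1.2,
                                                outcome = "y", group = "group"),
               "alpha")
})

test_that("covariance constrained regression binds the residual covariance at m c*", {
  dat <- make_instance(n = 200, p = 4, seed = 26)
  ols <- fit_ols(dat, outcome = "y", group = "group")
  c_star <- ols$c_star
  expect_gt(c_star, 0)

  m1 <- fit_covariance_constrained(dat, m = 1, outcome = "y", group = "group")
  expect_lt(rel_diff(m1$theta, ols$theta), 1e-6)

  for (m in c(0.2, 0.6)) {
    fit <- fit_covariance_constrained(dat, m = m, outcome = "y", group = "group")
    achieved <- fair_covariance(dat$y, fit$fitted, dat$group)
    expect_equal(achieved, m * c_star, tolerance = 1e-6 * max(1, c_star))
    expect_lt(rel_diff(fit$theta, oracle_cov_constrained(dat, m)), 1e-6)
  }

  # m = 0 drives the covariance to (at most) zero, and via the binary-A
  # identity the weighted group mean residuals balance
  m0 <- fit_covariance_constrained(dat, m = 0, outcome = "y", group = "group")
  cov0 <- fair_covariance(dat$y, m0$fitted, dat$group)
  expect_lt(cov0, 1e-8)
  r <- dat$y - m0$fitted
  p <- mean(dat$group)
  expect_equal(p * (1 - p) * (mean(r[dat$group == 1]) - mean(r[dat$group == 0])),
               cov0, tolerance = 1e-10)

  # two-sided flag keeps the same optimum when c* > 0
  ts <- fit_covariance_constrained(dat, m = 0.4, outcome = "y",
                                   group = "group", two_sided = TRUE)
  os <- fit_covariance_constrained(dat, m = 0.4, outcome = "y", group = "group")
  expect_equal(ts$theta, os$theta)
})

test_that("covariance constraint refuses groups not undercompensated under OLS", {
  dat <- make_instance(n = 150, p = 3, seed = 27)
  dat$group <- 1 - dat$group  # flip: 'group' now overcompensated
  expect_error(fit_covariance_constrained(dat, m = 0.5, outcome = "y",
                                          group = "group"),
               "not undercompensated")
})

test_that("MRD penalized regression matches the augmented normal equations", {
  dat <- make_instance(n = 180, p = 5, seed = 28)
  ols <- fit_ols(dat, outcome = "y", group = "group")

  l0 <- fit_mrd_penalized(dat, lambda = 0, outcome = "y", group = "group")
  expect_lt(rel_diff(l0$theta, ols$theta), 1e-8)

  # augmented normal equations (X'X + lambda v v') theta = X'y + lambda t v
  lam <- 30000
  X <- oracle_design(dat)
  g <- dat$group == 1
  v <- colMeans(X[g, , drop = FALSE]) - colMeans(X[!g, , drop = FALSE])
  t0 <- mean(dat$y[g]) - mean(dat$y[!g])
  theta_aug <- solve(crossprod(X) + lam * tcrossprod(v),
                     crossprod(X, dat$y) + lam * t0 * v)
  fit <- fit_mrd_penalized(dat, lambda = lam, outcome = "y", group = "group")
  expect_lt(rel_diff(fit$theta, as.vector(theta_aug)), 1e-8)

  # dominating penalty pushes the mean residual difference to zero
  big <- fit_mrd_penalized(dat, lambda = 1e12 * sd(dat$y), outcome = "y",
                           group = "group")
  expect_lt(abs(mean_residual_difference(dat$y, big$fitted, dat$group)),
            1e-6 * sd(dat$y))

  expect_error(fit_mrd_penalized(dat, lambda = -1, outcome = "y",
                                 group = "group"), "non-negative")
})

test_that("net compensation penalized regression has the hand-derived closed form", {
  dat <- make_instance(n = 160, p = 4, seed = 29)
  ols <- fit_ols(dat, outcome = "y", group = "group")

  l0 <- fit_netcomp_penalized(dat, lambda = 0, outcome = "y", group = "group")
  expect_lt(rel_diff(l0$theta, ols$theta), 1e-8)

  # differentiate SSE + lambda * sum_g(y - x'theta) by hand:
  # theta = (X'X)^{-1} (X'y + (lambda/2) sum_g x_i)
  lam <- 10
  X <- oracle_design(dat)
  sg <- colSums(X[dat$group == 1, , drop = FALSE])
  theta_hand <- solve(crossprod(X), crossprod(X, dat$y) + (lam / 2) * sg)
  fit <- fit_netcomp_penalized(dat, lambda = lam, outcome = "y", group = "group")
  expect_lt(rel_diff(fit$theta, as.vector(theta_hand)), 1e-8)

  # group design rows all zero -> penalty gradient vanishes, OLS for all lambda
  set.seed(30)
  n <- 60
  a <- rep(c(1, 0), each = n / 2)
  zdat <- tibble::tibble(x1 = rnorm(n) * (a == 0), group = a,
                         y = rnorm(n) + (a == 0) * 2)
  zfit <- fit_netcomp_penalized(zdat, lambda = 500, outcome = "y",
                                group = "group", features = "x1",
                                intercept = FALSE)
  zols <- fit_ols(zdat, outcome = "y", group = "group", features = "x1",
                  intercept = FALSE)
  expect_equal(zfit$theta, zols$theta, tolerance = 1e-10)
  # and the group-mean equality constraint is infeasible there
  expect_error(fit_average_constrained(zdat, outcome = "y", group = "group",
                                       features = "x1", intercept = FALSE),
               "zero vector")
})

test_that("group mean residual decreases monotonically in the net compensation penalty", {
  dat <- make_instance(n = 200, p = 4, seed = 31)
  lambdas <- c(0, 1, 5, 20, 100)
  resid_g <- vapply(lambdas, function(l) {
    fit <- fit_netcomp_penalized(dat, lambda = l, outcome = "y", group = "group")
    mean((dat$y - fit$fitted)[dat$group == 1])
  }, numeric(1))
  expect_true(all(diff(resid_g) < 0))  # strictly decreasing
})

test_that("netcomp constrained regression binds at z and maps to the penalized form", {
  dat <- make_instance(n = 180, p = 4, seed = 32)
  ols <- fit_ols(dat, outcome = "y", group = "group")
  resid_ols <- mean((dat$y - ols$fitted)[dat$group == 1])
  expect_gt(resid_ols, 0)

  # inactive bound returns OLS
  loose <- fit_netcomp_constrained(dat, z = resid_ols + 1, outcome = "y",
                                   group = "group")
  expect_lt(rel_diff(loose$theta, ols$theta), 1e-6)

  # binding bound: achieved group mean residual equals z
  z <- resid_ols / 2
  tight <- fit_netcomp_constrained(dat, z = z, outcome = "y", group = "group")
  expect_equal(mean((dat$y - tight$fitted)[dat$group == 1]), z,
               tolerance = 1e-6)

  # one-to-one correspondence: the penalized fit at lambda = nu / n_g
  # (nu = KKT multiplier of the binding constraint) reproduces the solution
  nu <- tight$constraint$multiplier
  expect_gt(nu, 0)
  lam <- nu / sum(dat$group == 1)
  pen <- fit_netcomp_penalized(dat, lambda = lam, outcome = "y", group = "group")
  expect_lt(rel_diff(pen$theta, tight$theta), 1e-6)

  expect_error(fit_netcomp_constrained(dat, z = 0, outcome = "y",
                                       group = "group"), "positive")
})

test_that("solver route and closed form agree for every estimator", {
  for (s in 1:5) {
    dat <- make_instance(n = 100 + 10 * s, p = 3 + (s %% 3), seed = 40 + s)
    fits <- list(
      list(fit_ols, list()),
      list(fit_average_constrained, list()),
      list(fit_weighted_average_constrained, list(alpha = 0.3)),
      list(fit_covariance_constrained, list(m = 0.5)),
      list(fit_mrd_penalized, list(lambda = 50)),
      list(fit_netcomp_penalized, list(lambda = 5)),
      list(fit_netcomp_constrained, list(z = 0.1))
    )
    for (f in fits) {
      args <- c(list(dat), f[[2]], list(outcome = "y", group = "group"))
      cf <- do.call(f[[1]], c(args, list(solver = "closed_form")))
      qp <- do.call(f[[1]], c(args, list(solver = "qp")))
      expect_lt(rel_diff(cf$theta, qp$theta), 1e-6)
      expect_equal(cf$solver_status, "closed_form")
      expect_match(qp$solver_status, "solver_")
    }
  }
})

test_that("constrained and penalized fits never beat OLS on in-sample SSE", {
  dat <- make_instance(n = 150, p = 4, seed = 50)
  ols <- fit_ols(dat, outcome = "y", group = "group")
  others <- list(
    fit_average_constrained(dat, outcome = "y", group = "group"),
    fit_weighted_average_constrained(dat, alpha = 0.4, outcome = "y",
                                     group = "group"),
    fit_covariance_constrained(dat, m = 0.3, outcome = "y", group = "group"),
    fit_mrd_penalized(dat, lambda = 100, outcome = "y", group = "group"),
    fit_netcomp_penalized(dat, lambda = 10, outcome = "y", group = "group"),
    fit_netcomp_constrained(dat, z = 0.05, outcome = "y", group = "group")
  )
  for (fit in others) {
    expect_gte(fit$sse, ols$sse)
    expect_lte(fit$r_squared, ols$r_squared)
  }
})

test_that("coefficients respond continuously to hyperparameter perturbations", {
  dat <- make_instance(n = 150, p = 4, seed = 51)
  pairs <- list(
    function(h) fit_weighted_average_constrained(dat, alpha = h, outcome = "y",
                                                 group = "group"),
    function(h) fit_covariance_constrained(dat, m = h, outcome = "y",
                                           group = "group"),
    function(h) fit_mrd_penalized(dat, lambda = 100 * h, outcome = "y",
                                  group = "group"),
    function(h) fit_netcomp_penalized(dat, lambda = 10 * h, outcome = "y",
                                      group = "group")
  )
  for (fitter in pairs) {
    base <- fitter(0.5)
    bumped <- fitter(0.5 + 1e-6)
    expect_lt(rel_diff(base$theta, bumped$theta), 1e-4)
  }
})

test_that("predict validates columns and reproduces training fits", {
  dat <- make_instance(n = 100, p = 3, seed = 52)
  fit <- fit_ols(dat, outcome = "y", group = "group")
  expect_equal(predict(fit, dat), fit$fitted)
  expect_error(predict(fit, dat[, c("x1", "y")]), "missing design columns.*x2")

  io <- tibble::tibble(y = c(2, 4, 6, 9), group = c(1, 0, 1, 0))
  cfit <- fit_ols(io, outcome = "y", group = "group", features = character(0))
  expect_equal(predict(cfit, io), rep(mean(io$y), 4))
})

test_that("fitted models serialize to JSON and back", {
  dat <- make_instance(n = 80, p = 3, seed = 53)
  fit <- fit_covariance_constrained(dat, m = 0.4, outcome = "y", group = "group")
  path <- withr::local_tempfile(fileext = ".json")
  write_fair_fit(fit, path)
  back <- read_fair_fit(path)
  expect_equal(back$theta, fit$theta)
  expect_equal(back$method, fit$method)
  expect_equal(back$hyperparameter$m, 0.4)
  expect_equal(predict(back, dat), predict(fit, dat))
})

test_that("tidy and glance summarise fits in the expected shapes", {
  dat <- make_instance(n = 90, p = 3, seed = 54)
  fit <- fit_mrd_penalized(dat, lambda = 10, outcome = "y", group = "group")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), length(fit$theta))
  gl <- glance(fit)
  expect_equal(gl$method, "mrd_penalized")
  expect_equal(gl$hyperparameter, "lambda = 10")
  expect_equal(gl$n, nrow(dat))
})
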