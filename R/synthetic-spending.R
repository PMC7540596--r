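#' Generate a claims-like spending population
#'
#' Simulates a person-level dataset shaped like the private claims samples
#' used to calibrate risk-adjustment formulas: demographics (sex, age),
#' binary condition-category indicators, a protected-group flag of
#' prevalence ~13.8% whose members spend roughly twice as much, and a heavily
#' right-skewed annual spending outcome (mean far above median).
#'
#' Spending follows a two-part model per group: a point mass at zero (no
#' claims that year) and a lognormal positive part whose location and scale
#' are solved in closed form so that each group's mean and median hit the
#' calibration targets exactly in expectation. Condition indicators are
#' driven by a latent severity score shared with spending, so they predict
#' spending within each group. `group_signal_leakage` sets how much of the
#' protected group the condition profile captures, through two channels: a
#' designated flag condition whose rate is elevated for members (at leakage
#' 1 it equals the group indicator, making OLS net compensation for the
#' group exactly zero by residual orthogonality), and a comorbidity cluster
#' of common conditions with strongly elevated rates among members, the way
#' coded condition categories co-occur with a diagnosis-defined group. At
#' leakage 0 conditions are independent of the group and the
#' undercompensation is maximal; the default 0.2 leaves the group visibly
#' underpaid while the condition set absorbs roughly half of its spending
#' shift and spans enough of the group indicator that constrained
#' estimators can repair payments without inflating everyone else's.
#'
#' @param n Population size (default 100 000).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param p_female Proportion female (default 0.52).
#' @param age_range Inclusive integer age range (default 21-63).
#' @param age_median Target median age (default 45).
#' @param n_conditions Number of binary condition indicators (default 62).
#' @param condition_prevalence Optional vector of per-condition prevalences;
#'   default log-spaced from 0.0005 to 0.15 so the rarest condition keeps at
#'   least 30 carriers at the default `n`.
#' @param p_group Protected-group prevalence (default 0.138).
#' @param target_moments Currency calibration targets: list with
#'   `group_mean`, `group_median`, `complement_mean`, `complement_median`
#'   (defaults 11520, 3744, 5880, 1274; the implied overall mean/median are
#'   ~6651 and ~1511).
#' @param p_zero Probability of zero annual spending per group,
#'   `c(g = 0.08, gc = 0.20)`.
#' @param group_signal_leakage In \[0, 1\]: how much of the group the
#'   condition set captures. It drives both the designated flag condition
#'   (the highest-prevalence indicator, which equals the group indicator at
#'   leakage 1) and the comorbidity-cluster elevation (liability shift
#'   `5 * leakage` on the twelve next-most-prevalent conditions); at 0
#'   conditions are independent of the group.
#' @param severity_loading Correlation between the latent severity score and
#'   each non-cluster condition's liability (default 0.5); cluster
#'   conditions load at 0.15, marking conditions that flag the group more
#'   than they price its spending.
#' @param diagnosable_share Share of the spending z-score variance carried by
#'   the diagnosable severity component that conditions can track (default
#'   0.35); the remainder is idiosyncratic, keeping attainable R2 at the
#'   levels typical of claims-based risk adjustment rather than near-perfect.
#' @return A tibble with columns `person_id`, `female`, `age`,
#'   `H001`...`H0nn`, `group`, `y`, carrying the generator configuration in
#'   `attr(, "config")`.
#' @examples
#' pop <- generate_spending_population(n = 5000, seed = 1)
#' mean(pop$y); median(pop$y)          # mean >> median
#' tapply(pop$y, pop$group, mean)      # group spends about twice as much
#' @export
generate_spending_population <- function(
    n = 100000, seed = 1,
    p_female = 0.52,
    age_range = c(21, 63), age_median = 45,
    n_conditions = 62, condition_prevalence = NULL,
    p_group = 0.138,
    target_moments = list(group_mean = 11520, group_median = 3744,
                          complement_mean = 5880, complement_median = 1274),
    p_zero = c(g = 0.08, gc = 0.20),
    group_signal_leakage = 0.2,
    severity_loading = 0.5,
    diagnosable_share = 0.35) {

  stopifnot(n >= 2, p_female > 0, p_female < 1, p_group > 0, p_group < 1,
            group_signal_leakage >= 0, group_signal_leakage <= 1,
            severity_loading > 0, severity_loading < 1,
            diagnosable_share > 0, diagnosable_share <= 1)
  tm <- target_moments
  if (any(unlist(tm) <= 0)) abort("Target moments must be positive.")
  if (tm$group_mean <= tm$complement_mean) {
    abort("Infeasible targets: group mean spending must exceed the complement mean.")
  }
  if (is.null(condition_prevalence)) {
    # log-spaced; the floor keeps >= 30 expected carriers per condition (the
    # usual retention rule for condition categories), whatever the n
    floor_prev <- max(5e-4, 30 / n)
    condition_prevalence <- exp(seq(log(floor_prev), log(0.15),
                                    length.out = n_conditions))
  }
  if (length(condition_prevalence) != n_conditions ||
      any(condition_prevalence <= 0) || any(condition_prevalence >= 1)) {
    abort("`condition_prevalence` must give one proportion in (0,1) per condition.")
  }

  par_g <- two_part_lognormal_params(tm$group_mean, tm$group_median,
                                     p_zero[["g"]])
  par_c <- two_part_lognormal_params(tm$complement_mean, tm$complement_median,
                                     p_zero[["gc"]])

  set.seed(seed)
  group <- rbinom(n, 1, p_group)
  female <- rbinom(n, 1, p_female)
  age <- sample_ages(n, age_range, age_median)

  pz <- ifelse(group == 1, p_zero[["g"]], p_zero[["gc"]])
  spender <- runif(n) >= pz
  # spending z-score = diagnosable severity + idiosyncratic variation;
  # conditions see only the former, which caps attainable R2 at realistic
  # risk-adjustment levels
  h <- rnorm(n)
  z <- sqrt(diagnosable_share) * h + sqrt(1 - diagnosable_share) * rnorm(n)
  mu <- ifelse(group == 1, par_g$mu, par_c$mu)
  sigma <- ifelse(group == 1, par_g$sigma, par_c$sigma)
  y <- ifelse(spender, exp(mu + sigma * z), 0)
  # latent severity driving diagnoses: low for people with no claims
  s <- ifelse(spender, h, rnorm(n, mean = -1.5, sd = 0.5))

  # comorbidity cluster: the dozen most prevalent conditions (after the
  # flag) run strongly elevated rates among group members - the way a
  # diagnosis-defined group co-occurs with a cluster of coded conditions -
  # while loading only weakly on spending severity. They give the design
  # matrix genuine span over the group indicator, so constrained estimators
  # can target the group instead of inflating everyone's predictions.
  # Thresholds keep each marginal prevalence on target under the mixture.
  prev_order <- order(condition_prevalence, decreasing = TRUE)
  proxy <- prev_order[1]  # group-linked flag condition
  cluster <- prev_order[seq(2, min(13, n_conditions))]
  H <- matrix(0L, nrow = n, ncol = n_conditions)
  for (t in seq_len(n_conditions)) {
    if (t == proxy) next
    in_cluster <- t %in% cluster
    delta <- if (in_cluster) 5 * group_signal_leakage else 0
    rho <- if (in_cluster) 0.15 else severity_loading
    thr <- mixture_threshold(condition_prevalence[t], delta, p_group)
    H[, t] <- as.integer(rho * s + delta * group +
                           sqrt(1 - rho^2) * rnorm(n) > thr)
  }
  lk <- group_signal_leakage
  p1 <- condition_prevalence[proxy]
  p_flag <- ifelse(group == 1, p1 + lk * (1 - p1), p1 * (1 - lk))
  H[, proxy] <- rbinom(n, 1, p_flag)

  colnames(H) <- sprintf("H%03d", seq_len(n_conditions))
  out <- dplyr::bind_cols(
    tibble(person_id = seq_len(n), female = female, age = age),
    as_tibble(as.data.frame(H)),
    tibble(group = group, y = y)
  )
  attr(out, "config") <- list(
    n = n, seed = seed, p_female = p_female, age_range = age_range,
    age_median = age_median, n_conditions = n_conditions,
    condition_prevalence = condition_prevalence, p_group = p_group,
    target_moments = tm, p_zero = p_zero,
    group_signal_leakage = group_signal_leakage,
    severity_loading = severity_loading,
    diagnosable_share = diagnosable_share,
    lognormal = list(g = par_g, gc = par_c), flag_condition = proxy,
    comorbidity_cluster = cluster
  )
  out
}

# Closed-form calibration of the two-part lognormal: with zero-spending
# probability pi < 1/2, target mean M and median med, the positive part
# exp(mu + sigma Z) must satisfy
#   (1 - pi) exp(mu + sigma^2/2) = M
#   mu + sigma * qnorm((1/2 - pi)/(1 - pi)) = log(med)
# which reduces to a quadratic in sigma.
two_part_lognormal_params <- function(mean_target, median_target, p_zero) {
  if (p_zero < 0 || p_zero >= 0.5) {
    abort("Zero-spending probability must be in [0, 0.5) for the median to be positive.")
  }
  q <- qnorm((0.5 - p_zero) / (1 - p_zero))
  L <- log(mean_target / ((1 - p_zero) * median_target))
  disc <- q^2 + 2 * L
  if (disc <= 0 || (q + sqrt(disc)) <= 0) {
    abort("Infeasible moment targets: mean is too small relative to the median.")
  }
  sigma <- q + sqrt(disc)
  mu <- log(median_target) - q * sigma
  list(mu = mu, sigma = sigma, p_zero = p_zero)
}

# Integer ages with an exact target median: a 6% atom at the median age and
# the rest split evenly (and uniformly) below and above, so the empirical
# median is the target with overwhelming probability at any practical n.
sample_ages <- function(n, age_range, age_median) {
  ages <- seq(age_range[1], age_range[2])
  below <- ages < age_median
  above <- ages > age_median
  if (!any(below) || !any(above) || !age_median %in% ages) {
    abort("`age_median` must lie strictly inside `age_range`.")
  }
  w <- ifelse(below, 0.47 / sum(below),
              ifelse(above, 0.47 / sum(above), 0.06))
  sample(ages, n, replace = TRUE, prob = w)
}

# Threshold for a probit-style condition liability with a group shift delta:
# solves (1-p_g) P(L > thr) + p_g P(L + delta > thr) = target prevalence
# with L approximately standard normal.
mixture_threshold <- function(prevalence, delta, p_group) {
  if (delta == 0) return(qnorm(1 - prevalence))
  f <- function(thr) {
    (1 - p_group) * pnorm(thr, lower.tail = FALSE) +
      p_group * pnorm(thr - delta, lower.tail = FALSE) - prevalence
  }
  stats::uniroot(f, interval = c(-10, 15), tol = 1e-10)$root
}
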