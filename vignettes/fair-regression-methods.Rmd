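---
title: "Fair regression for risk adjustment: models, choices, and what the synthetic data can show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fair regression for risk adjustment: models, choices, and what the synthetic data can show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairadjust)
```

## The statistical problem

Risk adjustment predicts a continuous spending outcome $Y$ from a design
$X$ of demographics and binary condition indicators, and pays insurers
according to $\hat Y$. A prespecified group $g$ (indicator $A$, prevalence
$P(A{=}1)$ estimated by $n_g/N$ from the data at hand, never an external
prior) is *undercompensated* when its mean residual is positive:
$\frac{1}{n_g}\sum_{i\in g}(Y_i - \hat Y_i) > 0$. Every method in this
package is ordinary least squares with a group-fairness requirement added
either as a linear constraint or as a penalty on the residuals.

All the resulting problems are convex quadratics in the coefficient vector
$\theta$ with at most one linear equality and one linear inequality, so
exact solutions follow from the KKT conditions — no iterative solver is
needed. Two independent solution paths are implemented and must agree: the
method-specific closed forms (`solver = "closed_form"`, the default, e.g.
$\theta = \theta_{OLS} - K d\,[d'Kd]^{-1}(d'\theta_{OLS} - b)$ with
$K = (X'X)^{-1}$ for a single equality $d'\theta = b$) and a generic
KKT/active-set route (`solver = "qp"`). The test suite additionally checks
both against a third-party quadratic-programming library on randomized
instances.

### Residual orientation

The *metrics* report $\hat Y - Y$ averages, so that a negative net
compensation reads "the group is paid too little"; the *estimator*
constraint and penalty terms are written on $Y - \hat Y$, so that a positive
group mean residual is what a penalty should shrink. Both orientations are
deliberate and `residual_orientation()` names them; mixing them up flips
every sign downstream.

## The estimators and their hyperparameters

* **Average constrained** — one equality: group mean prediction equals group
  mean observed spending. In-sample net compensation for $g$ is zero to
  machine precision (the tests assert $10^{-6}\,\mathrm{sd}(Y)$).
* **Weighted average constrained**, $\alpha \in [0,1]$ (dimensionless) — the
  equality target becomes $(1-\alpha)\times$ observed group mean
  $+\ \alpha\times$ OLS-predicted group mean. $\alpha = 1$ *is* OLS and
  $\alpha = 0$ *is* the average-constrained fit; both identities are tested.
* **Covariance constrained**, $m \in [0,1]$ (dimensionless) — one
  inequality $\mathrm{Cov}(A, Y - X\theta) \le m\,c^*$, where $c^*$ is the
  covariance under OLS *on the same training data* (never held-out data).
  The constraint is kept on the covariance scale (the $1/N$ included), so
  its bound is directly comparable to the reported fair-covariance metric.
  Only the one-sided bound is enforced by default: the concern is the
  group's residuals being too high, and with $c^* > 0$ the optimum of the
  one-sided problem already satisfies the lower bound, which is available
  behind `two_sided = TRUE` for completeness. Solvers work with closed
  constraint sets, so the bound is implemented as $\le$; at an optimum the
  distinction from $<$ carries no mass. If $c^* \le 0$ the group is not
  undercompensated under OLS, a one-sided tightening toward zero is
  meaningless, and the fit refuses with an explanatory error rather than
  guessing a behavior.
* **Mean-residual-difference penalized**, $\lambda \ge 0$ — adds
  $\lambda\,u(\theta)^2$ with $u$ the mean residual difference. Because the
  penalty is squared, its gradient carries $u$ itself and the fit approaches
  residual-mean parity smoothly as $\lambda \to \infty$ (tested at
  $\lambda = 10^{12}\,\mathrm{sd}(Y)$); useful $\lambda$ are of order $N$.
* **Net-compensation penalized**, $\lambda \ge 0$ — adds
  $\lambda \sum_{i \in g}(Y_i - \hat Y_i)$, a *linear* penalty on the summed
  group residual. The closed form is
  $\theta = (X'X)^{-1}\!\left(X'y + \tfrac{\lambda}{2}\sum_{i\in g} x_i\right)$.
* **Net-compensation constrained**, $z > 0$ (currency) — the constrained
  counterpart: group *mean* residual $\le z$. When the bound binds, its KKT
  multiplier $\nu$ identifies the penalized fit that produces the same
  coefficients ($\lambda = \nu / n_g$); the correspondence is exercised in
  the tests.

### Why the net-compensation penalty acts on the summed residual

A common way to write this penalty normalizes by the group size,
$\lambda\cdot\frac{1}{n_g}\sum_{i\in g}(Y_i - \hat Y_i)$. That normalization
has a structural consequence worth spelling out. For a linear penalty the
coefficient shift is $\frac{\lambda}{2}K\,d$ with $d$ the (mean) group
design row, and the induced reduction in the group mean residual is
$\frac{\lambda}{2}\,d'Kd \le \frac{\lambda}{2 n_g}$ — a hard algebraic bound
(via $a'Ha \le a'a$ for the projection $H$). With $n_g$ in the thousands, a
$\lambda$ of order $N/10$ could then move group payments by well under a
dollar: the normalized penalty is inert at every practically quoted
$\lambda$, and no observable trade-off curve exists on that scale. On the
summed residual the reduction is $\frac{\lambda}{2}\,s$, where
$s = a'Ha/n_g \in [n_g/N,\,1]$ is the share of the group indicator spanned
by the design — so $\lambda \approx N/10$ produces visible, partial
repayment, and a few multiples of that overshoot past parity. This package
therefore penalizes the *sum*. Two observable consequences follow and are
tested: the group mean residual is strictly decreasing in $\lambda$
(whenever the group design rows are not all zero), and far past parity the
group flips into overcompensation with a *negative* fair covariance — the
known failure mode of linear fairness penalties pushed too hard.

### Default grids

`default_estimator_grid(n)` uses $m, \alpha \in \{0.2, 0.4, 0.6, 0.8\}$ and
$\lambda \in \{N/100,\ N/10,\ N/5,\ 3N/10\}$ for both penalties, so the
grids scale with the sample and bracket the $\lambda = N/10$ rule of thumb.

## Evaluation protocol

`cross_validate()` uses five folds by default, stratified on the group
indicator. Stratification is the default because every training split must
contain both groups for the constrained fits to be well defined; plain
random folds are available (`stratify = FALSE`) and the harness errors with
a pointer to stratification if a split loses a group. All reports are
computed from *pooled held-out* predictions — each person predicted exactly
once — and OLS is always included as the reference configuration. The
$c^*$ used to scale the fair covariance in reports comes from the pooled
held-out OLS residuals (so the OLS row scales to exactly 1); the $c^*$ used
*inside* the covariance-constrained fit remains a training-fold quantity.

Two conventions are fixed package-wide. The covariance divisor is $N$, not
$N-1$ (matching the $1/N$ in the constraint derivation; at the package's
problem sizes the difference is far below reporting precision). The design
includes an intercept by default: without one, the identities the suite
leans on (residuals summing to zero under OLS, $R^2$ decompositions)
fail; `intercept = FALSE` is available.

Reporting rounds currency to whole dollars, ratios to three decimals and
$R^2$ to one decimal — presentation only; all computation is at full
precision.

When a single configuration per method must be chosen,
`select_configuration()` maximizes the group predictive ratio subject to a
relative cross-validated $R^2$ loss of at most 10% (the same ceiling the
frontier filter uses); the ceiling is a user argument, not a constant.

## The synthetic claims population

No claims data ship with the package; `generate_spending_population()`
stands in for a private sample whose published descriptives it is calibrated
to: 52% female, ages 21–63 with median 45, 62 condition indicators each with
at least 30 expected carriers, a protected group of prevalence 13.8%, group
mean/median spending \$11 520/\$3 744 against \$5 880/\$1 274 for the
complement (implying an overall mean near \$6 651 and median near \$1 511).

**Spending.** Per group, a two-part model: a point mass at zero (no claims:
8% in the group, 20% outside — group members nearly all use care) and a
lognormal positive part. Given the zero probability $\pi$, the target mean
$M$ and median $m$, the lognormal $(\mu, \sigma)$ solve
$(1-\pi)e^{\mu + \sigma^2/2} = M$ and
$\mu + \sigma\,\Phi^{-1}\!\big(\tfrac{1/2 - \pi}{1 - \pi}\big) = \log m$,
a quadratic in $\sigma$ solved in closed form — so the group-level means and
medians are exact in expectation, and the acceptance checks compare sample
moments against them within three Monte-Carlo standard errors over 20 seeds.
The implied $\sigma \approx 1.4$–$1.6$ gives the heavy right skew
characteristic of annual spending.

**Conditions.** A latent severity score drives both spending and diagnoses,
but only a `diagnosable_share` (default 0.35) of the spending z-score
variance is visible to the conditions; the rest is idiosyncratic. This caps
attainable $R^2$ near the 10–20% range typical of claims-based risk
adjustment — early drafts without the split reached an unrealistic 55%.
Condition prevalences are log-spaced from $\max(5\times10^{-4}, 30/n)$ to
0.15, mirroring the usual ≥30-carriers retention rule at any $n$.

**Group signal.** `group_signal_leakage` (default 0.2) controls how much of
the protected group the condition profile captures, through two channels:

1. a *flag* condition (the most prevalent indicator) whose rate is elevated
   for members and which equals the group indicator exactly at leakage 1 —
   giving the exact anchor that OLS net compensation for the group is then
   zero by residual orthogonality;
2. a *comorbidity cluster* — the twelve next-most-prevalent conditions get a
   probit liability shift of $5\times$leakage for members, with weak
   severity loading (0.15 vs 0.5 elsewhere), and thresholds re-solved so
   marginal prevalences stay on target.

The cluster shape matters more than it may look. If the group-linked signal
is smeared thinly across severity-linked conditions, the design moves
spending dollars without *spanning* the group indicator, and the cheapest
least-squares way to satisfy a group-mean constraint is to inflate the
intercept — everyone's payment rises and the complement group is heavily
overpaid, which is not how well-specified claims data behave. Concentrated,
weakly-severity-linked cluster conditions give the regression genuine group
span (about half the group indicator's variance at default leakage), so
constrained fits can target the group. At default leakage the OLS profile on
a 10 000-person draw — predictive ratio ≈ 0.9, net compensation ≈
−\$1 100 to −\$1 900 depending on seed, positive fair covariance — sits in
the regime the estimators are designed for, with roughly half of the
group's spending shift captured by the codes.

One residual caveat: with an intercept in the design and imperfect group
span, a group-mean repair necessarily spills a fraction of its budget
through the intercept, so the constrained fits remove *most* but not all of
the residual covariance (the acceptance check asserts at least a 70%
reduction). Driving the spillover to zero requires near-perfect span, which
simultaneously erases the undercompensation being studied.

**What the generator does not emulate.** Demographics are independent of
spending (age and sex act as near-null regressors rather than carrying the
mild real-world gradients); there is no longitudinal prior-year/next-year
structure — predictors and outcome are drawn jointly; no diagnosis-code
hierarchy or mapping logic exists, indicators are emitted directly; and at
leakage 0 a faint group–condition correlation survives through the
different zero-spending rates. Tests passing on these data show the
estimators and harness behave as the theory says on data *shaped like*
claims; they do not certify performance on any real claims sample.

## The simulation testbed

`generate_simulation_population()` builds populations of 100 000 with
covariates $X_1,\dots,X_9$ ($X_1$–$X_3$, $X_6$, $X_8$, $X_9$ standard
normal; $X_4$, $X_5$, $X_7$ binary) and two protected classes,
$A_1 = \{X_4{=}1 \text{ or } X_1 > 1.2\}$ and
$A_2 = \{X_4{=}1 \text{ or } X_2 > 1.2\}$ — distinct but overlapping
through $X_4$, as a multi-group fairness setting requires. Outcome forms:

* **complex** (scenario 1): main effects plus $3X_1^2$, a $5X_1X_4$
  interaction and heteroscedastic noise; estimators see only $X_2$–$X_7$.
  Omitting $X_1$ concentrates the unmodelled terms in the $A_1$ tail, so
  misspecified OLS undercompensates $A_1$ — and a hard group-mean
  constraint, estimated from a noisy small-sample group, costs a large
  share of cross-validated $R^2$.
* **simple** (scenario 2): near-linear with a mild hinge
  $3\max(X_1 - 1, 0)$; estimators see all nine covariates, so nothing is
  omitted but $X_6$–$X_9$ are pure noise and the hinge is unmodelled.
* **linear**: purely linear control; with `noise_sd = 0`, OLS on the true
  covariates recovers the coefficients exactly and all fairness metrics
  vanish — the well-specified limit the tests pin down.

The exact functional forms are package choices (configurable via
`scenario_config()`), not reproductions of any external specification. One
design iteration was needed: the linear signal ($X_2$ coefficient) was set
strong enough (8) that *partial* fairness corrections are affordable — a
net-compensation penalty at $\lambda = N/100$ costs a few percent of $R^2$ —
while the *full* group-mean constraint under misspecification still costs
far more than the 10% frontier ceiling. That is the regime of interest: the
scenario is meant to separate methods that can buy fairness gradually from
those that must buy it all at once. `run_scenario()` at 50 replicates of
$n = 1000$ reproduces the separation: average- and covariance-constrained
fits fall off the ≤10% relative-$R^2$-loss frontier while the partial
net-compensation penalty stays on it.

## Problem sizes in the test suite

The suite runs at sizes chosen to make every claim sharp but cheap: oracle
equivalence on 50 random instances with $N \le 200$ and at most 10 columns;
constraint exactness and the cross-validated ordering on 10 000-person
populations; generator calibration on twenty populations of 100 000; the
simulation finding on 50 replicates of $n = 1000$ drawn from a population
of 100 000. The whole suite completes in about a minute on one CPU.

## Known limitations

* One protected group per fit; simultaneous multi-group constraints are not
  implemented (the simulation module tracks a second class only for
  evaluation).
* No inference (standard errors, confidence intervals) on the fairness
  metrics.
* Rank-deficient designs are refused outright rather than resolved by
  pseudo-inversion — risk-adjustment coefficients are policy-interpreted,
  so silent non-uniqueness is worse than an error naming the collinear
  columns.
* The covariance-constrained fit requires $c^* > 0$; repairing an
  *over*compensated group is out of scope by construction.
* Hyperparameter search is grid-based; nothing automated explores the
  $\lambda$ space.
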