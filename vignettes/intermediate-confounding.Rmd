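---
title: "Mediation analysis with an exposure-induced confounder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation analysis with an exposure-induced confounder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semmed)
```

## The problem

Classical mediation analysis separates the effect of a binary exposure $X$
on a continuous outcome $Y$ into a part transmitted through a continuous
mediator $M$ and a part that is not.  The nonparametric identification
results behind natural direct and indirect effects, however, require that
no confounder of the $M$–$Y$ relationship be itself affected by the
exposure.  Many realistic systems violate exactly this: an
*exposure-induced* (intermediate) confounder $L$ sits causally between $X$
and both $M$ and $Y$.  A canonical epidemiological example is maternal
overweight ($X$) influencing a child's eating behaviour score ($Y$) partly
through childhood body size ($M$), with birth weight ($L$) affected by the
exposure and affecting both downstream variables.

semmed implements estimation in this setting by combining the structural
equation modelling tradition (which handles $L$ naturally, via a recursive
system of linear equations) with the potential-outcome definitions of the
estimands and the parametric assumptions under which they are identified.

## The model

The package fits the recursive three-equation linear system

$$
\begin{aligned}
L &= \gamma_0 + \gamma_x X + \gamma_c' C + \epsilon_l\\
M &= \alpha_0 + \alpha_x X + \alpha_l L + \alpha_c' C
     + \alpha_{xl} XL + \epsilon_m\\
Y &= \beta_0 + \beta_x X + \beta_m M + \beta_l L + \beta_c' C
     + \beta_{mm} M^2 + \beta_{ll} L^2 + \beta_{xl} XL + \beta_{xm} XM
     + \epsilon_y,
\end{aligned}
$$

with mean-zero errors of constant variances $\sigma_l^2, \sigma_m^2,
\sigma_y^2$, mutually uncorrelated and uncorrelated with the exogenous
$X$ and baseline covariates $C$.  Which of the optional terms
($\alpha_{xl}$; $\beta_{mm}, \beta_{ll}, \beta_{xl}, \beta_{xm}$) are
present is declared in a `sem_spec()`.  An $LM$ product in the outcome
equation is rejected at validation: under either identification assumption
available here its coefficient is constrained to zero, so permitting it
would only invite silent misspecification.

Estimation is equation-wise ordinary least squares.  For a recursive system
with independent errors, OLS is consistent and asymptotically equivalent to
full-information maximum likelihood, and it keeps the joint coefficient
covariance exactly block-diagonal; when the independence assumption is in
doubt, the nonparametric bootstrap (`bootstrap_mediation()`) is the
fallback.  Residual variances use the unbiased $n - p$ denominator; this
matters because $\hat\sigma_l^2$ and $\hat\sigma_m^2$ enter the estimand
formulas of the quadratic model.  The fitter refuses tables with missing
values instead of dropping rows silently, so the analysis $n$ is always an
explicit, caller-visible choice.

## Estimands and identification

The targets are the total causal effect
$\mathrm{TCE} = E\{Y(1)\} - E\{Y(0)\}$, the pure natural direct effect
$\mathrm{PNDE} = E\{Y(1, M(0))\} - E\{Y(0, M(0))\}$, the total natural
indirect effect $\mathrm{TNIE} = \mathrm{TCE} - \mathrm{PNDE}$, and the
controlled direct effect
$\mathrm{CDE}(m) = E\{Y(1, m)\} - E\{Y(0, m)\}$.

With an intermediate confounder present the natural effects are not
nonparametrically identified; one of two parametric restrictions on the
outcome model must hold:

* **Robins–Greenland**: no individual-level $X$–$M$ interaction on $Y$.
  For this model class that is exactly $\beta_{xm} = 0$.
* **Petersen**: conditional on $C$, the CDE does not vary with $M(0)$.
  Here both $Y(1,m) - Y(0,m)$ and $M(0)$ are functions of $\epsilon_l$
  unless $\beta_{ll} = \beta_{xl} = 0$, which is therefore the required
  constraint.

`check_identification()` fits the *unconstrained* associational outcome
model (all of $M^2, L^2, XL, XM$) and reports a single-coefficient Wald
test for $\beta_{xm}$ and a 2-df joint Wald test for
$(\beta_{xl}, \beta_{ll})$, plus the per-term p-values.  The
recommendation rule is a pure function of the two p-values: rejecting a
constraint excludes the corresponding assumption; if neither is rejected
both are admissible and results should be reported under both; if both are
rejected the natural effects are unidentified in this model class.  Two
deliberate choices: the tests use classical OLS standard errors (the
robust/sandwich alternative would only matter under heteroskedasticity,
which the model class excludes), and no multiple-testing correction is
applied across the two hypotheses — they select between parameterizations
rather than test discoveries.

```{r diagnostics}
sim <- simulate_sem(2749, seed = 1)
check_identification(sim$data, sim$spec)$recommendation
```

## Estimation by combination

Conditional on a covariate row $c$, the fitted system implies Gaussian laws
$L(x) \sim N(\mu_L(x,c), \sigma_l^2)$ with
$\mu_L(x,c) = \gamma_0 + \gamma_x x + \gamma_c'c$, and marginally
$M(x') \sim N(\mu_M(x',c), v_M(x'))$ with

$$
\mu_M(x',c) = \alpha_0 + \alpha_x x' + (\alpha_l + \alpha_{xl}x')
\mu_L(x',c) + \alpha_c'c, \qquad
v_M(x') = (\alpha_l + \alpha_{xl}x')^2\sigma_l^2 + \sigma_m^2 .
$$

In the nested counterfactual $Y(x, M(x'))$, the confounder is integrated
under exposure $x$ while the mediator is integrated under $x'$ through its
own independent confounder draw.  Because the outcome equation is quadratic
with no $LM$ product, that triple integral collapses to first and second
moments:

$$
E\{Y(x, M(x')) \mid c\} =
\beta_0 + \beta_x x + \beta_c'c
+ (\beta_l + \beta_{xl}x)\mu_L(x,c)
+ \beta_{ll}\{\mu_L(x,c)^2 + \sigma_l^2\}
+ (\beta_m + \beta_{xm}x)\mu_M(x',c)
+ \beta_{mm}\{\mu_M(x',c)^2 + v_M(x')\}.
$$

The estimands are contrasts of the legs $(x,x') \in
\{(1,1),(1,0),(0,0)\}$; $\mathrm{CDE}(m)$ replaces the $M(x')$ moments
with the fixed $m$ and $m^2$.  Covariate standardization is *empirical*:
the per-row closed form is averaged over the observed covariate rows.  This
handles discrete and continuous covariates uniformly; a moment-based
alternative could differ in the third decimal for skewed covariates, which
we accept.  With all optional terms absent the expressions reduce exactly
to the familiar path-tracing products, indirect
$\beta_m(\alpha_x + \alpha_l\gamma_x)$ and direct
$\beta_x + \gamma_x\beta_l$ — exposed separately as
`path_tracing_effects()` and used in the tests as an independent check.

Because these moment expressions were derived rather than transcribed, the
package gates them on two independent oracles: `truth_oracle()`, which
evaluates the same integrals by nested Gauss–Hermite quadrature (exact for
polynomial integrands; doubling the order moves the result by less than
$10^{-8}$), and the Monte Carlo route below.  One useful consequence of
the algebra: under a Robins–Greenland fit, $\mathrm{CDE}(m) -
\mathrm{PNDE} = \beta_{xm}\{m - \bar\mu_M(0)\} = 0$ for every $m$, so the
two estimates printed for those rows coincide exactly rather than merely
closely.

### Standard errors

SEs use the delta method: the gradient of each combination with respect to
the stacked coefficient vector (central finite differences, relative step
$10^{-6}$ — the expressions are smooth polynomials, so analytic gradients
would gain nothing), propagated through the block-diagonal OLS covariance.
Uncertainty in $\hat\sigma_l^2, \hat\sigma_m^2$ (which enter only through
$\beta_{ll}$ and $\beta_{mm}$ terms) is ignored; its contribution is
$O(\beta_{ll}^2\sigma^4/n)$ and negligible at study scale, and the
bootstrap is available when it is not.  Intervals are normal-approximation
for delta SEs and percentile for bootstrap ones.  The proportion mediated
$\mathrm{TNIE}/\mathrm{TCE}$ is always reported but flagged unstable
whenever the TCE interval covers zero, where a ratio of estimates is
ill-behaved.

## Monte Carlo g-computation

`mediate_montecarlo()` approximates the same integrals by simulation from
the fitted system, as a cross-check of the algebra and as the route that
generalizes beyond closed forms.  Three choices matter:

* **Rao–Blackwellization.** $L$ and $M$ are drawn but $Y$ is evaluated at
  its fitted conditional mean.  Every estimand is a mean of a
  linear/quadratic function, so this is unbiased and strictly reduces
  Monte Carlo variance relative to also drawing $\epsilon_y$.
* **Allocation.** `n_mc` is the *total* number of draws per leg, allocated
  by cycling deterministically over the covariate rows; per-row draw means
  are then combined with the rows' weights.  This keeps weighted covariate
  grids (used when evaluating at known parameters) exact, makes runs with
  degenerate $\sigma^2 = 0$ fits collapse to the deterministic plug-in,
  and lets the reported `mc_se` measure integration error only (pooled
  within-row variance propagated through the weights).  `n_mc` should be
  at least the number of rows; the default is 100,000, at which the two
  estimation routes typically agree to about three decimals.
* **Substreams.** Each leg draws from its own seed-derived substream, so
  legs are independent and every run is bit-reproducible from `seed`,
  which is required rather than defaulted.

Since there is no $LM$ product in the outcome equation, drawing $l$ and
$l'$ independently even when $x = x'$ changes no expectation — verified
numerically in the test suite.

## Sensitivity to unmeasured mediator–outcome confounding

Unmeasured $M$–$Y$ common causes make $\epsilon_m$ and $\epsilon_y$
correlated with some $\rho \ne 0$.  In the full outcome model, $\beta_m$
and $\rho$ are collinear and cannot be estimated jointly; the package
never offers that fit.  Instead `rho_prime()` fits the mediator equation
and the *reduced* outcome equation (on $X$ and $L$ only, omitting $M$) and
returns the sample correlation $\hat\rho'$ of their residuals, with a
percentile bootstrap CI (B = 1000 by default; whether a normal-based
interval was intended in prior practice is ambiguous, and the percentile
interval is the more assumption-free choice).  The reduced equation's
error is $\epsilon_y' = \beta_m\epsilon_m + \epsilon_y$, giving the
population value

$$
\rho' = \frac{\beta_m\sigma_m + \rho\sigma_y}
{\sqrt{\beta_m^2\sigma_m^2 + 2\beta_m\rho\sigma_m\sigma_y + \sigma_y^2}},
$$

implemented as `rho_prime_limit()` and used to calibrate the estimator in
the tests.  The interpretation is reported alongside the number: a
spurious residual correlation of at least $|\hat\rho'|$ would be needed
for the entire indirect effect to be an artefact of unmeasured
confounding, so larger values mean a more robust mediated path.  The
construction assumes no interaction terms; unlike the textbook version we
retain baseline covariates in both working equations by default (the
correlation is then conditional on $C$), with
`include_covariates = FALSE` for the stripped-down variant.

A companion fact, verified by simulation in the test suite: unmeasured
confounding of the $L$–$Y$ edge (a variable $U$ loading on both) biases
$\hat\beta_l$ and $\hat\beta_x$ individually but leaves the natural-effect
*combinations* unbiased, so fitting the SEM does not require assuming no
$L$–$Y$ confounding.

## The synthetic-data generator and what tests on it show

`simulate_sem()` draws from the full structural system under a default
configuration chosen to emulate a realistic cohort of this kind: exposure
prevalence 0.19; two Bernoulli baseline covariates at prevalences 0.55 and
0.13; $L$, $M$, $Y$ on standardized scales with unit error variances; and
default coefficients of study-like magnitude — a modest exposure effect on
the confounder ($\gamma_x = 0.13$), a strong exposure–mediator path
($\alpha_x = 0.55$), mild curvature ($\beta_{mm} = 0.04$,
$\beta_{ll} = 0.03$), an exposure–confounder interaction
($\alpha_{xl} = 0.1$, $\beta_{xl} = 0.08$) and no exposure–mediator
interaction ($\beta_{xm} = 0$), so the Robins–Greenland assumption holds
in truth.  Options add correlated errors ($\rho$), an unmeasured $L$–$Y$
confounder $U$ (excluded from the visible columns), and
covariate-dependent exposure through a logistic link (off by default,
keeping the truth integrals simple).  The error and $U$ realizations are
returned alongside the data, so generator self-consistency is itself
testable.

The generator produces exactly the Gaussian, correctly specified,
completely observed world the estimators assume.  Passing tests therefore
demonstrate the *statistical* properties of the machinery — unbiasedness,
calibration of SEs and test sizes, oracle agreement — not robustness to
non-Gaussian errors, misspecified functional forms, measurement error or
missingness, none of which the generator emulates and all of which real
cohorts exhibit.

## Numerical choices and degenerate inputs

* Quadrature: Gauss–Hermite with 24 nodes per integral (exact for the
  quadratic integrands; the order-doubling test confirms convergence).
* Finite differences: central, relative step $10^{-6}$.
* Collinearity is an error naming the aliased columns, never a silent
  drop.  A fully noise-free system ($\sigma_l^2 = \sigma_m^2 =
  \sigma_y^2 = 0$) is *necessarily* collinear — each endogenous variable
  becomes an exact linear combination of its regressors — so exact
  parameter recovery is only testable equation by equation, which is how
  the test suite does it.
* Degenerate residual variance in the sensitivity module is an error
  (`rho'` undefined), not an `NA`.
* Bootstrap replicates that fail are excluded with a warning above a 1%
  failure rate; seeds are mandatory everywhere randomness occurs.

## Problem sizes in the shipped checks

The test suite and acceptance script exercise the estimators at the sizes
at which their asymptotic claims are meaningful while remaining quick on a
single CPU: single-fit checks at $n$ = 20,000 with 100,000 Monte Carlo
draws; recovery and robustness studies at 200 replicates ($n$ = 20,000 and
5,000 respectively); sensitivity calibration at 100 replicates of $n$ =
10,000; diagnostic size calibration at 500 replicates of $n$ = 2,000; and
a 24-point parameter grid for the oracle-equivalence check.  The
acceptance script runs the full workflow once at the study-like $n$ =
2,749.

## Known limitations

Binary or otherwise non-continuous mediators and outcomes, non-Gaussian
errors, latent variables, measurement error, missing-data handling,
time-varying exposures, and semiparametric estimators (IPW, G-estimation,
targeted learning) are all out of scope.  The delta SEs ignore residual
variance uncertainty as described above.  The `auto` assumption resolution
is purely structural (it reads the fitted term set); choosing between
assumptions on the data is `check_identification()`'s job, and when it
reports `neither_admissible` the honest conclusion is that natural effects
are not identified in this model class.
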