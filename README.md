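# semmed

Causal mediation analysis for a binary exposure *X*, continuous mediator
*M* and continuous outcome *Y* when an **exposure-induced (intermediate)
confounder** *L* of the mediator–outcome relationship is present — the
setting in which the standard nonparametric identification of natural
direct and indirect effects breaks down.  The package is aimed at
epidemiologists and applied biostatisticians who want potential-outcome
estimands with explicit identification assumptions, but whose causal
diagram contains a variable like birth weight sitting between a maternal
exposure and both the child's mediator and outcome.

## What it computes

A recursive linear structural equation model is fitted by equation-wise
least squares:

    L = γ0 + γx X + γc'C + εl
    M = α0 + αx X + αl L + αc'C + αxl XL + εm
    Y = β0 + βx X + βm M + βl L + βc'C + βmm M² + βll L² + βxl XL + βxm XM + εy

From the fit, four estimands are produced on the outcome scale for the
exposure contrast 1 vs 0:

* **TCE** = E{Y(1)} − E{Y(0)} — total causal effect;
* **PNDE** = E{Y(1, M(0))} − E{Y(0, M(0))} — pure natural direct effect;
* **TNIE** = TCE − PNDE — total natural indirect effect;
* **CDE(m)** = E{Y(1, m)} − E{Y(0, m)} — controlled direct effect.

Natural effects require one of two parametric identification assumptions:
**Robins–Greenland** (no exposure–mediator interaction: βxm = 0) or
**Petersen** (CDE constant in M(0): βll = βxl = 0).
`check_identification()` tests both against the unconstrained outcome
model and recommends.  Estimation runs through two independent routes that
cross-validate each other: closed-form **estimation by combination**
(analytic integration of the fitted quadratic outcome model over the
Gaussian laws of L and M, empirical covariate standardization, delta
SEs) and **Monte Carlo g-computation** (the mediation-formula extension of
the g-formula, with bootstrap SEs).  `rho_prime()` quantifies how strong
an unmeasured mediator–outcome confounder would have to be to explain the
entire indirect effect.  `simulate_sem()` and `truth_oracle()` provide a
calibrated synthetic-data generator and an exact Gauss–Hermite quadrature
oracle for the estimands.

## Worked example

```r
library(semmed)

sim <- simulate_sem(2749, seed = 1)          # study-scale synthetic cohort
rep <- check_identification(sim$data, sem_spec("x", "m", "y", "l", c = c("c1", "c2")))
rep$recommendation
#> [1] "both_admissible"

fit <- fit_sem(sim$data, sim$spec)
mediate_combination(fit, "robins_greenland")
#> Mediation estimates (combination, robins_greenland)
#> # A tibble: 4 × 7
#>   estimand estimate     se  ci_low ci_high method      assumption
#>   <chr>       <dbl>  <dbl>   <dbl>   <dbl> <chr>       <chr>
#> 1 tce        0.289  0.0529  0.185    0.393 combination robins_greenland
#> 2 pnde       0.0869 0.0510 -0.0131   0.187 combination robins_greenland
#> 3 tnie       0.202  0.0213  0.160    0.244 combination robins_greenland
#> 4 cde        0.0869 0.0510 -0.0131   0.187 combination robins_greenland
#> proportion mediated: 0.699 (SE 0.128)
#> CDE evaluated at m = 0 ; n = 2749
```

Reading: of a total effect of 0.289 outcome SDs, 0.202 (about 70%) flows
through the mediator; the direct effect (0.087) is not distinguishable
from zero at this sample size.  Under a Robins–Greenland fit CDE(0)
equals the PNDE identically.  The Monte Carlo route reproduces the same
numbers to its integration error (e.g. TNIE 0.201 with `mc_se` 0.002 at
`n_mc = 100000`), which is the practical check that both the algebra and
the simulation are right:

```r
mediate_montecarlo(fit, n_mc = 100000, seed = 2)
```

And the sensitivity analysis:

```r
rho_prime(sim$data, sem_spec("x", "m", "y", "l", c = c("c1", "c2")),
          n_boot = 1000, seed = 3)
#> rho-prime: 0.299  (95% bootstrap CI 0.265, 0.332; B = 1000)
```

A spurious residual correlation of at least 0.30 between the mediator and
outcome equations would be needed for the estimated indirect effect to be
entirely an artefact of unmeasured mediator–outcome confounding — an
implausibly strong confounder, so the mediated path is robust.

See `vignette("intermediate-confounding")` for the model, the derivation
of the closed forms, and every numerical choice.

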