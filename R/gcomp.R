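#' Mediation estimands by Monte Carlo g-computation
#'
#' Approximates the same counterfactual integrals as [mediate_combination()]
#' by simulation from the fitted system (the mediation-formula extension of
#' the g-formula).  For each leg \eqn{(x, x')} of the decomposition —
#' \eqn{(1,1)}, \eqn{(1,0)}, \eqn{(0,0)} — and each covariate row: the
#' intermediate confounder is drawn under exposure \eqn{x}, an independent
#' confounder draw under \eqn{x'} feeds a mediator draw under \eqn{x'}, and
#' the outcome is evaluated at its fitted conditional mean (Rao–Blackwellized:
#' since every estimand is a mean of a linear/quadratic function, replacing
#' the outcome draw by its conditional mean is unbiased and strictly reduces
#' Monte Carlo variance).  The controlled direct effect fixes the mediator at
#' `cde_m` and draws only the confounder.
#'
#' `n_mc` is the total number of counterfactual draws per leg, allocated
#' uniformly across the observed covariate rows (cycling); each leg uses its
#' own RNG substream derived from `seed`, so legs are independent and results
#' are bit-reproducible.
#'
#' @param fit A `sem_fit`.
#' @param n_mc Total Monte Carlo draws per leg (at least 1000).
#' @param seed RNG seed; required, never defaulted silently.
#' @param assumption Identification assumption (see [mediate_combination()]).
#' @param cde_m Mediator level for the controlled direct effect.
#' @return A `mediation_estimates` tibble with columns `estimand`,
#'   `estimate`, `mc_se` (Monte Carlo integration standard error), `method`,
#'   `assumption`.  Sampling standard errors for this method come from
#'   [bootstrap_mediation()].
#' @examples
#' sim <- simulate_sem(2000, seed = 1)
#' fit <- fit_sem(sim$data, sim$spec)
#' mediate_montecarlo(fit, n_mc = 10000, seed = 99)
#' @export
mediate_montecarlo <- function(fit, n_mc = 100000, seed,
                               assumption = c("auto", "robins_greenland",
                                              "petersen"),
                               cde_m = 0) {
  stopifnot(inherits(fit, "sem_fit"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for Monte Carlo g-computation", call. = FALSE)
  }
  if (n_mc < 1000) stop("n_mc must be at least 1000", call. = FALSE)
  assumption <- resolve_assumption(fit$spec, match.arg(assumption))

  p <- fit$params
  crows <- fit$covariate_rows
  w <- fit$covariate_weights
  gcc <- lin_comb_rows(p$gamma_c, crows)
  acc <- lin_comb_rows(p$alpha_c, crows)
  bcc <- lin_comb_rows(p$beta_c, crows)
  sl <- sqrt(p$sigma2_l)
  sm <- sqrt(p$sigma2_m)

  leg_seeds <- local({
    set.seed(seed)
    sample.int(2^31 - 2, 5)
  })

  # deterministic uniform allocation of draws across covariate rows; the
  # leg mean weights the per-row draw means by the row weights, so weighted
  # covariate grids (exact standardization) are handled without resampling.
  # The reported variance is the integration error only: pooled within-row
  # draw variance, propagated through the weights.
  idx <- rep_len(seq_along(gcc), n_mc)
  n_r <- tabulate(idx, nbins = length(gcc))
  covered <- n_r > 0
  w_use <- w[covered] / sum(w[covered])

  aggregate_leg <- function(vals) {
    sums <- rowsum(vals, idx)[, 1]
    means_r <- sums / n_r[covered]
    leg_mean <- sum(w_use * means_r)
    df_within <- n_mc - sum(covered)
    var_within <- if (df_within >= 1) {
      sum((vals - means_r[idx])^2) / df_within
    } else {
      stats::var(vals)
    }
    c(mean = leg_mean,
      var = sum(w_use^2 / n_r[covered]) * var_within)
  }

  natural_leg <- function(x, xp, leg_seed) {
    set.seed(leg_seed)
    lp <- stats::rnorm(n_mc, mu_L_rows(p, xp, gcc)[idx], sl)
    m <- stats::rnorm(n_mc, p$alpha0 + p$alpha_x * xp +
                        (p$alpha_l + p$alpha_xl * xp) * lp + acc[idx], sm)
    l <- stats::rnorm(n_mc, mu_L_rows(p, x, gcc)[idx], sl)
    vals <- p$beta0 + p$beta_x * x + bcc[idx] +
      (p$beta_l + p$beta_xl * x) * l + p$beta_ll * l^2 +
      (p$beta_m + p$beta_xm * x) * m + p$beta_mm * m^2
    aggregate_leg(vals)
  }
  cde_leg <- function(x, leg_seed) {
    set.seed(leg_seed)
    l <- stats::rnorm(n_mc, mu_L_rows(p, x, gcc)[idx], sl)
    vals <- p$beta0 + p$beta_x * x + bcc[idx] +
      (p$beta_l + p$beta_xl * x) * l + p$beta_ll * l^2 +
      (p$beta_m + p$beta_xm * x) * cde_m + p$beta_mm * cde_m^2
    aggregate_leg(vals)
  }

  y11 <- natural_leg(1, 1, leg_seeds[1])
  y10 <- natural_leg(1, 0, leg_seeds[2])
  y00 <- natural_leg(0, 0, leg_seeds[3])
  c1 <- cde_leg(1, leg_seeds[4])
  c0 <- cde_leg(0, leg_seeds[5])

  est <- c(tce = y11[["mean"]] - y00[["mean"]],
           pnde = y10[["mean"]] - y00[["mean"]],
           tnie = y11[["mean"]] - y10[["mean"]],
           cde = c1[["mean"]] - c0[["mean"]])
  mc_se <- sqrt(c(y11[["var"]] + y00[["var"]],
                  y10[["var"]] + y00[["var"]],
                  y11[["var"]] + y10[["var"]],
                  c1[["var"]] + c0[["var"]]))

  out <- tibble::tibble(
    estimand = names(est), estimate = unname(est), mc_se = mc_se,
    method = "monte_carlo", assumption = assumption
  )
  new_mediation_estimates(out, method = "monte_carlo",
                          assumption = assumption, cde_m_level = cde_m,
                          n = fit$n, n_mc = n_mc, seed = seed,
                          prop_mediated = unname(est["tnie"] / est["tce"]),
                          prop_se = NA_real_, prop_unstable = NA)
}

#' Nonparametric bootstrap for any estimator in the package
#'
#' Resamples rows of the data with replacement, refits everything per
#' replicate, and returns the replicate standard deviation and percentile
#' confidence interval for each statistic the estimator returns.  Replicates
#' that fail (for example through a collinear resample) are recorded and
#' excluded; a warning is issued when more than 1% fail.
#'
#' @param data,spec Data and [sem_spec()] passed to the estimator.
#' @param estimator `"combination"`, `"monte_carlo"`, `"rho_prime"`, or a
#'   function `function(data, spec)` returning a named numeric vector.
#' @param n_boot Number of bootstrap replicates (at least 199).
#' @param seed RNG seed; required.
#' @param conf_level Confidence level of the percentile interval.
#' @param assumption,cde_m Passed to the built-in estimators.
#' @param n_mc Monte Carlo draws per replicate for
#'   `estimator = "monte_carlo"`.
#' @return A tibble with one row per statistic: `statistic`, `estimate`
#'   (full-sample value), `se` (bootstrap SD), `ci_low`, `ci_high`
#'   (percentile), plus attributes `n_boot`, `n_failed`, `seed`.
#' @examples
#' sim <- simulate_sem(400, seed = 3)
#' bootstrap_mediation(sim$data, sim$spec, "combination",
#'                     n_boot = 199, seed = 5)
#' @export
bootstrap_mediation <- function(data, spec, estimator = "combination",
                                n_boot = 1000, seed, conf_level = 0.95,
                                assumption = "auto", cde_m = 0,
                                n_mc = 10000) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for the bootstrap", call. = FALSE)
  }
  if (n_boot < 199) stop("n_boot must be at least 199", call. = FALSE)
  data <- as.data.frame(data)
  n <- nrow(data)

  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, n_boot + 1)
  idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)

  est_fun <- if (is.function(estimator)) {
    function(d, r) estimator(d, spec)
  } else {
    switch(match.arg(estimator, c("combination", "monte_carlo", "rho_prime")),
      combination = function(d, r) {
        e <- mediate_combination(fit_sem(d, spec), assumption = assumption,
                                 cde_m = cde_m)
        stats::setNames(e$estimate, e$estimand)
      },
      monte_carlo = function(d, r) {
        e <- mediate_montecarlo(fit_sem(d, spec), n_mc = n_mc,
                                seed = sub_seeds[r + 1],
                                assumption = assumption, cde_m = cde_m)
        stats::setNames(e$estimate, e$estimand)
      },
      rho_prime = function(d, r) {
        c(rho_prime = rho_prime(d, spec, ci = FALSE)$rho_prime_hat)
      }
    )
  }

  full <- est_fun(data, 0)
  reps <- matrix(NA_real_, n_boot, length(full),
                 dimnames = list(NULL, names(full)))
  n_failed <- 0
  for (r in seq_len(n_boot)) {
    d_r <- data[idx_mat[, r], , drop = FALSE]
    val <- tryCatch(est_fun(d_r, r), error = function(e) NULL)
    if (is.null(val)) n_failed <- n_failed + 1 else reps[r, ] <- val
  }
  if (n_failed / n_boot > 0.01) {
    warning(sprintf("%d of %d bootstrap replicates failed and were excluded",
                    n_failed, n_boot))
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  a <- (1 - conf_level) / 2
  out <- tibble::tibble(
    statistic = names(full),
    estimate = unname(full),
    se = unname(apply(reps, 2, stats::sd)),
    ci_low = unname(apply(reps, 2, stats::quantile, probs = a,
                          names = FALSE)),
    ci_high = unname(apply(reps, 2, stats::quantile, probs = 1 - a,
                           names = FALSE))
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "n_failed") <- n_failed
  attr(out, "seed") <- seed
  attr(out, "conf_level") <- conf_level
  out
}
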