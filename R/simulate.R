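#' Generate synthetic data from the full mediation SEM
#'
#' Draws a study-structured data set from the recursive Gaussian system:
#' binary exposure `x` (marginal prevalence `p_x`, 0.19 by default, mirroring
#' a high-maternal-BMI-type exposure), baseline covariates from `c_config`
#' (two Bernoulli covariates at prevalences 0.55 and 0.13 by default),
#' continuous intermediate confounder `l`, mediator `m` and outcome `y` on
#' standardized scales.  The mediator- and outcome-equation errors may be
#' correlated (`params$rho`, encoding unmeasured mediator-outcome
#' confounding), and an optional unmeasured standard-normal variable `u` can
#' load on both the intermediate confounder and the outcome (`u_config`),
#' inducing unmeasured confounding of the confounder-outcome edge.  `u` and
#' the error realizations are excluded from the visible columns and recorded
#' separately.
#'
#' By default the exposure is drawn independently of the covariates, which
#' keeps the exact truth integrals simple; `x_on_c` enables covariate-
#' dependent exposure through a logistic link (log-odds intercept
#' `qlogis(p_x)` plus the given covariate coefficients).
#'
#' @param n Number of rows.
#' @param params A [sem_params()]; its covariate coefficient vectors must
#'   match `c_config` in length.
#' @param p_x Marginal exposure prevalence in (0, 1).
#' @param c_config Named list of covariate distributions
#'   ([cov_bernoulli()] / [cov_normal()]); names become column names.
#' @param u_config Optional list `list(sd_u =, lambda_l =, lambda_y =)`
#'   activating the unmeasured confounder of the L-Y edge.
#' @param x_on_c Optional numeric vector of logistic covariate coefficients
#'   for covariate-dependent exposure.
#' @param seed RNG seed; required.
#' @return An object of class `sem_sim`: a list with `data` (tibble with
#'   columns `x`, `l`, `m`, `y` and the covariates), `spec` (the
#'   [sem_spec()] matching the generating term set), `truth` (a
#'   `simulation_truth` from [truth_oracle()]; exact estimand values — the
#'   unmeasured `u`, having mean zero and entering linearly, leaves them
#'   unchanged), `errors` (tibble of the error and `u` realizations), and
#'   the generating configuration.
#' @examples
#' sim <- simulate_sem(1000, seed = 1)
#' sim$truth$true_tnie
#' @export
simulate_sem <- function(n, params = sem_params(), p_x = 0.19,
                         c_config = default_c_config(), u_config = NULL,
                         x_on_c = NULL, seed) {
  stopifnot(inherits(params, "sem_params"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required to generate data", call. = FALSE)
  }
  if (!(p_x > 0 && p_x < 1)) stop("p_x must lie in (0, 1)", call. = FALSE)
  check_c_config(c_config)
  nc <- length(c_config)
  if (length(params$gamma_c) != nc) {
    stop("params has ", length(params$gamma_c), " covariate coefficients ",
         "but c_config describes ", nc, " covariates", call. = FALSE)
  }
  if (!is.null(u_config)) {
    if (!all(c("sd_u", "lambda_l", "lambda_y") %in% names(u_config)) ||
        u_config$sd_u <= 0) {
      stop("u_config must be list(sd_u > 0, lambda_l =, lambda_y =)",
           call. = FALSE)
    }
  }
  if (!is.null(x_on_c) && length(x_on_c) != nc) {
    stop("x_on_c must have one coefficient per covariate", call. = FALSE)
  }

  set.seed(seed)
  cc <- sample_covariates(c_config, n)
  x <- if (is.null(x_on_c)) {
    stats::rbinom(n, 1, p_x)
  } else {
    eta <- stats::qlogis(p_x) + lin_comb_rows(x_on_c, cc)
    stats::rbinom(n, 1, stats::plogis(eta))
  }
  u <- if (is.null(u_config)) rep(0, n) else stats::rnorm(n, 0, u_config$sd_u)
  lam_l <- if (is.null(u_config)) 0 else u_config$lambda_l
  lam_y <- if (is.null(u_config)) 0 else u_config$lambda_y

  eps_l <- stats::rnorm(n, 0, sqrt(params$sigma2_l))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  eps_m <- sqrt(params$sigma2_m) * z1
  eps_y <- sqrt(params$sigma2_y) *
    (params$rho * z1 + sqrt(1 - params$rho^2) * z2)

  gcc <- lin_comb_rows(params$gamma_c, cc)
  acc <- lin_comb_rows(params$alpha_c, cc)
  bcc <- lin_comb_rows(params$beta_c, cc)

  l <- params$gamma0 + params$gamma_x * x + gcc + lam_l * u + eps_l
  m <- params$alpha0 + params$alpha_x * x + params$alpha_l * l + acc +
    params$alpha_xl * x * l + eps_m
  y <- params$beta0 + params$beta_x * x + params$beta_m * m +
    params$beta_l * l + bcc + params$beta_mm * m^2 + params$beta_ll * l^2 +
    params$beta_xl * x * l + params$beta_xm * x * m + lam_y * u + eps_y

  c_names <- if (nc) names(c_config) else character()
  tt <- params_term_set(params)
  spec <- sem_spec("x", "m", "y", "l", c = c_names,
                   terms_m = union(tt$terms_m, "c"),
                   terms_y = union(tt$terms_y, "c"))
  data <- tibble::tibble(x = x, l = l, m = m, y = y)
  for (nm in c_names) data[[nm]] <- cc[[nm]]

  structure(
    list(data = data, spec = spec,
         truth = truth_oracle(params, c_config),
         errors = tibble::tibble(eps_l = eps_l, eps_m = eps_m,
                                 eps_y = eps_y, u = u),
         params = params, p_x = p_x, c_config = c_config,
         u_config = u_config, seed = seed),
    class = "sem_sim"
  )
}

#' @export
print.sem_sim <- function(x, ...) {
  cat("<sem_sim>  n =", nrow(x$data), " seed =", x$seed, "\n")
  cat(sprintf("truth: TCE %.4f  PNDE %.4f  TNIE %.4f  CDE(%g) %.4f\n",
              x$truth$true_tce, x$truth$true_pnde, x$truth$true_tnie,
              x$truth$cde_m, x$truth$true_cde))
  invisible(x)
}

#' Exact estimand values by quadrature (the truth oracle)
#'
#' Evaluates the counterfactual integrals defining the total, natural
#' direct/indirect, and controlled direct effects at *known* structural
#' parameters, by nested Gauss–Hermite quadrature over the Gaussian laws of
#' the intermediate confounder and the mediator, and exact expectation over
#' the covariate distribution (Bernoulli covariates enumerated; normal ones
#' Gauss–Hermite-discretized).  Because the outcome equation is polynomial of
#' degree 2 in each integrated variable, the quadrature is exact to floating
#' point at the default order.  This routine is deliberately independent of
#' the closed-form moment algebra in [mediate_combination()] and serves as
#' its oracle.
#'
#' @param params A [sem_params()].
#' @param c_config Covariate distribution list (see [cov_bernoulli()]).
#' @param assumption Optional: check that the parameter set satisfies the
#'   named identification assumption's zero-constraints before evaluating
#'   (`"robins_greenland"`: `beta_xm = 0`; `"petersen"`:
#'   `beta_ll = beta_xl = 0`).
#' @param cde_m Mediator level for the controlled direct effect.
#' @param gh_nodes Gauss–Hermite order per integral.
#' @return An object of class `simulation_truth`: a list with `params`,
#'   `true_tce`, `true_pnde`, `true_tnie`, `true_cde`, `cde_m`,
#'   `assumption`.
#' @export
truth_oracle <- function(params, c_config = default_c_config(),
                         assumption = NULL, cde_m = 0, gh_nodes = 24) {
  stopifnot(inherits(params, "sem_params"))
  if (!is.null(assumption)) {
    bad <- switch(assumption,
      robins_greenland = if (params$beta_xm != 0) "beta_xm",
      petersen = c(if (params$beta_ll != 0) "beta_ll",
                   if (params$beta_xl != 0) "beta_xl"),
      stop("unknown assumption: ", assumption, call. = FALSE))
    if (length(bad)) {
      stop("parameter set violates the '", assumption, "' constraints: ",
           paste(bad, collapse = ", "), " nonzero", call. = FALSE)
    }
  }
  if (length(params$gamma_c) != length(c_config)) {
    stop("c_config must describe one covariate per covariate coefficient",
         call. = FALSE)
  }
  gh <- pracma::gaussHermite(gh_nodes)
  tq <- sqrt(2) * gh$x
  wq <- gh$w / sqrt(pi)
  sl <- sqrt(params$sigma2_l)
  sm <- sqrt(params$sigma2_m)
  grid <- covariate_grid(c_config, gh_nodes = gh_nodes)
  gcc <- lin_comb_rows(params$gamma_c, grid$rows)
  acc <- lin_comb_rows(params$alpha_c, grid$rows)
  bcc <- lin_comb_rows(params$beta_c, grid$rows)
  cw <- grid$weights

  # E over l ~ N(mu, sl^2) of the outcome's l-part, by quadrature
  e_lpart <- function(x, mu_l) {
    vapply(mu_l, function(mu) {
      l_nodes <- mu + sl * tq
      sum(wq * ((params$beta_l + params$beta_xl * x) * l_nodes +
                  params$beta_ll * l_nodes^2))
    }, numeric(1))
  }
  # E over l' and m | l' of the outcome's m-part, by nested quadrature
  e_mpart <- function(x, xp, mu_lp, acc_i) {
    vapply(seq_along(mu_lp), function(i) {
      lp_nodes <- mu_lp[i] + sl * tq
      inner <- vapply(lp_nodes, function(lp) {
        mu_m <- params$alpha0 + params$alpha_x * xp +
          (params$alpha_l + params$alpha_xl * xp) * lp + acc_i[i]
        m_nodes <- mu_m + sm * tq
        sum(wq * ((params$beta_m + params$beta_xm * x) * m_nodes +
                    params$beta_mm * m_nodes^2))
      }, numeric(1))
      sum(wq * inner)
    }, numeric(1))
  }
  leg <- function(x, xp) {
    mu_lx <- params$gamma0 + params$gamma_x * x + gcc
    mu_lxp <- params$gamma0 + params$gamma_x * xp + gcc
    vals <- params$beta0 + params$beta_x * x + bcc +
      e_lpart(x, mu_lx) + e_mpart(x, xp, mu_lxp, acc)
    sum(cw * vals) / sum(cw)
  }
  cde_leg <- function(x) {
    mu_lx <- params$gamma0 + params$gamma_x * x + gcc
    vals <- params$beta0 + params$beta_x * x + bcc + e_lpart(x, mu_lx) +
      (params$beta_m + params$beta_xm * x) * cde_m +
      params$beta_mm * cde_m^2
    sum(cw * vals) / sum(cw)
  }

  y11 <- leg(1, 1)
  y10 <- leg(1, 0)
  y00 <- leg(0, 0)
  structure(
    list(params = params, assumption = assumption, cde_m = cde_m,
         true_tce = y11 - y00, true_pnde = y10 - y00, true_tnie = y11 - y10,
         true_cde = cde_leg(1) - cde_leg(0)),
    class = "simulation_truth"
  )
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "<simulation_truth>  TCE %.6f  PNDE %.6f  TNIE %.6f  CDE(%g) %.6f\n",
    x$true_tce, x$true_pnde, x$true_tnie, x$cde_m, x$true_cde))
  invisible(x)
}

#' @export
tidy.simulation_truth <- function(x, ...) {
  tibble::tibble(estimand = c("tce", "pnde", "tnie", "cde"),
                 truth = c(x$true_tce, x$true_pnde, x$true_tnie, x$true_cde),
                 cde_m = x$cde_m)
}
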