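#' Mediation estimands in closed form ("estimation by combination")
#'
#' Computes the total causal effect (TCE), pure natural direct effect (PNDE),
#' total natural indirect effect (TNIE), and controlled direct effect CDE(m)
#' by analytically integrating the fitted outcome regression over the fitted
#' Gaussian laws of the intermediate confounder and the mediator, then
#' averaging over the empirical covariate distribution (regression
#' standardization).  Standard errors come from the delta method applied to
#' the joint (block-diagonal) least-squares coefficient covariance;
#' confidence intervals are normal-approximation.
#'
#' For a fit with no interactions or quadratics the results reduce exactly to
#' the path-tracing products of coefficients: direct effect
#' \eqn{\beta_x + \gamma_x\beta_l}, indirect \eqn{\beta_m(\alpha_x +
#' \alpha_l\gamma_x)}.  For the general model, natural effects are only
#' identified under a declared parametric assumption: `"robins_greenland"`
#' (no exposure-mediator interaction in the outcome equation) or
#' `"petersen"` (no `xl`/`l2` terms, so the controlled direct effect does not
#' vary with the natural mediator value).  The fitted spec must satisfy the
#' declared assumption's zero-constraints; otherwise an identification error
#' is raised naming the offending terms.
#'
#' @param fit A `sem_fit` from [fit_sem()] (or [sem_fit_from_params()]).
#' @param assumption `"auto"`, `"robins_greenland"`, or `"petersen"`.
#'   `"auto"` resolves from the fitted term set; use [check_identification()]
#'   on the data to choose empirically.
#' @param cde_m Mediator value at which the controlled direct effect is
#'   evaluated (default 0, i.e. the mediator held at its standardized mean).
#' @param conf_level Confidence level for the normal-approximation intervals.
#' @return A tibble of class `mediation_estimates` with columns `estimand`
#'   (`tce`, `pnde`, `tnie`, `cde`), `estimate`, `se`, `ci_low`, `ci_high`,
#'   `method`, `assumption`.  Attributes carry `cde_m_level`,
#'   `prop_mediated` (TNIE/TCE) with its delta SE and an instability flag
#'   (set when the TCE interval covers 0, where the ratio is ill-behaved),
#'   and the sample size.
#' @examples
#' sim <- simulate_sem(2000, seed = 1)
#' fit <- fit_sem(sim$data, sim$spec)
#' mediate_combination(fit, assumption = "robins_greenland")
#' @export
mediate_combination <- function(fit, assumption = c("auto", "robins_greenland",
                                                    "petersen"),
                                cde_m = 0, conf_level = 0.95) {
  stopifnot(inherits(fit, "sem_fit"))
  assumption <- resolve_assumption(fit$spec, match.arg(assumption))
  est <- estimands_from_params(fit$params, fit$covariate_rows,
                               fit$covariate_weights, cde_m)
  J <- estimand_jacobian(fit, cde_m)
  V <- J %*% fit$coef_cov %*% t(J)
  se <- unname(suppressWarnings(sqrt(pmax(diag(V), 0))))
  if (any(!is.finite(diag(V)))) {
    warning("coefficient covariance is singular or non-finite; ",
            "standard errors unavailable")
    se <- rep(NA_real_, 4)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  prop <- unname(est["tnie"] / est["tce"])
  g_prop <- (J["tnie", ] * est["tce"] - est["tnie"] * J["tce", ]) / est["tce"]^2
  prop_se <- sqrt(max(0, drop(g_prop %*% fit$coef_cov %*% g_prop)))
  tce_ci <- est["tce"] + c(-1, 1) * z * se[1]
  prop_unstable <- is.na(se[1]) || (tce_ci[1] <= 0 && tce_ci[2] >= 0)

  out <- tibble::tibble(
    estimand = c("tce", "pnde", "tnie", "cde"),
    estimate = unname(est),
    se = se,
    ci_low = unname(est) - z * se,
    ci_high = unname(est) + z * se,
    method = "combination",
    assumption = assumption
  )
  new_mediation_estimates(out, method = "combination", assumption = assumption,
                          cde_m_level = cde_m, conf_level = conf_level,
                          n = fit$n, prop_mediated = prop, prop_se = prop_se,
                          prop_unstable = prop_unstable)
}

new_mediation_estimates <- function(tbl, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(tbl, nm) <- attrs[[nm]]
  class(tbl) <- c("mediation_estimates", class(tbl))
  tbl
}

#' @export
print.mediation_estimates <- function(x, ...) {
  cat("Mediation estimates (", attr(x, "method"), ", ",
      attr(x, "assumption"), ")\n", sep = "")
  print(tibble::as_tibble(x), ...)
  pm <- attr(x, "prop_mediated")
  if (!is.null(pm)) {
    cat(sprintf("proportion mediated: %.3f (SE %.3f)%s\n", pm,
                attr(x, "prop_se"),
                if (isTRUE(attr(x, "prop_unstable")))
                  "  [unstable: TCE interval covers 0]" else ""))
  }
  cat("CDE evaluated at m =", attr(x, "cde_m_level"), "; n =",
      attr(x, "n"), "\n")
  invisible(x)
}

#' @export
tidy.mediation_estimates <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mediation_estimates <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), assumption = attr(x, "assumption"),
                 cde_m_level = attr(x, "cde_m_level"), n = attr(x, "n"),
                 prop_mediated = attr(x, "prop_mediated"),
                 prop_mediated_se = attr(x, "prop_se"),
                 prop_mediated_unstable = attr(x, "prop_unstable"))
}

# Jacobian of (tce, pnde, tnie, cde) w.r.t. the stacked coefficient vector,
# central finite differences with relative step 1e-6
estimand_jacobian <- function(fit, cde_m) {
  theta <- stack_params(fit$params, fit$spec)
  p <- length(theta)
  J <- matrix(0, 4, p, dimnames = list(c("tce", "pnde", "tnie", "cde"),
                                       names(theta)))
  for (i in seq_len(p)) {
    h <- 1e-6 * max(1, abs(theta[i]))
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    e_up <- estimands_from_params(unstack_params(up, fit$params, fit$spec),
                                  fit$covariate_rows, fit$covariate_weights,
                                  cde_m)
    e_dn <- estimands_from_params(unstack_params(dn, fit$params, fit$spec),
                                  fit$covariate_rows, fit$covariate_weights,
                                  cde_m)
    J[, i] <- (e_up - e_dn) / (2 * h)
  }
  J
}

#' Delta-method standard error of a single mediation estimand
#'
#' @param fit A `sem_fit`.
#' @param estimand One of `"tce"`, `"pnde"`, `"tnie"`, `"cde"`.
#' @param assumption Identification assumption (see [mediate_combination()]).
#' @param cde_m Mediator level for the controlled direct effect.
#' @return The standard error, `sqrt(g' V g)` with `g` the gradient of the
#'   coefficient combination and `V` the joint coefficient covariance.
#' @export
delta_se <- function(fit, estimand = c("tce", "pnde", "tnie", "cde"),
                     assumption = "auto", cde_m = 0) {
  estimand <- match.arg(estimand)
  resolve_assumption(fit$spec, assumption)
  if (any(!is.finite(fit$coef_cov))) {
    warning("coefficient covariance contains non-finite entries; ",
            "SE unavailable")
    return(NA_real_)
  }
  g <- estimand_jacobian(fit, cde_m)[estimand, ]
  v <- drop(g %*% fit$coef_cov %*% g)
  if (!is.finite(v) || v < 0) {
    warning("delta variance is not a valid number; SE unavailable")
    return(NA_real_)
  }
  sqrt(v)
}

#' Path-tracing effect decomposition for the linear path model
#'
#' For a fit with no interactions or quadratics, traces the directed paths of
#' the system: the indirect (mediated) effect is the sum of coefficient
#' products along paths through the mediator, \eqn{\alpha_x\beta_m +
#' \gamma_x\alpha_l\beta_m}; the direct effect is the remainder,
#' \eqn{\beta_x + \gamma_x\beta_l}.  Serves as an independent cross-check of
#' [mediate_combination()], with which it agrees identically on such fits.
#'
#' @param fit A `sem_fit` whose spec has no optional terms.
#' @return A one-row tibble with `direct`, `indirect`, `total`.
#' @export
path_tracing_effects <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!is_model4(fit$spec)) {
    stop("path tracing requires a linear system with no interaction or ",
         "quadratic terms", call. = FALSE)
  }
  p <- fit$params
  tibble::tibble(
    direct = p$beta_x + p$gamma_x * p$beta_l,
    indirect = p$alpha_x * p$beta_m + p$gamma_x * p$alpha_l * p$beta_m,
    total = direct + indirect
  )
}
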