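#' Sensitivity of the indirect effect to unmeasured mediator-outcome
#' confounding
#'
#' Unmeasured common causes of the mediator and the outcome induce a
#' correlation \eqn{\rho} between the mediator- and outcome-equation errors.
#' In the full system that correlation is not identifiable — \eqn{\beta_m}
#' and \eqn{\rho} are collinear, so joint estimation is not offered anywhere
#' in this package.  What is identifiable is \eqn{\rho'}: the correlation
#' between the mediator-equation residual and the residual of the *reduced*
#' outcome equation that omits the mediator (outcome on exposure and
#' intermediate confounder only).  \eqn{\hat\rho'} is the amount of purely
#' spurious residual correlation that would have to exist for the entire
#' estimated indirect effect to be an artefact of unmeasured
#' mediator-outcome confounding: a large \eqn{|\hat\rho'|} means an
#' implausibly strong unmeasured confounder would be needed to nullify it,
#' i.e. the indirect effect is robust.
#'
#' Both working equations assume no interaction terms; a spec containing any
#' is rejected.  Baseline covariates, if present in the spec, are retained in
#' both equations by default (the residual correlation is then conditional on
#' them as well); set `include_covariates = FALSE` to drop them.
#'
#' @param data A data frame.
#' @param spec A [sem_spec()] with no interaction or quadratic terms.
#' @param n_boot Bootstrap replicates for the percentile confidence interval.
#' @param seed RNG seed for the bootstrap; required when `ci = TRUE`.
#' @param ci Compute a bootstrap percentile CI? Set `FALSE` for the point
#'   estimate only (e.g. inside simulation studies).
#' @param conf_level Confidence level of the percentile interval.
#' @param include_covariates Retain the spec's baseline covariates in both
#'   working equations?
#' @return An object of class `sensitivity_result`: a list with
#'   `rho_prime_hat`, `ci` (length-2 numeric or `NULL`), `reduced_fit`
#'   (coefficients and residual variance of the reduced outcome equation),
#'   `n`, `n_boot`, `seed`.
#' @examples
#' sim <- simulate_sem(1000, sem_params(beta_mm = 0, beta_ll = 0,
#'                                      beta_xl = 0, alpha_xl = 0), seed = 4)
#' rho_prime(sim$data, sim$spec, n_boot = 199, seed = 11)
#' @export
rho_prime <- function(data, spec, n_boot = 1000, seed = NULL, ci = TRUE,
                      conf_level = 0.95, include_covariates = TRUE) {
  stopifnot(inherits(spec, "sem_spec"))
  if (!is_model4(spec)) {
    stop("the sensitivity construction assumes a system with no interaction ",
         "or quadratic terms; supply a plain spec", call. = FALSE)
  }
  if (ci && is.null(seed)) {
    stop("a seed is required for the bootstrap confidence interval",
         call. = FALSE)
  }
  if (ci && n_boot < 199) stop("n_boot must be at least 199", call. = FALSE)

  point <- rho_prime_point(data, spec, include_covariates)

  ci_vec <- NULL
  if (ci) {
    boot <- bootstrap_mediation(
      data, spec,
      estimator = function(d, s) {
        c(rho_prime = rho_prime_point(d, s, include_covariates)$r)
      },
      n_boot = n_boot, seed = seed, conf_level = conf_level
    )
    ci_vec <- c(boot$ci_low, boot$ci_high)
  }
  structure(
    list(rho_prime_hat = point$r, ci = ci_vec,
         reduced_fit = point$reduced_fit, n = point$n,
         n_boot = if (ci) n_boot else 0L, seed = seed,
         conf_level = conf_level),
    class = "sensitivity_result"
  )
}

rho_prime_point <- function(data, spec, include_covariates) {
  data <- as.data.frame(data)
  used <- c(spec$x_name, spec$m_name, spec$y_name, spec$l_name,
            if (include_covariates) spec$c_names)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  na_cols <- used[vapply(data[used], anyNA, logical(1))]
  if (length(na_cols)) {
    stop("missing values in column(s): ", paste(na_cols, collapse = ", "),
         "; restrict to complete cases first", call. = FALSE)
  }
  covs <- if (include_covariates) spec$c_names else character()
  rhs <- sprintf("`%s`", c(spec$x_name, spec$l_name, covs))
  fm <- stats::lm(stats::reformulate(rhs, sprintf("`%s`", spec$m_name)),
                  data = data)
  fy <- stats::lm(stats::reformulate(rhs, sprintf("`%s`", spec$y_name)),
                  data = data)
  rm_ <- stats::residuals(fm)
  ry <- stats::residuals(fy)
  if (stats::sd(rm_) == 0 || stats::sd(ry) == 0) {
    stop("degenerate residual variance in a working equation; ",
         "rho-prime is undefined", call. = FALSE)
  }
  cf <- stats::coef(fy)
  list(
    r = stats::cor(rm_, ry),
    n = nrow(data),
    reduced_fit = list(
      coefficients = stats::setNames(unname(cf),
                                     gsub("^`|`$", "", names(cf))),
      sigma2_y_reduced = sum(ry^2) / stats::df.residual(fy)
    )
  )
}

#' Analytic large-sample value of the residual-correlation sensitivity
#' parameter
#'
#' In the linear system with mediator effect \eqn{\beta_m}, error scales
#' \eqn{\sigma_m, \sigma_y} and true error correlation \eqn{\rho}, the
#' reduced outcome equation's error is \eqn{\epsilon'_y = \beta_m \epsilon_m
#' + \epsilon_y}, so the population value of \eqn{\rho'} is
#' \deqn{\rho' = \frac{\beta_m\sigma_m + \rho\sigma_y}
#'   {\sqrt{\beta_m^2\sigma_m^2 + 2\beta_m\rho\sigma_m\sigma_y +
#'    \sigma_y^2}}.}
#' Useful for calibrating and testing the estimator: with no true confounding
#' (\eqn{\rho = 0}) this reduces to
#' \eqn{\beta_m\sigma_m/\sqrt{\beta_m^2\sigma_m^2 + \sigma_y^2}}.
#'
#' @param beta_m Mediator coefficient in the outcome equation.
#' @param sigma_m,sigma_y Error standard deviations of the mediator and
#'   outcome equations.
#' @param rho True correlation of the two errors.
#' @return The population residual correlation, in (-1, 1).
#' @export
rho_prime_limit <- function(beta_m, sigma_m = 1, sigma_y = 1, rho = 0) {
  num <- beta_m * sigma_m + rho * sigma_y
  den <- sqrt(beta_m^2 * sigma_m^2 + 2 * beta_m * rho * sigma_m * sigma_y +
                sigma_y^2)
  num / den
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("rho-prime: %.3f", x$rho_prime_hat))
  if (!is.null(x$ci)) {
    cat(sprintf("  (%d%% bootstrap CI %.3f, %.3f; B = %d)",
                round(100 * x$conf_level), x$ci[1], x$ci[2], x$n_boot))
  }
  cat("\n")
  cat("Interpretation: a spurious mediator-outcome residual correlation of ",
      "at least\n", sprintf("|%.3f|", x$rho_prime_hat),
      " would be needed for the estimated indirect effect to be entirely\n",
      "an artefact of unmeasured mediator-outcome confounding; the larger ",
      "this value,\nthe more robust the indirect effect.\n", sep = "")
  invisible(x)
}

#' @export
tidy.sensitivity_result <- function(x, ...) {
  tibble::tibble(
    rho_prime = x$rho_prime_hat,
    ci_low = if (is.null(x$ci)) NA_real_ else x$ci[1],
    ci_high = if (is.null(x$ci)) NA_real_ else x$ci[2],
    n = x$n, n_boot = x$n_boot
  )
}
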