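#' Structural parameters of the mediation SEM
#'
#' A container for every coefficient and error parameter of the three-equation
#' system (confounder, mediator, and outcome equations), used both as the
#' output of [fit_sem()] and as the input of the synthetic-data generator
#' [simulate_sem()] and the quadrature truth oracle [truth_oracle()].
#' Coefficients of terms absent from a model specification are identically 0.
#'
#' The defaults describe a study-scale system on standardized scales with a
#' modest exposure effect on the intermediate confounder, a strong
#' exposure-mediator path, mild curvature in both the mediator and the
#' confounder, an exposure-confounder interaction in both downstream
#' equations, and no exposure-mediator interaction (so the Robins–Greenland
#' identification assumption holds in truth).
#'
#' @param gamma0,gamma_x Intercept and exposure coefficient of the L equation.
#' @param gamma_c Numeric vector of covariate coefficients in the L equation.
#' @param alpha0,alpha_x,alpha_l,alpha_xl M-equation coefficients (intercept,
#'   exposure, confounder, exposure-by-confounder interaction).
#' @param alpha_c Covariate coefficients in the M equation.
#' @param beta0,beta_x,beta_m,beta_l,beta_mm,beta_ll,beta_xl,beta_xm
#'   Y-equation coefficients (intercept, exposure, mediator, confounder,
#'   mediator squared, confounder squared, exposure-by-confounder,
#'   exposure-by-mediator).
#' @param beta_c Covariate coefficients in the Y equation.
#' @param sigma2_l,sigma2_m,sigma2_y Residual variances (strictly positive
#'   except in deliberately degenerate noise-free systems, where 0 is
#'   allowed).
#' @param rho Correlation of the mediator and outcome errors; nonzero values
#'   encode unmeasured mediator-outcome confounding and are only honoured by
#'   the generator (estimation always assumes 0).
#' @return An object of class `sem_params` (a named list).
#' @examples
#' sem_params()                       # the default study-like system
#' sem_params(beta_mm = 0, beta_ll = 0, beta_xl = 0, alpha_xl = 0)  # no
#' # curvature or interactions: the classical linear path model
#' @export
sem_params <- function(gamma0 = 0.1, gamma_x = 0.13,
                       gamma_c = c(-0.04, -0.04),
                       alpha0 = 0, alpha_x = 0.55, alpha_l = 0.05,
                       alpha_c = c(0.10, -0.02), alpha_xl = 0.1,
                       beta0 = 0, beta_x = 0.07, beta_m = 0.31,
                       beta_l = 0.03, beta_c = c(-0.011, 0.207),
                       beta_mm = 0.04, beta_ll = 0.03,
                       beta_xl = 0.08, beta_xm = 0,
                       sigma2_l = 1, sigma2_m = 1, sigma2_y = 1,
                       rho = 0) {
  if (length(gamma_c) != length(alpha_c) || length(gamma_c) != length(beta_c)) {
    stop("gamma_c, alpha_c and beta_c must have a common length ",
         "(one entry per baseline covariate)", call. = FALSE)
  }
  if (any(c(sigma2_l, sigma2_m, sigma2_y) < 0)) {
    stop("residual variances must be non-negative", call. = FALSE)
  }
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  structure(
    list(gamma0 = gamma0, gamma_x = gamma_x, gamma_c = gamma_c,
         alpha0 = alpha0, alpha_x = alpha_x, alpha_l = alpha_l,
         alpha_c = alpha_c, alpha_xl = alpha_xl,
         beta0 = beta0, beta_x = beta_x, beta_m = beta_m, beta_l = beta_l,
         beta_c = beta_c, beta_mm = beta_mm, beta_ll = beta_ll,
         beta_xl = beta_xl, beta_xm = beta_xm,
         sigma2_l = sigma2_l, sigma2_m = sigma2_m, sigma2_y = sigma2_y,
         rho = rho),
    class = "sem_params"
  )
}

#' @export
print.sem_params <- function(x, ...) {
  cat("<sem_params>\n")
  cat(sprintf("  L: g0=%g gx=%g gc=(%s)  s2l=%g\n", x$gamma0, x$gamma_x,
              paste(x$gamma_c, collapse = ", "), x$sigma2_l))
  cat(sprintf("  M: a0=%g ax=%g al=%g axl=%g ac=(%s)  s2m=%g\n", x$alpha0,
              x$alpha_x, x$alpha_l, x$alpha_xl,
              paste(x$alpha_c, collapse = ", "), x$sigma2_m))
  cat(sprintf(
    "  Y: b0=%g bx=%g bm=%g bl=%g bmm=%g bll=%g bxl=%g bxm=%g bc=(%s)  s2y=%g\n",
    x$beta0, x$beta_x, x$beta_m, x$beta_l, x$beta_mm, x$beta_ll, x$beta_xl,
    x$beta_xm, paste(x$beta_c, collapse = ", "), x$sigma2_y))
  if (x$rho != 0) cat(sprintf("  corr(eps_m, eps_y) = %g\n", x$rho))
  invisible(x)
}

# which spec terms a parameter set actually uses (nonzero optional terms)
params_term_set <- function(params) {
  terms_m <- c("x", "l", if (params$alpha_xl != 0) "xl")
  terms_y <- c("x", "m", "l",
               if (params$beta_mm != 0) "m2",
               if (params$beta_ll != 0) "l2",
               if (params$beta_xl != 0) "xl",
               if (params$beta_xm != 0) "xm")
  list(terms_m = terms_m, terms_y = terms_y)
}
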