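#' Diagnose which parametric identification assumption is tenable
#'
#' With an intermediate confounder present, natural direct and indirect
#' effects are identified only under one of two parametric restrictions on
#' the outcome model: the Robins–Greenland assumption (no individual-level
#' exposure–mediator interaction, i.e. \eqn{\beta_{xm} = 0}) or the Petersen
#' assumption (the controlled direct effect does not vary with the natural
#' mediator value, which for this system requires \eqn{\beta_{ll} =
#' \beta_{xl} = 0}).  This function fits the unconstrained associational
#' outcome model containing all of `m2`, `l2`, `xl`, `xm` and reports the
#' evidence against each restriction: a single-coefficient Wald test for
#' `xm`, and a 2-df joint Wald test for (`xl`, `l2`) (per-term p-values are
#' also reported).
#'
#' The recommendation is a pure function of the two p-values and `alpha`:
#' rejecting `xm = 0` excludes Robins–Greenland; rejecting the joint null
#' excludes Petersen; when neither is rejected both assumptions are
#' admissible (report estimates under both); when both are rejected the
#' natural effects are not identified under either option.  No
#' multiple-testing correction is applied across the two hypotheses: they
#' select between model parameterizations rather than test discoveries.
#'
#' @param data A data frame.
#' @param spec A [sem_spec()]; its outcome equation is upgraded internally to
#'   the full term set.
#' @param alpha Significance level for the exclusion rule (default 0.05).
#' @return An object of class `identification_report`: a list with
#'   `coefficients` (tibble of estimate/SE/statistic/p per outcome-equation
#'   term), `p_beta_xm`, `p_joint_xl_ll`, per-term `p_beta_xl`, `p_beta_ll`,
#'   `alpha`, and `recommendation` (one of `"robins_greenland"`,
#'   `"petersen"`, `"both_admissible"`, `"neither_admissible"`).
#' @examples
#' sim <- simulate_sem(2000, seed = 2)
#' check_identification(sim$data, sim$spec)
#' @export
check_identification <- function(data, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "sem_spec"), alpha > 0, alpha < 1)
  full_spec <- sem_spec(spec$x_name, spec$m_name, spec$y_name, spec$l_name,
                        c = spec$c_names, terms_m = spec$terms_m,
                        terms_y = c("x", "m", "l", "c", "m2", "l2", "xl",
                                    "xm"))
  fit <- fit_sem(data, full_spec)
  sm <- summary(fit$fits$y)$coefficients
  rn <- gsub("^`|`$", "", rownames(sm))
  coef_tbl <- tibble::tibble(
    term = gsub("^\\.", "", rn),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
  p_of <- function(term) coef_tbl$p.value[coef_tbl$term == term]

  # 2-df joint Wald test for (xl, l2)
  v <- stats::vcov(fit$fits$y)
  rownames(v) <- colnames(v) <- rn
  b <- stats::coef(fit$fits$y)
  names(b) <- rn
  joint_terms <- c(".xl", ".l2")
  W <- drop(t(b[joint_terms]) %*% solve(v[joint_terms, joint_terms]) %*%
              b[joint_terms])
  p_joint <- stats::pchisq(W, df = 2, lower.tail = FALSE)

  rec <- identification_recommendation(p_of("xm"), p_joint, alpha)
  structure(
    list(coefficients = coef_tbl,
         p_beta_xm = p_of("xm"), p_joint_xl_ll = p_joint,
         p_beta_xl = p_of("xl"), p_beta_ll = p_of("l2"),
         wald_joint = W, alpha = alpha, recommendation = rec,
         n = fit$n, fit = fit),
    class = "identification_report"
  )
}

#' @rdname check_identification
#' @param p_beta_xm,p_joint_xl_ll The two Wald p-values.
#' @export
identification_recommendation <- function(p_beta_xm, p_joint_xl_ll, alpha = 0.05) {
  rg_ok <- p_beta_xm >= alpha
  pt_ok <- p_joint_xl_ll >= alpha
  if (rg_ok && pt_ok) "both_admissible"
  else if (rg_ok) "robins_greenland"
  else if (pt_ok) "petersen"
  else "neither_admissible"
}

#' @export
print.identification_report <- function(x, ...) {
  cat("Identification diagnostics (unconstrained outcome model, n =", x$n,
      ")\n")
  print(x$coefficients, ...)
  cat(sprintf("\nWald p for xm = 0:            %.4g\n", x$p_beta_xm))
  cat(sprintf("joint Wald p for xl = l2 = 0: %.4g (per-term: xl %.4g, l2 %.4g)\n",
              x$p_joint_xl_ll, x$p_beta_xl, x$p_beta_ll))
  cat("recommendation (alpha =", x$alpha, "):", x$recommendation, "\n")
  if (x$recommendation == "neither_admissible") {
    cat("warning: natural effects are not identified under either ",
        "parametric assumption for this model\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.identification_report <- function(x, ...) x$coefficients

#' @export
glance.identification_report <- function(x, ...) {
  tibble::tibble(p_beta_xm = x$p_beta_xm, p_joint_xl_ll = x$p_joint_xl_ll,
                 p_beta_xl = x$p_beta_xl, p_beta_ll = x$p_beta_ll,
                 alpha = x$alpha, recommendation = x$recommendation, n = x$n)
}
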