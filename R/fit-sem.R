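#' Fit the mediation SEM by equation-wise least squares
#'
#' Fits the recursive three-equation system declared by a [sem_spec()] to a
#' rectangular data set: the intermediate confounder on the exposure (and
#' covariates), the mediator on exposure and confounder, and the outcome on
#' exposure, mediator and confounder, each by ordinary least squares.  For a
#' recursive system with mutually uncorrelated errors, equation-wise OLS is
#' consistent and asymptotically equivalent to full-information maximum
#' likelihood, and keeps the joint coefficient covariance block-diagonal
#' (cross-equation covariances are exactly 0 under the independent-error
#' assumption; the nonparametric bootstrap is available when that assumption
#' is in doubt).
#'
#' The fitter refuses tables containing missing values in any used column
#' rather than silently dropping rows, so the analysis sample size is always
#' explicit; filter to complete cases first.
#'
#' @param data A data frame containing all columns named by `spec`.
#' @param spec A [sem_spec()].
#' @return An object of class `sem_fit` with components `spec`, `params`
#'   (a [sem_params()] of point estimates, `rho` fixed at 0), `coef_cov`
#'   (joint block-diagonal covariance of all estimated coefficients), `n`,
#'   `residuals` (named list of per-equation residual vectors),
#'   `covariate_rows` (observed covariate table with empirical weights, kept
#'   for regression standardization), and the underlying `lm` fits.
#' @examples
#' sim <- simulate_sem(500, seed = 1)
#' fit <- fit_sem(sim$data, sim$spec)
#' tidy(fit)
#' @export
fit_sem <- function(data, spec) {
  stopifnot(inherits(spec, "sem_spec"))
  data <- as.data.frame(data)
  used <- c(spec$x_name, spec$m_name, spec$y_name, spec$l_name, spec$c_names)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (nm in used) {
    if (!is.numeric(data[[nm]])) {
      stop("column '", nm, "' must be numeric", call. = FALSE)
    }
  }
  na_cols <- used[vapply(data[used], anyNA, logical(1))]
  if (length(na_cols)) {
    stop("missing values in column(s): ", paste(na_cols, collapse = ", "),
         "; restrict to complete cases before fitting (e.g. tidyr::drop_na())",
         call. = FALSE)
  }
  xv <- data[[spec$x_name]]
  if (!all(xv %in% c(0, 1))) {
    stop("exposure column '", spec$x_name,
         "' must be coded 0/1 (contrast is 1 vs 0)", call. = FALSE)
  }

  d <- design_frame(data, spec)
  n <- nrow(d)

  fits <- list(
    l = fit_equation(d, ".l", eq_design_terms(spec, "l"), spec),
    m = fit_equation(d, ".m", eq_design_terms(spec, "m"), spec),
    y = fit_equation(d, ".y", eq_design_terms(spec, "y"), spec)
  )

  params <- params_from_fits(fits, spec)
  vcovs <- lapply(fits, stats::vcov)
  p_tot <- sum(vapply(vcovs, nrow, integer(1)))
  coef_cov <- matrix(0, p_tot, p_tot)
  labels <- character(p_tot)
  at <- 0
  for (eq in c("l", "m", "y")) {
    v <- vcovs[[eq]]
    idx <- at + seq_len(nrow(v))
    coef_cov[idx, idx] <- v
    labels[idx] <- paste0(eq, ":", rownames(v))
    at <- at + nrow(v)
  }
  dimnames(coef_cov) <- list(labels, labels)

  covariate_rows <- tibble::as_tibble(data[spec$c_names])
  structure(
    list(spec = spec, params = params, coef_cov = coef_cov, n = n,
         residuals = lapply(fits, stats::residuals),
         covariate_rows = covariate_rows,
         covariate_weights = rep(1 / n, n),
         fits = fits),
    class = "sem_fit"
  )
}

# canonical internal design columns: .x .m .y .l .xl .m2 .l2 .xm plus the
# user-named covariates (checked against collisions with the dot names)
design_frame <- function(data, spec) {
  reserved <- c(".x", ".m", ".y", ".l", ".xl", ".m2", ".l2", ".xm")
  clash <- intersect(spec$c_names, reserved)
  if (length(clash)) {
    stop("covariate name(s) collide with internal design columns: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(.x = data[[spec$x_name]], .m = data[[spec$m_name]],
                  .y = data[[spec$y_name]], .l = data[[spec$l_name]],
                  check.names = FALSE)
  for (nm in spec$c_names) d[[nm]] <- data[[nm]]
  d$.xl <- d$.x * d$.l
  d$.m2 <- d$.m^2
  d$.l2 <- d$.l^2
  d$.xm <- d$.x * d$.m
  d
}

# ordered design columns for one equation (excluding the intercept)
eq_design_terms <- function(spec, eq) {
  covs <- spec$c_names
  if (eq == "l") return(c(".x", covs))
  if (eq == "m") {
    tt <- spec$terms_m
    return(c(".x", ".l", covs, if ("xl" %in% tt) ".xl"))
  }
  tt <- spec$terms_y
  c(".x", ".m", ".l", covs,
    if ("m2" %in% tt) ".m2", if ("l2" %in% tt) ".l2",
    if ("xl" %in% tt) ".xl", if ("xm" %in% tt) ".xm")
}

fit_equation <- function(d, response, rhs, spec) {
  if (nrow(d) <= length(rhs) + 1) {
    stop("n must exceed the number of coefficients in each equation",
         call. = FALSE)
  }
  f <- stats::reformulate(sprintf("`%s`", rhs), response = sprintf("`%s`", response))
  fit <- stats::lm(f, data = d)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- gsub("`", "", names(cf)[is.na(cf)])
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit
}

params_from_fits <- function(fits, spec) {
  nc <- length(spec$c_names)
  grab <- function(fit, term) {
    cf <- stats::coef(fit)
    names(cf) <- gsub("^`|`$", "", names(cf))
    if (term %in% names(cf)) unname(cf[[term]]) else 0
  }
  grab_c <- function(fit) {
    if (nc == 0) return(numeric(0))
    vapply(spec$c_names, function(cn) grab(fit, cn), numeric(1), USE.NAMES = FALSE)
  }
  s2 <- function(fit) {
    r <- stats::residuals(fit)
    sum(r^2) / stats::df.residual(fit)
  }
  sem_params(
    gamma0 = grab(fits$l, "(Intercept)"), gamma_x = grab(fits$l, ".x"),
    gamma_c = grab_c(fits$l),
    alpha0 = grab(fits$m, "(Intercept)"), alpha_x = grab(fits$m, ".x"),
    alpha_l = grab(fits$m, ".l"), alpha_c = grab_c(fits$m),
    alpha_xl = grab(fits$m, ".xl"),
    beta0 = grab(fits$y, "(Intercept)"), beta_x = grab(fits$y, ".x"),
    beta_m = grab(fits$y, ".m"), beta_l = grab(fits$y, ".l"),
    beta_c = grab_c(fits$y),
    beta_mm = grab(fits$y, ".m2"), beta_ll = grab(fits$y, ".l2"),
    beta_xl = grab(fits$y, ".xl"), beta_xm = grab(fits$y, ".xm"),
    sigma2_l = s2(fits$l), sigma2_m = s2(fits$m), sigma2_y = s2(fits$y),
    rho = 0
  )
}

#' Build a `sem_fit` directly from known structural parameters
#'
#' Wraps a [sem_params()] in the same container [fit_sem()] returns, so the
#' estimand machinery (closed-form combination, Monte Carlo g-computation,
#' delta-method standard errors) can be evaluated at arbitrary — for example,
#' true generating — parameter values.  The coefficient covariance defaults
#' to an all-zero matrix; covariates can be supplied either as observed rows
#' or as a distributional `c_config` (see [covariate_config()]), in which case
#' the exact covariate distribution (enumerated for Bernoulli covariates,
#' Gauss–Hermite-discretized for normal ones) is used for standardization.
#'
#' @param params A [sem_params()].
#' @param spec A [sem_spec()]; defaults to a spec whose optional terms are the
#'   nonzero ones in `params`, with covariate names `c1, c2, ...`.
#' @param covariate_rows Optional data frame of covariate values to
#'   standardize over (equal weights).
#' @param c_config Optional covariate distribution list; used when
#'   `covariate_rows` is absent.
#' @param coef_cov Optional joint coefficient covariance matrix (defaults to
#'   zero, i.e. parameters treated as known).
#' @return A `sem_fit`.
#' @export
sem_fit_from_params <- function(params, spec = NULL, covariate_rows = NULL,
                                c_config = NULL, coef_cov = NULL) {
  stopifnot(inherits(params, "sem_params"))
  nc <- length(params$gamma_c)
  if (is.null(spec)) {
    tt <- params_term_set(params)
    spec <- sem_spec("x", "m", "y", "l",
                     c = if (nc) paste0("c", seq_len(nc)) else character(),
                     terms_m = union(tt$terms_m, "c"),
                     terms_y = union(tt$terms_y, "c"))
  }
  if (length(spec$c_names) != nc) {
    stop("spec names ", length(spec$c_names), " covariates but params has ",
         nc, " covariate coefficients", call. = FALSE)
  }
  if (!is.null(covariate_rows)) {
    cw <- rep(1 / nrow(as.data.frame(covariate_rows)),
              nrow(as.data.frame(covariate_rows)))
    crows <- tibble::as_tibble(as.data.frame(covariate_rows)[spec$c_names])
  } else if (!is.null(c_config)) {
    grid <- covariate_grid(c_config, names = spec$c_names)
    crows <- grid$rows
    cw <- grid$weights
  } else {
    if (nc > 0) {
      stop("supply covariate_rows or c_config for a parameter set with ",
           "covariate coefficients", call. = FALSE)
    }
    crows <- tibble::new_tibble(list(), nrow = 1)
    cw <- 1
  }
  p <- length(stack_params(params, spec))
  if (is.null(coef_cov)) coef_cov <- matrix(0, p, p)
  structure(
    list(spec = spec, params = params, coef_cov = coef_cov,
         n = length(cw), residuals = NULL,
         covariate_rows = crows, covariate_weights = cw, fits = NULL),
    class = "sem_fit"
  )
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("<sem_fit>  n =", x$n, "\n")
  print(x$params)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a fitted mediation SEM
#'
#' @param x A `sem_fit` from [fit_sem()].
#' @param ... Unused.
#' @return A tibble with one row per estimated coefficient: `equation`
#'   (`"l"`, `"m"` or `"y"`), `term` (design-column name, with the internal
#'   dot prefix stripped), `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.sem_fit <- function(x, ...) {
  if (is.null(x$fits)) {
    stop("this sem_fit was built from parameters, not data; nothing to tidy",
         call. = FALSE)
  }
  purrr::map_dfr(c("l", "m", "y"), function(eq) {
    sm <- summary(x$fits[[eq]])$coefficients
    tibble::tibble(
      equation = eq,
      term = gsub("^`|`$", "", gsub("^\\.", "", rownames(sm))),
      estimate = sm[, 1], std.error = sm[, 2],
      statistic = sm[, 3], p.value = sm[, 4]
    )
  })
}

#' @rdname tidy.sem_fit
#' @return For `glance()`: a one-row tibble with the sample size and the
#'   per-equation residual standard deviations and R-squared values.
#' @export
glance.sem_fit <- function(x, ...) {
  r2 <- function(eq) {
    if (is.null(x$fits)) return(NA_real_)
    summary(x$fits[[eq]])$r.squared
  }
  tibble::tibble(
    n = x$n,
    sigma_l = sqrt(x$params$sigma2_l), sigma_m = sqrt(x$params$sigma2_m),
    sigma_y = sqrt(x$params$sigma2_y),
    r.squared_l = r2("l"), r.squared_m = r2("m"), r.squared_y = r2("y")
  )
}

# --- stacked-coefficient utilities (delta method) -------------------------

# field mapping for one equation, in the order the design columns appear
eq_field_map <- function(spec, eq) {
  covs <- spec$c_names
  base <- switch(eq,
    l = c("(Intercept)" = "gamma0", ".x" = "gamma_x"),
    m = c("(Intercept)" = "alpha0", ".x" = "alpha_x", ".l" = "alpha_l"),
    y = c("(Intercept)" = "beta0", ".x" = "beta_x", ".m" = "beta_m",
          ".l" = "beta_l"))
  cmap <- if (length(covs)) {
    stats::setNames(paste0(switch(eq, l = "gamma_c", m = "alpha_c",
                                  y = "beta_c"), "[", seq_along(covs), "]"),
                    covs)
  } else character(0)
  extra <- switch(eq,
    l = character(0),
    m = if ("xl" %in% spec$terms_m) c(".xl" = "alpha_xl") else character(0),
    y = c(if ("m2" %in% spec$terms_y) c(".m2" = "beta_mm"),
          if ("l2" %in% spec$terms_y) c(".l2" = "beta_ll"),
          if ("xl" %in% spec$terms_y) c(".xl" = "beta_xl"),
          if ("xm" %in% spec$terms_y) c(".xm" = "beta_xm")))
  c(base, cmap, extra)
}

# stack the estimated coefficients in coef_cov order
stack_params <- function(params, spec) {
  out <- c()
  for (eq in c("l", "m", "y")) {
    fm <- eq_field_map(spec, eq)
    vals <- vapply(fm, function(f) {
      if (grepl("\\[", f)) {
        fld <- sub("\\[.*", "", f)
        j <- as.integer(sub(".*\\[(\\d+)\\]", "\\1", f))
        params[[fld]][j]
      } else params[[f]]
    }, numeric(1))
    names(vals) <- paste0(eq, ":", names(fm))
    out <- c(out, vals)
  }
  out
}

# rebuild a sem_params from a stacked coefficient vector (variances kept)
unstack_params <- function(theta, params, spec) {
  at <- 0
  for (eq in c("l", "m", "y")) {
    fm <- eq_field_map(spec, eq)
    for (f in fm) {
      at <- at + 1
      if (grepl("\\[", f)) {
        fld <- sub("\\[.*", "", f)
        j <- as.integer(sub(".*\\[(\\d+)\\]", "\\1", f))
        params[[fld]][j] <- theta[at]
      } else {
        params[[f]] <- theta[at]
      }
    }
  }
  params
}
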