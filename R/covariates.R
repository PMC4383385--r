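#' Describe baseline-covariate distributions
#'
#' Small constructors used by the synthetic-data generator and the exact
#' truth oracle to describe each baseline covariate's marginal distribution.
#' `cov_bernoulli(p)` is a 0/1 covariate with success probability `p`;
#' `cov_normal(mean, sd)` a Gaussian one.  A covariate configuration is a
#' named list of these, e.g. `list(c1 = cov_bernoulli(0.55), c2 =
#' cov_bernoulli(0.13))` (the default: two binary covariates at study-like
#' prevalences).
#'
#' @param p Success probability in (0, 1).
#' @param mean,sd Mean and standard deviation (`sd > 0`).
#' @return A list describing the distribution.
#' @export
cov_bernoulli <- function(p) {
  if (!(is.numeric(p) && length(p) == 1 && p > 0 && p < 1)) {
    stop("bernoulli probability must lie in (0, 1)", call. = FALSE)
  }
  list(dist = "bernoulli", p = p)
}

#' @rdname cov_bernoulli
#' @export
cov_normal <- function(mean = 0, sd = 1) {
  if (!(is.numeric(sd) && length(sd) == 1 && sd > 0)) {
    stop("normal sd must be positive", call. = FALSE)
  }
  list(dist = "normal", mean = mean, sd = sd)
}

#' @rdname cov_bernoulli
#' @export
default_c_config <- function() {
  list(c1 = cov_bernoulli(0.55), c2 = cov_bernoulli(0.13))
}

check_c_config <- function(c_config) {
  if (is.null(c_config)) return(invisible(NULL))
  ok <- vapply(c_config, function(cc) {
    is.list(cc) && cc$dist %in% c("bernoulli", "normal")
  }, logical(1))
  if (!all(ok)) stop("c_config entries must be cov_bernoulli()/cov_normal()",
                     call. = FALSE)
  invisible(NULL)
}

# exact (or Gauss-Hermite-exact) weighted grid over the covariate
# distribution: Bernoulli covariates are enumerated, normal ones discretized
# at gh_nodes Hermite nodes (exact for the polynomial estimand expressions)
covariate_grid <- function(c_config, names = NULL, gh_nodes = 16) {
  check_c_config(c_config)
  if (is.null(names)) names <- names(c_config)
  if (length(c_config) == 0) {
    return(list(rows = tibble::new_tibble(list(), nrow = 1), weights = 1))
  }
  supports <- lapply(c_config, function(cc) {
    if (cc$dist == "bernoulli") {
      list(x = c(0, 1), w = c(1 - cc$p, cc$p))
    } else {
      gh <- pracma::gaussHermite(gh_nodes)
      list(x = cc$mean + sqrt(2) * cc$sd * gh$x, w = gh$w / sqrt(pi))
    }
  })
  vals <- expand.grid(lapply(supports, `[[`, "x"), KEEP.OUT.ATTRS = FALSE)
  ws <- expand.grid(lapply(supports, `[[`, "w"), KEEP.OUT.ATTRS = FALSE)
  names(vals) <- names
  list(rows = tibble::as_tibble(vals),
       weights = Reduce(`*`, ws, rep(1, nrow(ws))))
}

sample_covariates <- function(c_config, n) {
  check_c_config(c_config)
  if (length(c_config) == 0) return(tibble::new_tibble(list(), nrow = n))
  cols <- lapply(c_config, function(cc) {
    if (cc$dist == "bernoulli") stats::rbinom(n, 1, cc$p)
    else stats::rnorm(n, cc$mean, cc$sd)
  })
  tibble::as_tibble(cols)
}
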