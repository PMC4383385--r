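# shared fixtures: parameter sets and specs used across test files

# plain linear path model (no interactions, no quadratics)
params_linear <- function(...) {
  sem_params(alpha_xl = 0, beta_mm = 0, beta_ll = 0, beta_xl = 0,
             beta_xm = 0, ...)
}

spec_linear <- function(covs = c("c1", "c2")) {
  sem_spec("x", "m", "y", "l", c = covs)
}

# full general model with the Robins-Greenland constraint (beta_xm = 0)
spec_general_rg <- function(covs = c("c1", "c2")) {
  sem_spec("x", "m", "y", "l", c = covs,
           terms_m = c("x", "l", "c", "xl"),
           terms_y = c("x", "m", "l", "c", "m2", "l2", "xl"))
}

# Petersen-constrained model (no xl/l2 in the outcome equation, xm allowed)
spec_general_pt <- function(covs = c("c1", "c2")) {
  sem_spec("x", "m", "y", "l", c = covs,
           terms_m = c("x", "l", "c", "xl"),
           terms_y = c("x", "m", "l", "c", "m2", "xm"))
}

params_petersen <- function(beta_xm = 0.09, ...) {
  sem_params(beta_ll = 0, beta_xl = 0, beta_xm = beta_xm, ...)
}

truth_vec <- function(truth) {
  c(tce = truth$true_tce, pnde = truth$true_pnde, tnie = truth$true_tnie,
    cde = truth$true_cde)
}

no_cov_config <- function() list()

params_no_cov <- function(...) {
  sem_params(gamma_c = numeric(0), alpha_c = numeric(0), beta_c = numeric(0),
             ...)
}
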