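test_that("linear-model closed forms match hand arithmetic and path tracing", {
  p <- params_no_cov(gamma_x = 0.5, alpha_x = 0.3, alpha_l = 0.2,
                     beta_x = 0.2, beta_l = 0.4, beta_m = 0.5,
                     alpha_xl = 0, beta_mm = 0, beta_ll = 0, beta_xl = 0,
                     beta_xm = 0)
  fit <- sem_fit_from_params(p, c_config = no_cov_config())
  est <- mediate_combination(fit)
  got <- setNames(est$estimate, est$estimand)
  expect_equal(got[["pnde"]], 0.40, tolerance = 1e-12)
  expect_equal(got[["tnie"]], 0.20, tolerance = 1e-12)
  expect_equal(got[["tce"]], 0.60, tolerance = 1e-12)
  expect_equal(got[["cde"]], got[["pnde"]], tolerance = 1e-12)

  pt <- path_tracing_effects(fit)
  expect_equal(pt$direct, got[["pnde"]], tolerance = 1e-12)
  expect_equal(pt$indirect, got[["tnie"]], tolerance = 1e-12)
})

test_that("a null mediator coefficient severs the indirect path", {
  p <- params_linear(beta_m = 0)
  fit <- sem_fit_from_params(p, c_config = default_c_config())
  est <- mediate_combination(fit)
  got <- setNames(est$estimate, est$estimand)
  expect_equal(got[["tnie"]], 0, tolerance = 1e-12)
  expect_equal(got[["pnde"]], got[["tce"]], tolerance = 1e-12)
})

test_that("the general combination degenerates to the simple one when extras vanish", {
  sim <- simulate_sem(3000, params_linear(), seed = 11)
  # fit once under the general RG spec and once under the plain spec: with
  # the optional coefficients estimated freely vs constrained, the *formulas*
  # must coincide when evaluated at identical parameter values
  p_hat <- fit_sem(sim$data, spec_linear())$params
  fit_plain <- sem_fit_from_params(p_hat, spec_linear(),
                                   covariate_rows = sim$data[c("c1", "c2")])
  fit_as_general <- sem_fit_from_params(p_hat, spec_general_rg(),
                                        covariate_rows = sim$data[c("c1", "c2")])
  e1 <- mediate_combination(fit_plain)
  e2 <- mediate_combination(fit_as_general, "robins_greenland")
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-12)
})

test_that("tnie equals tce minus pnde identically, and cde is affine in m with slope beta_xm", {
  for (seed in 1:5) {
    sim <- simulate_sem(1200, params_petersen(), seed = seed)
    fit <- fit_sem(sim$data, sim$spec)
    est <- mediate_combination(fit, "petersen")
    got <- setNames(est$estimate, est$estimand)
    expect_equal(got[["tnie"]], got[["tce"]] - got[["pnde"]],
                 tolerance = 1e-12)
    cde_at <- function(m) {
      e <- mediate_combination(fit, "petersen", cde_m = m)
      e$estimate[e$estimand == "cde"]
    }
    slope <- (cde_at(1.5) - cde_at(0.5)) / 1
    expect_equal(slope, fit$params$beta_xm, tolerance = 1e-8)
    # second difference zero: affine
    expect_equal(cde_at(2) - 2 * cde_at(1) + cde_at(0), 0, tolerance = 1e-8)
  }
  # under a Robins-Greenland fit the slope is exactly zero and CDE = PNDE at
  # every m for the plain linear model
  sim <- simulate_sem(1200, params_linear(), seed = 9)
  fit <- fit_sem(sim$data, spec_linear())
  for (m in c(-1, 0, 2)) {
    e <- mediate_combination(fit, cde_m = m)
    got <- setNames(e$estimate, e$estimand)
    expect_equal(got[["cde"]], got[["pnde"]], tolerance = 1e-12)
  }
})

test_that("tnie scales linearly in beta_m with all else fixed", {
  base <- params_linear()
  tnie_at <- function(bm) {
    p <- params_linear(beta_m = bm)
    fit <- sem_fit_from_params(p, c_config = default_c_config())
    e <- mediate_combination(fit)
    e$estimate[e$estimand == "tnie"]
  }
  t1 <- tnie_at(0.2)
  t2 <- tnie_at(0.4)
  t3 <- tnie_at(0.8)
  expect_equal(t2 / t1, 2, tolerance = 1e-10)
  expect_equal(t3 / t1, 4, tolerance = 1e-10)
})

test_that("delta-method SE reproduces the hand-evaluated formula and degenerates with V = 0", {
  p <- params_no_cov(gamma_x = 1.0, beta_l = 0.5, alpha_xl = 0, beta_mm = 0,
                     beta_ll = 0, beta_xl = 0, beta_xm = 0)
  fit <- sem_fit_from_params(p, c_config = no_cov_config())
  # stacked order: l:(Intercept), l:.x, m:(Intercept), m:.x, m:.l,
  #                y:(Intercept), y:.x, y:.m, y:.l
  V <- diag(c(0, 0.09, 0, 0, 0, 0, 0.01, 0, 0.04))
  fit$coef_cov <- V
  # PNDE = beta_x + beta_l gamma_x: Var = 0.01 + 1^2*0.04 + 0.5^2*0.09
  expect_equal(delta_se(fit, "pnde"), sqrt(0.0725), tolerance = 1e-6)
  expect_equal(delta_se(fit, "cde"), sqrt(0.0725), tolerance = 1e-6)

  fit$coef_cov <- matrix(0, 9, 9)
  for (est in c("tce", "pnde", "tnie", "cde")) {
    expect_equal(delta_se(fit, est), 0)
  }
  est0 <- mediate_combination(fit)
  expect_equal(est0$se, rep(0, 4))

  fit$coef_cov <- matrix(NaN, 9, 9)
  expect_warning(se_bad <- delta_se(fit, "tnie"), "unavailable")
  expect_true(is.na(se_bad))
})

test_that("combination estimates on simulated linear data agree with MC g-computation", {
  sim <- simulate_sem(20000, params_linear(), seed = 7)
  fit <- fit_sem(sim$data, spec_linear())
  cmb <- mediate_combination(fit)
  mc <- mediate_montecarlo(fit, n_mc = 100000, seed = 17)
  diff <- abs(cmb$estimate - mc$estimate)
  expect_true(all(diff <= 3 * pmax(mc$mc_se, 1e-12)))
})

test_that("natural effects stay unbiased under unmeasured confounder-outcome confounding", {
  # U -> L and U -> Y active: beta_l-hat is biased, but the combination's
  # PNDE/TNIE are not (>= 200 replicates)
  n_rep <- 200
  n <- 2000
  p <- params_linear()
  u_cfg <- list(sd_u = 1, lambda_l = 0.7, lambda_y = 0.7)
  truth <- truth_vec(truth_oracle(p))
  res <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_sem(n, p, u_config = u_cfg, seed = 60000 + r)
    fit <- fit_sem(sim$data, spec_linear())
    e <- mediate_combination(fit)
    c(setNames(e$estimate, e$estimand), beta_l = fit$params$beta_l)
  }, numeric(5))
  for (nm in c("pnde", "tnie")) {
    bias <- mean(res[nm, ]) - truth[[nm]]
    mc_se <- sd(res[nm, ]) / sqrt(n_rep)
    expect_lt(abs(bias), 2 * mc_se)
  }
  bl_bias <- mean(res["beta_l", ]) - p$beta_l
  bl_se <- sd(res["beta_l", ]) / sqrt(n_rep)
  expect_gt(abs(bl_bias), 5 * bl_se)
})
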