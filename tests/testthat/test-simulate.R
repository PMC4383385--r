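test_that("the generator is seeded, self-consistent, and honours the error correlation", {
  s1 <- simulate_sem(500, seed = 61)
  s2 <- simulate_sem(500, seed = 61)
  expect_identical(s1$data, s2$data)

  # data satisfy the structural surfaces exactly given the recorded errors
  p <- s1$params
  d <- s1$data
  e <- s1$errors
  expect_equal(d$m,
               p$alpha0 + p$alpha_x * d$x + p$alpha_l * d$l +
                 p$alpha_c[1] * d$c1 + p$alpha_c[2] * d$c2 +
                 p$alpha_xl * d$x * d$l + e$eps_m, tolerance = 1e-12)

  big <- simulate_sem(100000, params_linear(rho = 0.4), seed = 62)
  expect_lt(abs(cor(big$errors$eps_m, big$errors$eps_y) - 0.4), 0.01)
  expect_lt(abs(mean(big$data$x) - 0.19), 0.01)
  expect_lt(abs(mean(big$data$c1) - 0.55), 0.01)
})

test_that("the quadrature oracle reproduces the printed closed forms for the linear model", {
  p <- params_linear()
  tr <- truth_oracle(p)
  expect_equal(tr$true_pnde, p$beta_x + p$beta_l * p$gamma_x,
               tolerance = 1e-10)
  expect_equal(tr$true_cde, p$beta_x + p$beta_l * p$gamma_x,
               tolerance = 1e-10)
  expect_equal(tr$true_tnie,
               p$beta_m * (p$alpha_x + p$alpha_l * p$gamma_x),
               tolerance = 1e-10)
  expect_equal(tr$true_tce, tr$true_pnde + tr$true_tnie, tolerance = 1e-12)
})

test_that("a mediator-squared term feeds the indirect effect through both moments of M", {
  # only beta_mm added to the linear model, no covariates: hand expression
  # TNIE = beta_m dmu + beta_mm (mu1^2 - mu0^2), dmu = alpha_x + alpha_l gamma_x
  p <- params_no_cov(alpha_xl = 0, beta_ll = 0, beta_xl = 0, beta_xm = 0,
                     beta_mm = 0.06)
  tr <- truth_oracle(p, c_config = no_cov_config())
  mu_m <- function(x) {
    p$alpha0 + p$alpha_x * x + p$alpha_l * (p$gamma0 + p$gamma_x * x)
  }
  hand_tnie <- p$beta_m * (mu_m(1) - mu_m(0)) +
    p$beta_mm * (mu_m(1)^2 - mu_m(0)^2)
  expect_equal(tr$true_tnie, hand_tnie, tolerance = 1e-10)
  expect_equal(tr$true_pnde, p$beta_x + p$beta_l * p$gamma_x,
               tolerance = 1e-10)

  # plain Monte Carlo cross-check of the nested counterfactual integrals,
  # simulated directly from the structural equations
  set.seed(63)
  n <- 1000000
  draw_leg <- function(x, xp) {
    l <- p$gamma0 + p$gamma_x * x + rnorm(n, 0, sqrt(p$sigma2_l))
    lp <- p$gamma0 + p$gamma_x * xp + rnorm(n, 0, sqrt(p$sigma2_l))
    m <- p$alpha0 + p$alpha_x * xp + p$alpha_l * lp +
      rnorm(n, 0, sqrt(p$sigma2_m))
    y <- p$beta0 + p$beta_x * x + p$beta_m * m + p$beta_mm * m^2 +
      p$beta_l * l + rnorm(n, 0, sqrt(p$sigma2_y))
    y
  }
  y11 <- draw_leg(1, 1)
  y10 <- draw_leg(1, 0)
  tnie_mc <- mean(y11) - mean(y10)
  mc_se <- sqrt(var(y11) / n + var(y10) / n)
  expect_lt(abs(tnie_mc - tr$true_tnie), 3 * mc_se)
})

test_that("doubling the quadrature order leaves the oracle unchanged", {
  p <- sem_params()
  t1 <- truth_oracle(p, gh_nodes = 24)
  t2 <- truth_oracle(p, gh_nodes = 48)
  expect_lt(abs(t1$true_tce - t2$true_tce), 1e-8)
  expect_lt(abs(t1$true_pnde - t2$true_pnde), 1e-8)
  expect_lt(abs(t1$true_tnie - t2$true_tnie), 1e-8)
  expect_lt(abs(t1$true_cde - t2$true_cde), 1e-8)
})

test_that("oracle constraint checking and config validation fire", {
  expect_error(truth_oracle(sem_params(beta_xm = 0.2),
                            assumption = "robins_greenland"), "beta_xm")
  expect_error(truth_oracle(sem_params(), assumption = "petersen"),
               "beta_ll")
  expect_error(simulate_sem(100, sem_params(), c_config = list(),
                            seed = 1), "covariate")
  expect_error(cov_bernoulli(1.2), "\\(0, 1\\)")
  expect_error(simulate_sem(100, seed = 1,
                            u_config = list(sd_u = -1, lambda_l = 1,
                                            lambda_y = 1)), "u_config")
})

test_that("correlated errors with no mediated path produce exactly the confounding signature", {
  # the scenario the sensitivity analysis is built to flag: rho != 0 and
  # beta_m = 0 biases the estimated indirect effect away from its true 0,
  # while rho-prime converges to rho
  p <- params_linear(beta_m = 0, rho = 0.35)
  sim <- simulate_sem(20000, p, seed = 64)
  expect_equal(sim$truth$true_tnie, 0, tolerance = 1e-10)
  res <- rho_prime(sim$data, spec_linear(), ci = FALSE)
  expect_equal(res$rho_prime_hat, rho_prime_limit(0, rho = 0.35),
               tolerance = 0.03)
  est <- mediate_combination(fit_sem(sim$data, spec_linear()))
  tnie_row <- est[est$estimand == "tnie", ]
  expect_gt(abs(tnie_row$estimate), 3 * tnie_row$se)
})
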