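test_that("an exactly interpolating outcome equation is recovered to machine precision", {
  # free mediator/confounder columns + deterministic outcome: the Y equation
  # interpolates, so OLS returns the generating coefficients exactly
  set.seed(31)
  n <- 400
  d <- tibble::tibble(
    x = rbinom(n, 1, 0.4), l = rnorm(n), m = rnorm(n),
    c1 = rbinom(n, 1, 0.5), c2 = rnorm(n)
  )
  b <- c(b0 = 0.3, bx = 0.07, bm = 0.31, bl = 0.03, bc1 = -0.011,
         bc2 = 0.207, bmm = 0.04, bll = 0.03, bxl = 0.08)
  d$y <- with(d, b["b0"] + b["bx"] * x + b["bm"] * m + b["bl"] * l +
                b["bc1"] * c1 + b["bc2"] * c2 + b["bmm"] * m^2 +
                b["bll"] * l^2 + b["bxl"] * x * l)
  fit <- suppressWarnings(fit_sem(d, spec_general_rg()))  # perfect fit
  p <- fit$params
  expect_equal(c(p$beta0, p$beta_x, p$beta_m, p$beta_l, p$beta_c,
                 p$beta_mm, p$beta_ll, p$beta_xl),
               unname(b), tolerance = 1e-10)
  expect_equal(p$sigma2_y, 0, tolerance = 1e-16)
})

test_that("an exactly interpolating mediator equation is recovered to machine precision", {
  # free confounder column + deterministic mediator; the Petersen-style
  # outcome spec keeps the Y design full rank despite the exact M surface
  set.seed(32)
  n <- 400
  d <- tibble::tibble(
    x = rbinom(n, 1, 0.4), l = rnorm(n),
    c1 = rbinom(n, 1, 0.5), c2 = rbinom(n, 1, 0.3)
  )
  a <- c(a0 = 0.1, ax = 0.55, al = 0.05, ac1 = 0.10, ac2 = -0.02, axl = 0.1)
  d$m <- with(d, a["a0"] + a["ax"] * x + a["al"] * l + a["ac1"] * c1 +
                a["ac2"] * c2 + a["axl"] * x * l)
  d$y <- with(d, 0.3 * x + 0.31 * m + 0.03 * l + rnorm(n))
  fit <- suppressWarnings(fit_sem(d, spec_general_pt()))  # perfect fit
  p <- fit$params
  expect_equal(c(p$alpha0, p$alpha_x, p$alpha_l, p$alpha_c, p$alpha_xl),
               unname(a), tolerance = 1e-10)
  expect_equal(p$sigma2_m, 0, tolerance = 1e-16)
})

test_that("a fully deterministic system is reported as collinear", {
  sim <- simulate_sem(200, sem_params(sigma2_l = 0, sigma2_m = 0,
                                      sigma2_y = 0), seed = 5)
  # data lie exactly on the structural surfaces ...
  p <- sim$params
  expect_equal(sim$data$l,
               with(sim$data, p$gamma0 + p$gamma_x * x + p$gamma_c[1] * c1 +
                      p$gamma_c[2] * c2), tolerance = 1e-12)
  # ... which makes the downstream designs rank deficient
  expect_error(fit_sem(sim$data, sim$spec), "rank deficient")
})

test_that("coefficients are recovered within 4 standard errors at n = 5000", {
  sim <- simulate_sem(5000, seed = 1)
  fit <- fit_sem(sim$data, sim$spec)
  tt <- tidy(fit)
  p <- sim$params
  true <- c(p$gamma0, p$gamma_x, p$gamma_c,
            p$alpha0, p$alpha_x, p$alpha_l, p$alpha_c, p$alpha_xl,
            p$beta0, p$beta_x, p$beta_m, p$beta_l, p$beta_c,
            p$beta_mm, p$beta_ll, p$beta_xl)
  expect_equal(nrow(tt), length(true))
  expect_true(all(abs(tt$estimate - true) < 4 * tt$std.error))
})

test_that("input validation errors are explicit", {
  sim <- simulate_sem(300, seed = 2)
  d <- sim$data
  expect_error(fit_sem(d[setdiff(names(d), "m")], sim$spec), "not found.*m")

  d_na <- d
  d_na$y[5] <- NA
  expect_error(fit_sem(d_na, sim$spec), "missing values.*y")

  d_x <- d
  d_x$x[1] <- 2
  expect_error(fit_sem(d_x, sim$spec), "0/1")

  # duplicated covariate column => collinearity error naming the column
  d_dup <- d
  d_dup$c3 <- d_dup$c1
  sp_dup <- sem_spec("x", "m", "y", "l", c = c("c1", "c2", "c3"))
  expect_error(fit_sem(d_dup, sp_dup), "rank deficient.*c3")
})

test_that("residuals are centered and orthogonal to the regressors, and refits are bit-reproducible", {
  sim <- simulate_sem(1500, seed = 3)
  fit <- fit_sem(sim$data, sim$spec)
  for (eq in c("l", "m", "y")) {
    r <- fit$residuals[[eq]]
    X <- stats::model.matrix(fit$fits[[eq]])
    expect_lt(max(abs(crossprod(X, r))) / nrow(X), 1e-10)
    expect_lt(abs(mean(r)), 1e-12)
  }
  expect_true(isSymmetric(fit$coef_cov))
  expect_gte(min(eigen(fit$coef_cov, only.values = TRUE)$values), -1e-12)
  fit2 <- fit_sem(sim$data, sim$spec)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$coef_cov, fit2$coef_cov)
})

test_that("the reduced-form exposure coefficient equals the coefficient combination (no covariates)", {
  # nested-OLS algebra: with no covariates the X coefficient of Y ~ X equals
  # beta_x + alpha_x beta_m + alpha_l beta_m gamma_x + beta_l gamma_x exactly
  sim <- simulate_sem(800, params_no_cov(alpha_xl = 0, beta_mm = 0,
                                         beta_ll = 0, beta_xl = 0),
                      c_config = no_cov_config(), seed = 4)
  fit <- fit_sem(sim$data, spec_linear(covs = character()))
  p <- fit$params
  reduced <- unname(coef(lm(y ~ x, data = sim$data))["x"])
  expect_equal(reduced,
               p$beta_x + p$alpha_x * p$beta_m +
                 p$alpha_l * p$beta_m * p$gamma_x + p$beta_l * p$gamma_x,
               tolerance = 1e-10)
})
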