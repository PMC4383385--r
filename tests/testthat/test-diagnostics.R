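test_that("the recommendation rule is a pure function of the two p-values", {
  # study-like evidence: no exposure-mediator interaction, but curvature and
  # exposure-confounder interaction present => Robins-Greenland retained
  expect_identical(identification_recommendation(0.76, 0.01), "robins_greenland")
  expect_identical(identification_recommendation(0.5, 0.5), "both_admissible")
  expect_identical(identification_recommendation(0.001, 0.6), "petersen")
  expect_identical(identification_recommendation(0.001, 0.001),
                   "neither_admissible")
  # boundary: p == alpha is not a rejection
  expect_identical(identification_recommendation(0.05, 0.05, alpha = 0.05),
                   "both_admissible")
})

test_that("strong generating interactions drive the report to the right branch", {
  # large beta_xm and beta_ll: both tests reject => neither admissible
  p_bad <- sem_params(beta_xm = 0.5, beta_ll = 0.4, beta_xl = 0)
  sim <- simulate_sem(4000, p_bad, seed = 41)
  rep1 <- check_identification(sim$data, spec_linear())
  expect_identical(rep1$recommendation, "neither_admissible")
  expect_lt(rep1$p_beta_xm, 0.05)
  expect_lt(rep1$p_joint_xl_ll, 0.05)

  # only curvature/interaction in L: Robins-Greenland retained
  sim2 <- simulate_sem(4000, sem_params(beta_ll = 0.4, beta_xl = 0.3),
                       seed = 42)
  rep2 <- check_identification(sim2$data, spec_linear())
  expect_identical(rep2$recommendation, "robins_greenland")

  # only an exposure-mediator interaction: Petersen retained
  sim3 <- simulate_sem(4000, params_petersen(beta_xm = 0.5), seed = 43)
  rep3 <- check_identification(sim3$data, spec_linear())
  expect_identical(rep3$recommendation, "petersen")
})

test_that("the report reproduces the SEM fit on shared terms and has valid p-values", {
  sim <- simulate_sem(1500, params_linear(), seed = 44)
  rep <- check_identification(sim$data, spec_linear())
  expect_true(all(rep$coefficients$p.value >= 0 &
                    rep$coefficients$p.value <= 1))
  # the unconstrained outcome model is what a full-term fit_sem would give
  full_spec <- sem_spec("x", "m", "y", "l", c = c("c1", "c2"),
                        terms_y = c("x", "m", "l", "c", "m2", "l2", "xl",
                                    "xm"))
  fit_full <- fit_sem(sim$data, full_spec)
  tt <- tidy(fit_full)
  yy <- tt[tt$equation == "y", ]
  expect_equal(rep$coefficients$estimate, yy$estimate, tolerance = 1e-12)
  expect_equal(rep$coefficients$std.error, yy$std.error, tolerance = 1e-12)
})

test_that("null-model p-values are approximately uniform", {
  # moderate replication here; the full 500-replicate calibration of the
  # rejection rate lives with the acceptance checks
  n_rep <- 120
  p <- params_linear()
  ps <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_sem(800, p, seed = 3000 + r)
    rep <- check_identification(sim$data, spec_linear())
    c(rep$p_beta_xm, rep$p_joint_xl_ll)
  }, numeric(2))
  for (i in 1:2) {
    ks <- suppressWarnings(ks.test(ps[i, ], "punif"))
    expect_lt(unname(ks$statistic), 0.15)
  }
})
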