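test_that("standardization reproduces the closed-form latent-response scaling", {
  # null coefficients: no rescaling at all
  s0 <- standardize_probit(c(0, 0), diag(1.15, 2))
  expect_equal(s0$sd_u, 1)
  expect_equal(s0$bs, c(0, 0))
  # single predictor, b = 1, V(x) = 1.15
  s1 <- standardize_probit(1, matrix(1.15), se = 0.1)
  expect_equal(s1$sd_u, sqrt(2.15))
  expect_equal(s1$bs, sqrt(1.15) / sqrt(2.15), tolerance = 1e-6)
  expect_equal(s1$bs, 0.7313, tolerance = 1e-4)
  expect_equal(s1$se, 0.1 * sqrt(1.15) / sqrt(2.15))
  # the generating model maps back to the population coefficients
  s2 <- standardize_probit(c(0.2, 0.3), diag(1.15, 2))
  expect_equal(s2$sd_u, sqrt(0.1495 + 1))
  expect_equal(s2$bs, c(0.20, 0.30), tolerance = 5e-3)
  expect_error(standardize_probit(c(1, 1), matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("the complete-case probit optimum matches an independent optimizer", {
  obs <- make_obs(n = 1000, b_non1 = 0.3, b_non2 = 0.0, seed = 101)
  fit <- fit_probit_cc(obs)
  expect_true(fit$converged)
  expect_identical(fit$n_used, 700L)
  oracle <- oracle_probit_opt(obs$y_cat, as.matrix(obs[c("x1", "x2")]),
                              K = 4)
  expect_lt(abs(fit$raw$logLik + oracle$objective), 1e-4)
  expect_equal(unname(fit$raw$coef), unname(oracle$par[1:2]),
               tolerance = 1e-3)
})

test_that("threshold estimates are strictly increasing across replications", {
  for (r in 1:20) {
    obs <- make_obs(n = 500, b_non1 = 0.1, b_non2 = 0.3, seed = 110 + r)
    fit <- fit_probit_cc(obs)
    if (fit$converged) expect_true(all(diff(fit$raw$zeta) > 0))
  }
})

test_that("a null generating model yields null standardized estimates", {
  pop0 <- population_params(b_pred1 = 0, b_pred2 = 0)
  s <- generate_complete_sample(pop0, n = 4000, seed = 121)
  dat <- as.data.frame(s)
  dat$y_cat <- ordinalize(dat$y_cont, ordinal_spec(4),
                          sd_y = theoretical_moments(pop0)$sd_y)
  fit <- fit_probit_cc(dat)
  for (i in 1:2) {
    expect_lt(abs(fit$estimates$estimate[i]), 3 * fit$estimates$se[i])
  }
})

test_that("estimators agree when nothing is missing", {
  s <- generate_complete_sample(default_pop, n = 1500, seed = 131)
  dat <- as.data.frame(s)
  dat$y_obs <- dat$y_cont
  dat$y_cat <- ordinalize(dat$y_cont, ordinal_spec(4),
                          sd_y = default_mom$sd_y)
  cc <- fit_probit_cc(dat)
  mi <- fit_probit_mi(dat, mi_settings(m = 5), seed = 1)
  fiml <- fit_probit_fiml(dat)
  # MI with nothing to impute is the complete-case fit, relabelled
  expect_identical(mi$estimates, cc$estimates)
  expect_identical(mi$method, "MI")
  # FIML's joint model adds an orthogonal auxiliary: same estimates up
  # to optimizer/finite-sample wiggle
  expect_equal(fiml$estimates$estimate, cc$estimates$estimate,
               tolerance = 0.02)
})

test_that("CI bounds are the Wald construction around the standardized estimate", {
  obs <- make_obs(seed = 141)
  fit <- fit_probit_cc(obs)
  expect_equal(fit$estimates$ci_low,
               fit$estimates$estimate - 1.96 * fit$estimates$se)
  expect_equal(fit$estimates$ci_high,
               fit$estimates$estimate + 1.96 * fit$estimates$se)
})

test_that("an extreme category emptied by deletion is collapsed, not fatal", {
  obs <- make_obs(n = 600, seed = 151)
  # deletion leaves no complete case in the bottom category
  obs$y_cat[obs$y_cat == 1L] <- NA
  fit <- fit_probit_cc(obs)
  expect_true(fit$converged)
  expect_match(fit$notes, "collapsed")
  expect_length(fit$raw$zeta, 2L)   # 3 categories left
})

test_that("the linear complete-case slope equals the covariance ratio", {
  dat <- data.frame(x1 = c(-2, -1, 0, 1, 2),
                    y_obs = c(-1.9, -1.2, 0.3, 0.8, 2.1))
  fit <- fit_linear_cc(dat, predictors = "x1")
  expect_equal(fit$estimates$estimate,
               cov(dat$x1, dat$y_obs) / var(dat$x1))
  expect_identical(fit$n_used, 5L)
  # rank deficiency is an error
  dat2 <- data.frame(x1 = 1:5, x2 = 2 * (1:5), y_obs = rnorm(5))
  expect_error(fit_linear_cc(dat2), "rank-deficient")
})

test_that("linear regression on complete cases recovers the population slopes", {
  s <- generate_complete_sample(default_pop, n = 2e5, seed = 161)
  dat <- as.data.frame(s)
  dat$y_obs <- dat$y_cont
  fit <- fit_linear_cc(dat)
  expect_equal(fit$estimates$estimate, c(0.20, 0.30), tolerance = 0.02)
})
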