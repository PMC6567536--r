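test_that("analytic liability variance matches a Monte Carlo oracle", {
  # rho_x3 = 0 so the systematic part's variance can also be computed
  # by brute force from a huge sample
  pop <- population_params(rho_x3 = 0)
  scen <- missingness_scenario(0.1, 0.1, 0.7)
  vr <- liability_variance(pop, scen)
  s <- generate_complete_sample(pop, n = 1e6, seed = 21)
  sys_part <- 0.1 * (s$x1 + s$x2 + s$x3) + 0.1 * s$y_cont
  expect_equal(var(sys_part), vr$var_systematic, tolerance = 0.01)
  expect_equal(vr$var_systematic + vr$var_residual, 1.15)
})

test_that("total liability variance is 1.15 in every condition", {
  s <- generate_complete_sample(default_pop, n = 1e6, seed = 22)
  for (dep in list(c(0, 0), c(0.1, 0.1), c(0.3, 0.0), c(0.3, 0.3))) {
    scen <- missingness_scenario(dep[1], dep[2], 0.7)
    L <- compute_liability(s, scen, seed = 23)
    expect_equal(var(L), 1.15, tolerance = 0.01)
  }
})

test_that("over-explained liability is rejected with the offending coefficients", {
  scen <- missingness_scenario(b_non1 = 1.0, b_non2 = 0, 0.7)
  expect_error(liability_variance(default_pop, scen),
               "b_non1 = 1.*exceeding")
})

test_that("achieved missingness equals the target exactly under both mechanisms", {
  s <- generate_complete_sample(default_pop, n = 1000, seed = 31)
  for (rr in c(0.7, 0.5)) for (ex in c(FALSE, TRUE)) {
    scen <- missingness_scenario(0.3, 0.1, rr, extremes_removed = ex)
    obs <- apply_missingness(s, scen, seed = 32)
    expect_identical(sum(obs$m), as.integer(1000 * (1 - rr)))
    expect_identical(is.na(obs$y_obs), obs$m == 1L)
    expect_false(anyNA(obs[c("x1", "x2", "x3")]))
  }
  # odd n: ceiling of the target count
  s2 <- generate_complete_sample(default_pop, n = 999, seed = 33)
  obs2 <- apply_missingness(s2, missingness_scenario(0, 0, 0.7), seed = 34)
  expect_identical(sum(obs2$m), as.integer(ceiling(999 * 0.3)))
})

test_that("the liability cut sits at its population quantile (0.52 SD at 70%)", {
  s <- generate_complete_sample(default_pop, n = 1e5, seed = 41)
  scen70 <- missingness_scenario(0.1, 0.1, 0.70)
  obs70 <- apply_missingness(s, scen70, seed = 42)
  expect_equal(attr(obs70, "thresholds")$L_cut_sd, qnorm(0.70),
               tolerance = 0.02)
  scen50 <- missingness_scenario(0.1, 0.1, 0.50)
  obs50 <- apply_missingness(s, scen50, seed = 42)
  expect_equal(attr(obs50, "thresholds")$L_cut_sd, 0, tolerance = 0.02)
})

test_that("MCAR missingness leaves responders and non-responders exchangeable", {
  scen <- missingness_scenario(0, 0, 0.7)
  diffs <- vapply(1:200, function(r) {
    s <- generate_complete_sample(default_pop, n = 400, seed = 100 + r)
    obs <- apply_missingness(s, scen, seed = 300 + r)
    mean(obs$y_cont[obs$m == 1]) - mean(obs$y_cont[obs$m == 0])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("removing extremes empties the top decile; under-representation keeps it", {
  s <- generate_complete_sample(default_pop, n = 1000, seed = 51)
  cut90 <- quantile(s$y_cont, 0.9, type = 1)
  rem <- apply_missingness(s, missingness_scenario(0.3, 0.3, 0.7, TRUE),
                           seed = 52)
  expect_identical(sum(rem$m), 300L)
  top <- rank(-s$y_cont, ties.method = "first") <= 100
  expect_true(all(rem$m[top] == 1L))
  expect_lt(max(rem$y_obs, na.rm = TRUE), max(s$y_cont[top]))
  und <- apply_missingness(s, missingness_scenario(0.3, 0.3, 0.7, FALSE),
                           seed = 52)
  expect_gt(sum(und$y_obs > cut90, na.rm = TRUE), 0)  # extremes present
  expect_lt(sum(und$y_obs > cut90, na.rm = TRUE), 100)  # under-represented
})

test_that("with zero dependency the L cut removes exactly the residual count", {
  # brute-force reconstruction of the union of the two criteria
  s <- generate_complete_sample(default_pop, n = 1000, seed = 61)
  scen <- missingness_scenario(0, 0, 0.7, extremes_removed = TRUE)
  obs <- apply_missingness(s, scen, seed = 62)
  L <- compute_liability(s, scen, seed = 62)
  top <- rank(-s$y_cont, ties.method = "first") <= 100
  expect_identical(sum(obs$m == 1L & !top), 200L)
  o <- order(-L)
  brute <- top
  for (i in o) {
    if (sum(brute) >= 300) break
    brute[i] <- TRUE
  }
  expect_identical(obs$m == 1L, brute)
})

test_that("stronger outcome dependency widens the responder/non-responder gap", {
  gap <- function(b_non2, r) {
    s <- generate_complete_sample(default_pop, n = 500, seed = 700 + r)
    obs <- apply_missingness(
      s, missingness_scenario(0.1, b_non2, 0.7), seed = 900 + r)
    mean(obs$y_cont[obs$m == 1]) - mean(obs$y_cont[obs$m == 0])
  }
  g0 <- vapply(1:100, function(r) gap(0.0, r), numeric(1))
  g3 <- vapply(1:100, function(r) gap(0.3, r), numeric(1))
  expect_gt(mean(g3), mean(g0))
  expect_gt(mean(g3), 0.3)   # clearly selective
})

test_that("infeasible extreme-removal calibration is rejected", {
  s <- generate_complete_sample(default_pop, n = 100, seed = 71)
  scen <- missingness_scenario(0, 0, 0.95, extremes_removed = TRUE)
  expect_error(apply_missingness(s, scen, seed = 72), "infeasible")
  expect_error(missingness_scenario(0, 0, response_rate = 1), "response_rate")
  expect_error(missingness_scenario(0, 0, response_rate = 0), "response_rate")
})

test_that("dispatch guards against the wrong mechanism function", {
  s <- generate_complete_sample(default_pop, n = 100, seed = 81)
  expect_error(apply_missingness_underrep(
    s, missingness_scenario(0, 0, 0.7, TRUE), seed = 1), "extremes_removed")
  expect_error(apply_missingness_extremes_removed(
    s, missingness_scenario(0, 0, 0.7, FALSE), seed = 1), "extremes_removed")
})
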