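test_that("per-replication seeds are deterministic, distinct and 31-bit", {
  s1 <- derive_seed(1, "a-scenario", 1)
  expect_identical(s1, derive_seed(1, "a-scenario", 1))
  seeds <- vapply(1:500, function(r) derive_seed(1, "a-scenario", r),
                  integer(1))
  expect_identical(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 1 & seeds < 2^31))
  expect_false(derive_seed(1, "a-scenario", 1) ==
                 derive_seed(1, "b-scenario", 1))
  expect_false(derive_seed(1, "a-scenario", 1) ==
                 derive_seed(2, "a-scenario", 1))
})

test_that("a short scenario run emits a structurally complete summary", {
  sc <- scenario(miss = missingness_scenario(0.3, 0.1, 0.7, TRUE),
                 methods = c("CC", "FIML", "MI"),
                 mi = mi_settings(m = 3), n_replications = 5)
  res <- run_scenario(sc, base_seed = 3)
  expect_s3_class(res, "scenario_result")
  expect_identical(nrow(res$summary), 6L)   # 3 methods x 2 predictors
  expect_setequal(res$summary$method, c("CC", "FIML", "MI"))
  expect_true(all(c("mean_estimate", "mean_se", "relative_bias",
                    "coverage95", "n_replications", "n_converged")
                  %in% names(res$summary)))
  expect_identical(unique(res$summary$n_replications), 5L)
  expect_identical(nrow(res$fits), 5L * 3L * 2L)
})

test_that("identical configuration and seed reproduce results exactly", {
  sc <- scenario(miss = missingness_scenario(0.1, 0.3, 0.5),
                 methods = "CC", n_replications = 8)
  a <- run_scenario(sc, base_seed = 11)
  b <- run_scenario(sc, base_seed = 11)
  expect_identical(a$fits, b$fits)
  expect_identical(a$summary, b$summary)
  c <- run_scenario(sc, base_seed = 12)
  expect_false(identical(a$summary$mean_estimate,
                         c$summary$mean_estimate))
})

test_that("scenario-level infeasibility surfaces before any replication", {
  expect_error(scenario(miss = missingness_scenario(1.0, 0.3)),
               "exceeding")
  expect_error(scenario(miss = missingness_scenario(
    0, 0, response_rate = 0.95, extremes_removed = TRUE)),
    "infeasible")
})

test_that("the study grid enumerates every condition exactly once", {
  g <- study_grid()
  expect_length(g, 24L)   # 6 dependency pairs x 2 rates x 2 mechanisms
  expect_identical(anyDuplicated(names(g)), 0L)
  deps <- t(vapply(g, function(s) c(s$miss$b_non1, s$miss$b_non2),
                   numeric(2)))
  expect_identical(nrow(unique(deps)), 6L)
  rates <- vapply(g, function(s) s$miss$response_rate, numeric(1))
  expect_setequal(rates, c(0.7, 0.5))
  # 3 outcome scales x 6 pairs x 2 mechanisms at 50% response
  f <- followup_grid()
  expect_length(f, 36L)
  expect_true(all(vapply(f, function(s) identical(s$methods, "CC"),
                         logical(1))))
  conts <- vapply(f, function(s) isTRUE(s$ordinal$continuous), logical(1))
  expect_identical(sum(conts), 12L)
})

test_that("a reduced grid run writes deterministic tables and pairs prevention", {
  g <- study_grid(dep_pairs = cbind(0.3, 0.3), response_rates = 0.7,
                  methods = "CC", n_replications = 6)
  out1 <- withr::local_tempdir()
  r1 <- run_grid(g, base_seed = 5, out_dir = out1)
  for (f in c("fits.csv", "summary.csv", "prevention.csv",
              "summary_table.txt"))
    expect_true(file.exists(file.path(out1, f)))
  expect_identical(nrow(r1$summary), 4L)  # 2 mechanisms x 2 predictors
  expect_identical(nrow(r1$prevention), 2L)
  expect_true(all(c("R1", "R2", "prevented_pct") %in%
                    names(r1$prevention)))
  expect_equal(r1$prevention$prevented_pct,
               100 * (r1$prevention$R1 - r1$prevention$R2) /
                 r1$prevention$R1)
  out2 <- withr::local_tempdir()
  run_grid(g, base_seed = 5, out_dir = out2)
  expect_identical(readLines(file.path(out1, "summary.csv")),
                   readLines(file.path(out2, "summary.csv")))
})

test_that("a continuous-outcome scenario runs the linear estimator", {
  sc <- scenario(miss = missingness_scenario(0.3, 0.3, 0.5, TRUE),
                 ordinal = ordinal_spec(continuous = TRUE),
                 n_replications = 5)
  expect_identical(sc$methods, "CC")
  res <- run_scenario(sc, base_seed = 21)
  expect_identical(nrow(res$summary), 2L)
  # totally missing extremes attenuate the linear slope too
  expect_gt(res$summary$relative_bias[res$summary$predictor == "x2"], 0)
})

test_that("formatted summary tables carry the scenario-by-method layout", {
  g <- study_grid(dep_pairs = cbind(0.1, 0.1), response_rates = 0.7,
                  methods = "CC", n_replications = 4)
  r <- run_grid(g, base_seed = 7)
  txt <- format_summary_table(r$summary)
  expect_true(any(grepl("Response rate 70%, extreme scores totally missing",
                        txt)))
  expect_true(any(grepl("present \\(under-represented\\)", txt)))
  expect_true(any(grepl("^0.1    0.1    x1", txt)))
})
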