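#' Define one simulation scenario
#'
#' Bundles population parameters, a missingness scenario, an ordinal
#' measurement spec, the estimator set and the replication count into
#' a single validated object.  Scenario-level infeasibilities (a
#' liability residual variance that would be negative, an extreme
#' fraction exceeding the target non-response) are surfaced here,
#' before any replication runs.
#'
#' @param pop [population_params()].
#' @param miss [missingness_scenario()].
#' @param ordinal [ordinal_spec()].  A continuous spec restricts the
#'   estimator set to the linear complete-case fit.
#' @param n Sample size before non-response (default 1000).
#' @param methods Estimators to run: subset of `"CC"`, `"FIML"`,
#'   `"MI"`.
#' @param mi [mi_settings()] used when `"MI"` is requested.
#' @param n_replications Number of Monte Carlo replications (default
#'   500, the full study setting).
#' @param id Scenario identifier; derived from the configuration when
#'   omitted.  Enters per-replication seed derivation, so two
#'   scenarios with different ids draw independent streams.
#' @return An object of class `scenario`.
#' @export
scenario <- function(pop = population_params(),
                     miss = missingness_scenario(),
                     ordinal = ordinal_spec(4L),
                     n = 1000L,
                     methods = c("CC", "FIML", "MI"),
                     mi = mi_settings(),
                     n_replications = 500L,
                     id = NULL) {
  stopifnot(inherits(pop, "population_params"),
            inherits(miss, "missingness_scenario"),
            inherits(ordinal, "ordinal_spec"),
            inherits(mi, "mi_settings"))
  methods <- match.arg(methods, c("CC", "FIML", "MI"),
                       several.ok = TRUE)
  if (ordinal$continuous && !identical(methods, "CC"))
    methods <- "CC"  # continuous follow-up uses the linear CC fit
  liability_variance(pop, miss)       # errors if infeasible
  if (miss$extremes_removed &&
      round(n * miss$extreme_fraction) > target_missing(n, miss$response_rate))
    stop("infeasible scenario: extreme fraction exceeds target ",
         "non-response", call. = FALSE)
  if (is.null(id))
    id <- sprintf("rr%02.0f_%s_bn1-%g_bn2-%g_%s",
                  100 * miss$response_rate,
                  if (miss$extremes_removed) "removed" else "present",
                  miss$b_non1, miss$b_non2,
                  if (ordinal$continuous) "cont"
                  else paste0("k", ordinal$n_categories))
  structure(list(pop = pop, miss = miss, ordinal = ordinal,
                 n = as.integer(n), methods = methods, mi = mi,
                 n_replications = as.integer(n_replications), id = id),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': n = %d, %d replications, methods = %s\n",
              x$id, x$n, x$n_replications,
              paste(x$methods, collapse = "/")))
  print(x$miss)
  print(x$ordinal)
  invisible(x)
}

#' Deterministic per-replication seed
#'
#' Derives a 31-bit seed from `(base_seed, scenario id, replication
#' index)` with a polynomial string hash, so that every replication of
#' every scenario has its own reproducible random stream regardless of
#' execution order or parallel scheduling.
#'
#' @param base_seed Integer master seed.
#' @param scenario_id Scenario identifier string.
#' @param rep Replication index.
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
derive_seed <- function(base_seed, scenario_id, rep) {
  M <- 2147483629  # largest prime < 2^31; 31*h + 255 stays exact in doubles
  key <- paste(scenario_id, rep, sep = "#")
  h <- as.numeric(base_seed) %% M
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% M
  as.integer(h + 1)
}

#' Run one replication of a scenario
#'
#' Generates a complete sample, imposes non-response, categorizes the
#' outcome and runs every requested estimator, all under a single
#' deterministic seed.
#'
#' @param scen A [scenario()].
#' @param seed Integer seed for this replication (typically from
#'   [derive_seed()]).
#' @return A list of `fit_result` objects, one per method, with the
#'   realized missingness thresholds attached as attribute
#'   `"thresholds"`.
#' @export
run_replication <- function(scen, seed) {
  stopifnot(inherits(scen, "scenario"))
  withr::with_seed(seed, {
    smp <- generate_complete_sample(scen$pop, n = scen$n)
    obs <- apply_missingness(smp, scen$miss)
    sd_y <- theoretical_moments(scen$pop)$sd_y
    if (!scen$ordinal$continuous)
      obs$y_cat <- ordinalize(obs$y_obs, scen$ordinal, sd_y = sd_y)
    fits <- lapply(scen$methods, function(m) {
      if (scen$ordinal$continuous) fit_linear_cc(obs)
      else switch(m,
                  CC = fit_probit_cc(obs),
                  FIML = fit_probit_fiml(obs),
                  MI = fit_probit_mi(obs, settings = scen$mi))
    })
    names(fits) <- scen$methods
    attr(fits, "thresholds") <- attr(obs, "thresholds")
    fits
  })
}

#' Run all replications of a scenario and summarize
#'
#' Per-replication seeds come from [derive_seed()], so an identical
#' configuration and `base_seed` reproduce the summary exactly.
#'
#' @param scen A [scenario()].
#' @param base_seed Master seed (default 1).
#' @param true_values Named true coefficients used for relative bias
#'   and coverage; defaults to the scenario's generating coefficients.
#' @param progress Print a dot every 50 replications?
#' @return An object of class `scenario_result`: `scenario`, tidy
#'   replication-level `fits` (one row per replication x method x
#'   predictor), the aggregated `summary`, and a `convergence` count
#'   per method.
#' @export
run_scenario <- function(scen, base_seed = 1L, true_values = NULL,
                         progress = FALSE) {
  stopifnot(inherits(scen, "scenario"))
  true_values <- true_values %||%
    c(x1 = scen$pop$b_pred1, x2 = scen$pop$b_pred2)
  rows <- vector("list", scen$n_replications)
  for (r in seq_len(scen$n_replications)) {
    fits <- run_replication(scen, derive_seed(base_seed, scen$id, r))
    rows[[r]] <- do.call(rbind, lapply(names(fits), function(m) {
      df <- as.data.frame(fits[[m]])
      df$method <- m   # label by requested method (linear CC included)
      cbind(scenario = scen$id, replication = r, df)
    }))
    if (progress && r %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  fits_df <- do.call(rbind, rows)
  conv <- tapply(fits_df$converged[fits_df$predictor == "x1"],
                 fits_df$method[fits_df$predictor == "x1"], sum)
  structure(list(scenario = scen,
                 fits = fits_df,
                 summary = cbind(scenario = scen$id,
                                 summarize_fits(fits_df, true_values)),
                 convergence = conv),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%d replications)\n",
              x$scenario$id, x$scenario$n_replications))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' The full factorial of study conditions
#'
#' Builds the scenario grid of the simulation study: six dependency
#' pairs `(b_non1, b_non2)` in (0.3, 0.0), (0.1, 0.1), (0.3, 0.1),
#' (0.0, 0.3), (0.1, 0.3), (0.3, 0.3), crossed with response rates 70%
#' and 50% and with extreme scorers present versus totally missing,
#' analyzed with CC, FIML and MI on the 4-category ordinal outcome.
#'
#' @param dep_pairs Two-column matrix (or data frame) of
#'   `(b_non1, b_non2)` pairs.
#' @param response_rates Response rates to cross (default 0.70, 0.50).
#' @param extremes Logical values of `extremes_removed` to cross.
#' @param ordinal Ordinal spec shared by all scenarios.
#' @param methods,n,mi,n_replications Passed to [scenario()].
#' @param pop Population parameters shared by all scenarios.
#' @return A named list of [scenario()] objects.
#' @export
study_grid <- function(dep_pairs = cbind(b_non1 = c(0.3, 0.1, 0.3, 0.0, 0.1, 0.3),
                                         b_non2 = c(0.0, 0.1, 0.1, 0.3, 0.3, 0.3)),
                       response_rates = c(0.70, 0.50),
                       extremes = c(FALSE, TRUE),
                       ordinal = ordinal_spec(4L),
                       methods = c("CC", "FIML", "MI"),
                       n = 1000L, mi = mi_settings(),
                       n_replications = 500L,
                       pop = population_params()) {
  dep_pairs <- as.matrix(dep_pairs)
  out <- list()
  for (rr in response_rates)
    for (ex in extremes)
      for (i in seq_len(nrow(dep_pairs))) {
        sc <- scenario(pop = pop,
                       miss = missingness_scenario(
                         b_non1 = dep_pairs[i, 1L],
                         b_non2 = dep_pairs[i, 2L],
                         response_rate = rr, extremes_removed = ex),
                       ordinal = ordinal, n = n, methods = methods,
                       mi = mi, n_replications = n_replications)
        out[[sc$id]] <- sc
      }
  out
}

#' Follow-up conditions: 5/2-category and continuous outcomes
#'
#' The follow-up analyses rerun the 50% response-rate conditions with
#' the outcome observed on a 5-point scale, a 2-point scale, and on
#' its continuous scale (linear regression), complete cases only.
#'
#' @inheritParams study_grid
#' @return A named list of [scenario()] objects.
#' @export
followup_grid <- function(dep_pairs = cbind(b_non1 = c(0.3, 0.1, 0.3, 0.0, 0.1, 0.3),
                                            b_non2 = c(0.0, 0.1, 0.1, 0.3, 0.3, 0.3)),
                          n = 1000L, n_replications = 500L,
                          pop = population_params()) {
  specs <- list(ordinal_spec(5L), ordinal_spec(2L),
                ordinal_spec(continuous = TRUE))
  out <- list()
  for (sp in specs) {
    g <- study_grid(dep_pairs = dep_pairs, response_rates = 0.50,
                    ordinal = sp, methods = "CC", n = n,
                    n_replications = n_replications, pop = pop)
    out <- c(out, g)
  }
  out
}

#' Run a scenario grid and write tables, figure data and figures
#'
#' Runs every scenario (failures are logged and skipped), writes the
#' tidy replication-level results, the scenario summaries, a
#' formatted text table mirroring the scenario-by-method layout of the
#' study's result tables, the bias-prevention decomposition, and --
#' when `ggplot2` is available -- bar-chart figures for relative bias,
#' coverage and prevention.
#'
#' @param scenarios List of [scenario()] objects (e.g. [study_grid()]).
#' @param base_seed Master seed.
#' @param out_dir Output directory; created if needed.  `NULL` skips
#'   all file output.
#' @param true_values Named true coefficients.
#' @return (Invisibly) a list with `results` (per-scenario
#'   `scenario_result`s), `summary` (combined summary table) and
#'   `prevention` (see [prevention_table()]).
#' @export
run_grid <- function(scenarios, base_seed = 1L, out_dir = NULL,
                     true_values = c(x1 = 0.20, x2 = 0.30)) {
  results <- list()
  for (sc in scenarios) {
    res <- tryCatch(run_scenario(sc, base_seed = base_seed,
                                 true_values = true_values),
                    error = function(e) {
                      warning(sprintf("scenario '%s' failed: %s",
                                      sc$id, conditionMessage(e)),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(res)) results[[sc$id]] <- res
  }
  summary <- do.call(rbind, c(lapply(results, function(r) {
    s <- r$summary
    s$response_rate <- r$scenario$miss$response_rate
    s$extremes_removed <- r$scenario$miss$extremes_removed
    s$b_non1 <- r$scenario$miss$b_non1
    s$b_non2 <- r$scenario$miss$b_non2
    s
  }), make.row.names = FALSE))
  prevention <- prevention_table(summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fits <- do.call(rbind, c(lapply(results, `[[`, "fits"),
                             make.row.names = FALSE))
    utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (nrow(prevention))
      utils::write.csv(prevention, file.path(out_dir, "prevention.csv"),
                       row.names = FALSE)
    writeLines(format_summary_table(summary),
               file.path(out_dir, "summary_table.txt"))
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      save_plot <- function(p, file)
        tryCatch(ggplot2::ggsave(file.path(out_dir, file), p,
                                 width = 9, height = 5, dpi = 150),
                 error = function(e)
                   warning("could not render ", file, ": ",
                           conditionMessage(e), call. = FALSE))
      save_plot(plot_relative_bias(summary), "relative_bias.png")
      save_plot(plot_coverage(summary), "coverage.png")
      if (nrow(prevention))
        save_plot(plot_prevention(prevention), "prevention.png")
    }
  }
  invisible(list(results = results, summary = summary,
                 prevention = prevention))
}

#' Bias-prevention decomposition across paired conditions
#'
#' Pairs conditions that differ only in whether extreme scorers are
#' totally missing (`R1`) or present but under-represented (`R2`) and
#' computes [prevention_percentage()] for each pair.
#'
#' @param summary Combined summary table from [run_grid()].
#' @return Data frame with one row per response rate x dependency pair
#'   x method x predictor: `R1`, `R2`, `prevented_pct`.
#' @export
prevention_table <- function(summary) {
  need <- c("response_rate", "b_non1", "b_non2", "method", "predictor",
            "extremes_removed", "relative_bias")
  stopifnot(all(need %in% names(summary)))
  rem <- summary[summary$extremes_removed, , drop = FALSE]
  pre <- summary[!summary$extremes_removed, , drop = FALSE]
  if (!nrow(rem) || !nrow(pre)) return(data.frame())
  key <- function(d) paste(d$response_rate, d$b_non1, d$b_non2,
                           d$method, d$predictor, sep = "|")
  i <- match(key(rem), key(pre))
  ok <- !is.na(i)
  rem <- rem[ok, , drop = FALSE]
  out <- rem[c("response_rate", "b_non1", "b_non2", "method",
               "predictor")]
  out$R1 <- rem$relative_bias
  out$R2 <- pre$relative_bias[i[ok]]
  out$prevented_pct <- prevention_percentage(out$R1, out$R2)
  rownames(out) <- NULL
  out
}

#' Format a scenario summary as a fixed-width text table
#'
#' One row per dependency pair and predictor, method columns showing
#' `estimate (SE)` and coverage, mirroring the layout of the study's
#' result tables (estimates and SEs to 2 decimals, coverage to
#' integers).
#'
#' @param summary Combined summary table from [run_grid()].
#' @return Character vector of table lines.
#' @export
format_summary_table <- function(summary) {
  lines <- character()
  for (rr in sort(unique(summary$response_rate), decreasing = TRUE)) {
    for (ex in c(TRUE, FALSE)) {
      sub <- summary[summary$response_rate == rr &
                       summary$extremes_removed == ex, , drop = FALSE]
      if (!nrow(sub)) next
      lines <- c(lines, sprintf(
        "Response rate %.0f%%, extreme scores %s", 100 * rr,
        if (ex) "totally missing" else "present (under-represented)"))
      methods <- unique(sub$method)
      lines <- c(lines, paste0(
        sprintf("%-6s %-6s %-5s", "b_non1", "b_non2", "pred"),
        paste(sprintf("  %-16s", methods), collapse = "")))
      keys <- unique(sub[c("b_non1", "b_non2", "predictor")])
      for (j in seq_len(nrow(keys))) {
        row <- sprintf("%-6.1f %-6.1f %-5s", keys$b_non1[j],
                       keys$b_non2[j], keys$predictor[j])
        for (m in methods) {
          cell <- sub[sub$b_non1 == keys$b_non1[j] &
                        sub$b_non2 == keys$b_non2[j] &
                        sub$predictor == keys$predictor[j] &
                        sub$method == m, , drop = FALSE]
          row <- paste0(row, if (nrow(cell))
            sprintf("  %.2f (%.2f) %3.0f", cell$mean_estimate,
                    cell$mean_se, cell$coverage95)
            else sprintf("  %-16s", "--"))
        }
        lines <- c(lines, row)
      }
      lines <- c(lines, "")
    }
  }
  lines
}
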