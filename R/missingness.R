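#' Specify a selective non-response scenario
#'
#' Non-response is driven by a latent normally distributed liability
#'
#' \deqn{L = b_0 + b_{non1}(x_1 + x_2 + x_3) + b_{non2}\, y + e_L,}
#'
#' where the residual variance of \eqn{e_L} is chosen so that the total
#' variance of `L` equals `var_L` (1.15 by default) in every condition,
#' keeping the dependency coefficients comparable across conditions.
#' Units whose liability exceeds a threshold fail to report the
#' outcome; the threshold is calibrated per sample so that exactly a
#' fraction `1 - response_rate` of the outcome is missing.
#'
#' When `extremes_removed` is `TRUE`, the top `extreme_fraction` (10%
#' by default) of the continuous outcome is additionally forced
#' missing, and the liability cut is re-calibrated so that the total
#' non-response rate still equals `1 - response_rate`.  This contrasts
#' samples in which the highest scorers are merely under-represented
#' with samples from which they are absent entirely.
#'
#' @param b_non1 Dependency of the liability on each predictor (the
#'   same coefficient applies to `x1`, `x2` and `x3`).
#' @param b_non2 Dependency of the liability on the outcome `y`.
#' @param response_rate Target fraction of units with an observed
#'   outcome; strictly between 0 and 1 (the study uses 0.70 and 0.50).
#' @param extremes_removed Force the top `extreme_fraction` of the
#'   outcome to be missing?
#' @param extreme_fraction Fraction of highest outcome scores removed
#'   when `extremes_removed` is `TRUE` (default 0.10).
#' @param var_L Total variance of the liability (default 1.15).
#' @param b0 Liability intercept (default 0; it has no effect on the
#'   rank-based threshold calibration and is kept for completeness).
#'
#' @return An object of class `missingness_scenario`.
#' @seealso [compute_liability()], [apply_missingness()]
#' @export
missingness_scenario <- function(b_non1 = 0, b_non2 = 0,
                                 response_rate = 0.70,
                                 extremes_removed = FALSE,
                                 extreme_fraction = 0.10,
                                 var_L = 1.15, b0 = 0) {
  if (!is.numeric(response_rate) || length(response_rate) != 1L ||
      response_rate <= 0 || response_rate >= 1)
    stop("`response_rate` must lie strictly between 0 and 1",
         call. = FALSE)
  if (var_L <= 0) stop("`var_L` must be positive", call. = FALSE)
  if (extreme_fraction < 0 || extreme_fraction >= 1)
    stop("`extreme_fraction` must lie in [0, 1)", call. = FALSE)
  structure(
    list(b_non1 = b_non1, b_non2 = b_non2,
         response_rate = response_rate,
         extremes_removed = isTRUE(extremes_removed),
         extreme_fraction = extreme_fraction,
         var_L = var_L, b0 = b0),
    class = "missingness_scenario")
}

#' @export
print.missingness_scenario <- function(x, ...) {
  cat("Missingness scenario\n")
  cat(sprintf("  liability    : L = %.2f + %.2f*(x1+x2+x3) + %.2f*y + e_L, Var(L) = %.2f\n",
              x$b0, x$b_non1, x$b_non2, x$var_L))
  cat(sprintf("  response rate: %.0f%%\n", 100 * x$response_rate))
  cat(sprintf("  extremes     : %s\n",
              if (x$extremes_removed)
                sprintf("top %.0f%% of the outcome totally missing",
                        100 * x$extreme_fraction)
              else "under-represented, not removed"))
  invisible(x)
}

#' Variance decomposition of the non-response liability
#'
#' Splits the total liability variance into the part explained by the
#' systematic component \eqn{b_{non1}(x_1+x_2+x_3) + b_{non2} y} --
#' computed from the full theoretical covariance structure of
#' `(x1, x2, x3, y)`, including the y--x covariances -- and the residual
#' variance needed for `Var(L) = var_L`.
#'
#' @param params A [population_params()] object.
#' @param scen A [missingness_scenario()] object.
#' @return A list with `var_systematic` and `var_residual`.
#' @export
liability_variance <- function(params, scen) {
  stopifnot(inherits(scen, "missingness_scenario"))
  mom <- theoretical_moments(params)
  cvec <- c(scen$b_non1, scen$b_non1, scen$b_non1, scen$b_non2)
  var_sys <- drop(t(cvec) %*% mom$Sigma_z %*% cvec)
  var_res <- scen$var_L - var_sys
  if (var_res <= 0)
    stop(sprintf(paste0(
      "liability dependencies b_non1 = %.3g, b_non2 = %.3g explain ",
      "variance %.4g, exceeding the total liability variance %.4g"),
      scen$b_non1, scen$b_non2, var_sys, scen$var_L), call. = FALSE)
  list(var_systematic = var_sys, var_residual = var_res)
}

#' Realized non-response liability for a sample
#'
#' @param sample A [generate_complete_sample()] result (or any data
#'   frame with columns `x1`, `x2`, `x3`, `y_cont` and a `params`
#'   attribute; pass `params` explicitly otherwise).
#' @param scen A [missingness_scenario()] object.
#' @param seed Optional integer seed for the liability noise.
#' @param params Population parameters; defaults to the sample's
#'   `params` attribute.
#' @return Numeric vector of realized liabilities, one per row.
#' @export
compute_liability <- function(sample, scen, seed = NULL, params = NULL) {
  params <- params %||% attr(sample, "params")
  if (is.null(params))
    stop("`sample` carries no population parameters; pass `params`",
         call. = FALSE)
  vr <- liability_variance(params, scen)
  draw <- function() stats::rnorm(nrow(sample), 0, sqrt(vr$var_residual))
  e_L <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  scen$b0 + scen$b_non1 * (sample$x1 + sample$x2 + sample$x3) +
    scen$b_non2 * sample$y_cont + e_L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ceiling of n*(1 - response_rate), guarded against floating-point
# representation of the rate (1 - 0.7 is slightly above 0.3)
target_missing <- function(n, response_rate) {
  as.integer(ceiling(round(n * (1 - response_rate), 6)))
}

new_observed_sample <- function(sample, m, scen, thresholds) {
  out <- as.data.frame(sample)
  out$m <- as.integer(m)
  out$y_obs <- ifelse(m, NA_real_, out$y_cont)
  attr(out, "params") <- attr(sample, "params")
  attr(out, "scenario") <- scen
  attr(out, "thresholds") <- thresholds
  class(out) <- c("observed_sample", "data.frame")
  out
}

#' Impose non-response with extreme scorers under-represented
#'
#' Marks as missing the `ceiling(n * (1 - response_rate))` units with
#' the largest realized liability.  The threshold is therefore the
#' empirical `response_rate` quantile of `L`; in population terms this
#' is 0.52 SD above the mean for a 70% response rate and the mean for a
#' 50% rate.  High outcome scorers become under-represented among
#' responders (when `b_non2 > 0`) but are never excluded outright.
#'
#' @inheritParams compute_liability
#' @return A `data.frame` of class `observed_sample`: the input columns
#'   plus `m` (1 = outcome missing) and `y_obs` (`y_cont` with missing
#'   entries).  The realized liability cut (absolute and in SD units of
#'   `L`) is attached as attribute `"thresholds"`.
#' @export
apply_missingness_underrep <- function(sample, scen, seed = NULL,
                                       params = NULL) {
  stopifnot(inherits(scen, "missingness_scenario"))
  if (scen$extremes_removed)
    stop("scenario has `extremes_removed = TRUE`; use ",
         "`apply_missingness_extremes_removed()`", call. = FALSE)
  L <- compute_liability(sample, scen, seed = seed, params = params)
  n <- nrow(sample)
  n_miss <- target_missing(n, scen$response_rate)
  m <- rank(-L, ties.method = "first") <= n_miss
  cut_L <- if (n_miss > 0) min(L[m]) else Inf
  new_observed_sample(sample, m, scen,
                      list(L_cut = cut_L,
                           L_cut_sd = cut_L / sqrt(scen$var_L)))
}

#' Impose non-response with extreme scorers totally missing
#'
#' First forces the top `extreme_fraction` of the continuous outcome to
#' be missing (in population terms, outcomes more than 1.28 SD above
#' the mean for the default top decile), then marks as missing the
#' remaining units with the largest liability until the total missing
#' count equals `ceiling(n * (1 - response_rate))`.  The liability cut
#' thus adapts to the overlap between the two criteria, which varies
#' with the dependency strengths, so the total non-response rate is hit
#' exactly in every condition.
#'
#' @inheritParams compute_liability
#' @return As [apply_missingness_underrep()]; the `"thresholds"`
#'   attribute additionally records the outcome cut.
#' @export
apply_missingness_extremes_removed <- function(sample, scen, seed = NULL,
                                               params = NULL) {
  stopifnot(inherits(scen, "missingness_scenario"))
  if (!scen$extremes_removed)
    stop("scenario has `extremes_removed = FALSE`; use ",
         "`apply_missingness_underrep()`", call. = FALSE)
  L <- compute_liability(sample, scen, seed = seed, params = params)
  n <- nrow(sample)
  n_miss <- target_missing(n, scen$response_rate)
  n_top <- round(n * scen$extreme_fraction)
  if (n_top > n_miss)
    stop(sprintf(paste0(
      "infeasible calibration: the extreme fraction (%.0f%% = %d units) ",
      "already exceeds the target non-response (%d units)"),
      100 * scen$extreme_fraction, n_top, n_miss), call. = FALSE)
  top_y <- rank(-sample$y_cont, ties.method = "first") <= n_top
  m <- top_y
  L_rest <- L
  L_rest[top_y] <- -Inf   # already missing; exclude from the L criterion
  extra <- rank(-L_rest, ties.method = "first") <= (n_miss - n_top)
  m[extra] <- TRUE
  cut_y <- if (n_top > 0) min(sample$y_cont[top_y]) else Inf
  cut_L <- if (n_miss > n_top) min(L_rest[extra]) else Inf
  new_observed_sample(sample, m, scen,
                      list(y_cut = cut_y, L_cut = cut_L,
                           L_cut_sd = cut_L / sqrt(scen$var_L)))
}

#' Impose non-response on a complete sample
#'
#' Dispatches to [apply_missingness_underrep()] or
#' [apply_missingness_extremes_removed()] according to the scenario's
#' `extremes_removed` flag.
#'
#' @inheritParams compute_liability
#' @return An `observed_sample` data frame; see
#'   [apply_missingness_underrep()].
#' @export
#' @examples
#' s <- generate_complete_sample(population_params(), n = 1000, seed = 1)
#' scen <- missingness_scenario(b_non1 = 0.3, b_non2 = 0.3,
#'                              response_rate = 0.70)
#' obs <- apply_missingness(s, scen, seed = 2)
#' mean(obs$m)   # exactly 0.30
apply_missingness <- function(sample, scen, seed = NULL, params = NULL) {
  if (isTRUE(scen$extremes_removed))
    apply_missingness_extremes_removed(sample, scen, seed, params)
  else
    apply_missingness_underrep(sample, scen, seed, params)
}
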