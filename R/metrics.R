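#' Relative bias of a mean estimate, in percent
#'
#' Defined as `100 * (true_value - mean_estimate) / true_value`:
#' attenuation toward zero of a positive association gives a positive
#' relative bias, matching the sign convention of the study's figures.
#'
#' @param mean_estimate Mean estimate across replications (vectorized).
#' @param true_value True population value; must be nonzero (the null
#'   coefficient of `x3` is never a bias denominator).
#' @return Relative bias in percent.
#' @export
#' @examples
#' relative_bias(0.17, 0.20)  # 15
relative_bias <- function(mean_estimate, true_value) {
  if (any(true_value == 0))
    stop("`true_value` must be nonzero for relative bias", call. = FALSE)
  100 * (true_value - mean_estimate) / true_value
}

#' 95% confidence-interval coverage across replications
#'
#' Percentage of converged replications whose 95% CI contains the true
#' population value.
#'
#' @param fits Either a list of `fit_result` objects or a data frame
#'   with columns `ci_low`, `ci_high` and optionally `converged`
#'   (non-converged rows are excluded).  When a list is given,
#'   `predictor` selects the row of each fit.
#' @param true_value True population value of the coefficient.
#' @param predictor Predictor name used with list input (default
#'   `"x1"`).
#' @return Coverage in percent.
#' @export
coverage95 <- function(fits, true_value, predictor = "x1") {
  if (is.data.frame(fits)) {
    df <- fits
  } else if (is.list(fits) && length(fits) &&
             inherits(fits[[1L]], "fit_result")) {
    df <- do.call(rbind, lapply(fits, as.data.frame))
    df <- df[df$predictor == predictor, , drop = FALSE]
  } else {
    stop("`fits` must be a data frame or a list of fit_result objects",
         call. = FALSE)
  }
  if ("converged" %in% names(df)) df <- df[df$converged, , drop = FALSE]
  df <- df[!is.na(df$ci_low) & !is.na(df$ci_high), , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no converged replications to compute coverage from",
         call. = FALSE)
  100 * mean(df$ci_low <= true_value & true_value <= df$ci_high)
}

#' Percentage of bias preventable by retaining extreme scorers
#'
#' `100 * (R1 - R2) / R1`, where `R1` is the relative bias when the
#' most extreme outcome scores are totally missing from the sample and
#' `R2` the relative bias when they are under-represented but present.
#' Undefined when `R1 = 0` (nothing to prevent); reported as `NA`.
#'
#' @param R1 Relative bias (percent) with extreme scores totally
#'   missing.
#' @param R2 Relative bias (percent) with extreme scores present.
#' @return Percentage of preventable bias (vectorized); `NA` where
#'   `R1 == 0`.
#' @export
#' @examples
#' prevention_percentage(15, 0)   # 100
#' prevention_percentage(20, 10)  # 50
prevention_percentage <- function(R1, R2) {
  out <- 100 * (R1 - R2) / R1
  out[R1 == 0] <- NA_real_
  out
}

#' Aggregate replication-level fits into scenario summaries
#'
#' Computes, per method and predictor, the mean estimate, mean SE,
#' relative bias and 95% coverage over converged replications.
#'
#' @param fits Tidy data frame of replication-level results as produced
#'   by [run_scenario()] (columns `method`, `predictor`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `converged`; extra columns are
#'   ignored).
#' @param true_values Named vector of true coefficients per predictor.
#' @return Data frame with one row per method x predictor:
#'   `mean_estimate`, `mean_se`, `relative_bias`, `coverage95`,
#'   `n_replications`, `n_converged`.
#' @export
summarize_fits <- function(fits, true_values = c(x1 = 0.20, x2 = 0.30)) {
  stopifnot(is.data.frame(fits),
            all(c("method", "predictor", "estimate", "se",
                  "ci_low", "ci_high", "converged") %in% names(fits)))
  keys <- unique(fits[c("method", "predictor")])
  keys <- keys[keys$predictor %in% names(true_values), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- fits[fits$method == keys$method[i] &
                  fits$predictor == keys$predictor[i], , drop = FALSE]
    conv <- sub[sub$converged & !is.na(sub$estimate), , drop = FALSE]
    truth <- true_values[[keys$predictor[i]]]
    data.frame(method = keys$method[i],
               predictor = keys$predictor[i],
               mean_estimate = mean(conv$estimate),
               mean_se = mean(conv$se),
               relative_bias = relative_bias(mean(conv$estimate), truth),
               coverage95 = coverage95(conv, truth),
               n_replications = nrow(sub),
               n_converged = nrow(conv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
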