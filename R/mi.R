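#' Multiple-imputation settings
#'
#' @param m Number of imputed data sets (default 50, the full study
#'   setting; grid runs may scale this down).
#' @param donors Size of the predictive-mean-matching donor pool
#'   (default 5, the usual convention for PMM).
#' @param predictors Covariates of the imputation model (default
#'   `x1`, `x2`, `x3`; the auxiliary `x3` enters here).
#' @return An object of class `mi_settings`.
#' @export
mi_settings <- function(m = 50L, donors = 5L,
                        predictors = c("x1", "x2", "x3")) {
  if (!is.numeric(m) || m < 2) stop("`m` must be >= 2", call. = FALSE)
  if (!is.numeric(donors) || donors < 1)
    stop("`donors` must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), donors = as.integer(donors),
                 predictors = predictors),
            class = "mi_settings")
}

# One predictive-mean-matching draw for the missing entries of y.
# Bayesian linear regression of y on X among observed rows (normal
# inverse-chi-square posterior, small ridge for numerical stability),
# type-1 matching: donors are matched on X beta_hat, missing rows on
# X beta_star, and each missing entry receives the observed value of a
# donor sampled uniformly from the `donors` closest matches.  Imputed
# values are therefore always observed categories.
pmm_impute <- function(y, X, donors) {
  obs <- !is.na(y)
  Xo <- cbind(1, X[obs, , drop = FALSE])
  Xm <- cbind(1, X[!obs, , drop = FALSE])
  yo <- y[obs]
  p <- ncol(Xo)
  S <- crossprod(Xo) + diag(1e-5, p)
  Sinv <- solve(S)
  beta_hat <- drop(Sinv %*% crossprod(Xo, yo))
  res <- yo - drop(Xo %*% beta_hat)
  df <- max(length(yo) - p, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  beta_star <- beta_hat +
    drop(t(chol(Sinv)) %*% stats::rnorm(p)) * sqrt(sigma2)
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(Xm %*% beta_star)
  idx <- vapply(yhat_mis, function(v) {
    d <- abs(yhat_obs - v)
    pool <- order(d, stats::runif(length(d)))[seq_len(min(donors, length(d)))]
    pool[sample.int(length(pool), 1L)]
  }, integer(1L))
  out <- y
  out[!obs] <- yo[idx]
  out
}

#' @rdname fit_probit_cc
#' @param settings An [mi_settings()] object.
#' @param seed Optional integer seed for the imputation draws.
#' @export
fit_probit_mi <- function(data, settings = mi_settings(), seed = NULL,
                          predictors = c("x1", "x2")) {
  stopifnot(inherits(settings, "mi_settings"),
            all(c(settings$predictors, predictors, "y_cat") %in%
                  names(data)))
  y <- data$y_cat
  if (!anyNA(y)) {             # nothing to impute: MI reduces to CC
    out <- fit_probit_cc(data, predictors)
    out$method <- "MI"
    return(out)
  }
  Ximp <- as.matrix(data[settings$predictors])
  Xfit <- as.matrix(data[predictors])
  S <- stats::cov(data[predictors])   # all rows; identical across draws

  run <- function() {
    qs <- matrix(NA_real_, settings$m, length(predictors))
    us <- matrix(NA_real_, settings$m, length(predictors))
    dropped <- 0L
    for (i in seq_len(settings$m)) {
      yc <- pmm_impute(y, Ximp, settings$donors)
      op <- ordered_probit(yc, Xfit)
      if (!op$ok || !op$converged) { dropped <- dropped + 1L; next }
      std <- standardize_probit(op$coef, S, se = sqrt(diag(op$vcov)))
      qs[i, ] <- std$bs
      us[i, ] <- std$se
    }
    list(qs = qs, us = us, dropped = dropped)
  }
  r <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  ok <- stats::complete.cases(r$qs)
  m_eff <- sum(ok)
  if (m_eff < 2L)
    return(failed_fit("MI", predictors, nrow(data),
                      "fewer than 2 converged imputations"))
  qbar <- colMeans(r$qs[ok, , drop = FALSE])
  W <- colMeans(r$us[ok, , drop = FALSE]^2)
  B <- apply(r$qs[ok, , drop = FALSE], 2L, stats::var)
  se <- sqrt(W + (1 + 1 / m_eff) * B)     # Rubin's rules
  est <- data.frame(predictor = predictors, estimate = qbar, se = se,
                    ci_low = qbar - 1.96 * se,
                    ci_high = qbar + 1.96 * se,
                    stringsAsFactors = FALSE)
  notes <- if (r$dropped > 0L)
    sprintf("%d of %d imputations dropped", r$dropped, settings$m)
  else character()
  new_fit_result("MI", est,
                 converged = r$dropped <= 0.2 * settings$m,
                 n_used = nrow(data), notes = notes)
}
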