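#' Population parameters for the data-generating model
#'
#' Defines the population from which complete samples are drawn.  The
#' three predictors `x1`, `x2`, `x3` are multivariate normal with mean 0
#' and common variance `var_x`; the continuous latent health outcome is
#'
#' \deqn{y = b_1 x_1 + b_2 x_2 + b_3 x_3 + e,\qquad e \sim N(0,
#'   \sigma^2_e).}
#'
#' With the defaults (`b_pred1 = 0.20`, `b_pred2 = 0.30`, `b_pred3 = 0`,
#' `var_x = 1.15`, `resid_var_y = 1`) the outcome has theoretical
#' variance \eqn{(0.20^2 + 0.30^2)\cdot 1.15 + 1 = 1.1495}, i.e. all
#' study variables have (nearly) the same total variance of 1.15, which
#' keeps regression coefficients on comparable scales.  `x3` carries no
#' direct effect on the outcome by default; it exists as a predictor of
#' non-response and as an auxiliary variable for the estimators, and is
#' weakly correlated (`rho_x3`, default 0.10) with the risk factor `x1`.
#'
#' @param b_pred1,b_pred2,b_pred3 Regression coefficients of the outcome
#'   on `x1`, `x2`, `x3`.
#' @param var_x Common variance of the three predictors.  Must be > 0.
#' @param resid_var_y Residual variance of the outcome.  Must be > 0.
#' @param rho_x3 Correlation between `x3` and `x1`.  Strictly inside
#'   (-1, 1).
#' @param rho_x12 Correlation between the two risk factors `x1` and
#'   `x2`; 0 (independent) by default.
#'
#' @return An object of class `population_params`.
#' @seealso [generate_complete_sample()], [theoretical_moments()]
#' @export
#' @examples
#' p <- population_params()
#' theoretical_moments(p)$var_y   # 1.1495
population_params <- function(b_pred1 = 0.20, b_pred2 = 0.30,
                              b_pred3 = 0.00, var_x = 1.15,
                              resid_var_y = 1.0, rho_x3 = 0.10,
                              rho_x12 = 0.0) {
  if (!is.numeric(var_x) || length(var_x) != 1L || var_x <= 0)
    stop("`var_x` must be a single positive number", call. = FALSE)
  if (!is.numeric(resid_var_y) || length(resid_var_y) != 1L ||
      resid_var_y <= 0)
    stop("`resid_var_y` must be a single positive number", call. = FALSE)
  if (abs(rho_x3) >= 1 || abs(rho_x12) >= 1)
    stop("correlations must lie strictly between -1 and 1", call. = FALSE)
  p <- structure(
    list(b_pred1 = b_pred1, b_pred2 = b_pred2, b_pred3 = b_pred3,
         var_x = var_x, resid_var_y = resid_var_y,
         rho_x3 = rho_x3, rho_x12 = rho_x12),
    class = "population_params")
  # correlation structure must be a valid covariance matrix
  ev <- eigen(theoretical_moments(p)$Sigma_x, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("predictor correlations do not form a positive-definite ",
         "covariance matrix", call. = FALSE)
  p
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters\n")
  cat(sprintf("  outcome model : y = %.2f*x1 + %.2f*x2 + %.2f*x3 + e, Var(e) = %.2f\n",
              x$b_pred1, x$b_pred2, x$b_pred3, x$resid_var_y))
  cat(sprintf("  Var(x)        : %.4g  (cor(x1,x3) = %.2f, cor(x1,x2) = %.2f)\n",
              x$var_x, x$rho_x3, x$rho_x12))
  cat(sprintf("  Var(y)        : %.4f (theoretical)\n",
              theoretical_moments(x)$var_y))
  invisible(x)
}

#' Theoretical moments implied by population parameters
#'
#' Closed-form covariance structure of `(x1, x2, x3, y)` under the
#' data-generating model.  Used to calibrate liability residual
#' variances and to anchor ordinal thresholds to the population (not
#' per-sample) scale of the outcome.
#'
#' @param params A [population_params()] object.
#' @return A list with elements `Sigma_x` (3x3 predictor covariance),
#'   `beta` (outcome coefficients), `cov_yx` (covariances of y with the
#'   predictors), `var_y`, `sd_y`, and `Sigma_z` (4x4 covariance of
#'   `(x1, x2, x3, y)`).
#' @export
theoretical_moments <- function(params) {
  stopifnot(inherits(params, "population_params"))
  v <- params$var_x
  Sigma_x <- v * matrix(c(1, params$rho_x12, params$rho_x3,
                          params$rho_x12, 1, 0,
                          params$rho_x3, 0, 1), 3L, 3L)
  dimnames(Sigma_x) <- list(c("x1", "x2", "x3"), c("x1", "x2", "x3"))
  beta <- c(x1 = params$b_pred1, x2 = params$b_pred2, x3 = params$b_pred3)
  cov_yx <- drop(Sigma_x %*% beta)
  var_y <- drop(t(beta) %*% Sigma_x %*% beta) + params$resid_var_y
  Sigma_z <- rbind(cbind(Sigma_x, y = cov_yx), y = c(cov_yx, var_y))
  list(Sigma_x = Sigma_x, beta = beta, cov_yx = cov_yx,
       var_y = var_y, sd_y = sqrt(var_y), Sigma_z = Sigma_z)
}

#' Generate one complete sample from the population model
#'
#' Draws `n` units of `(x1, x2, x3)` from the multivariate normal
#' implied by `params` and constructs the continuous latent outcome
#' `y_cont`.  Predictors are drawn with their exact population
#' covariance as distribution parameters; drawn samples are not
#' rescaled, so sample moments fluctuate around the population values
#' as they would in a real survey.
#'
#' @param params A [population_params()] object.
#' @param n Sample size before non-response (default 1000).
#' @param seed Optional integer; when supplied the sample is drawn
#'   under this seed without disturbing the caller's RNG state.  The
#'   same seed and parameters give a bit-identical sample.
#'
#' @return A `data.frame` of class `complete_sample` with columns
#'   `x1`, `x2`, `x3`, `y_cont` and the generating parameters attached
#'   as attribute `"params"`.
#' @export
#' @examples
#' s <- generate_complete_sample(population_params(), n = 500, seed = 1)
#' colMeans(s)
generate_complete_sample <- function(params, n = 1000L, seed = NULL) {
  stopifnot(inherits(params, "population_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2", call. = FALSE)
  n <- as.integer(n)
  draw <- function() {
    mom <- theoretical_moments(params)
    X <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = mom$Sigma_x)
    e <- stats::rnorm(n, 0, sqrt(params$resid_var_y))
    y <- drop(X %*% mom$beta) + e
    data.frame(x1 = X[, 1L], x2 = X[, 2L], x3 = X[, 3L], y_cont = y)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "params") <- params
  class(out) <- c("complete_sample", "data.frame")
  out
}
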