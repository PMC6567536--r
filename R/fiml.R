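# Full-information maximum likelihood with an auxiliary variable.
#
# Joint model for (latent response u*, auxiliary x3) given the risk
# factors (x1, x2):
#
#   u* = b1 x1 + b2 x2 + u,          u ~ N(0, 1)
#   x3 = a0 + a1 x1 + a2 x2 + v,     v ~ N(0, sv^2),  cor(u, v) = r
#
# The ordinal outcome arises by cutting u* at increasing thresholds.
# Rows with an observed outcome contribute f(x3 | x1, x2) times the
# ordinal probit probability conditional on x3 (a normal conditional
# mean shift r*(x3 - mu3)/sv and residual SD sqrt(1 - r^2)); rows with
# a missing outcome contribute only the marginal density of x3.  The
# residual correlation r is how the auxiliary variable carries
# information about the missing outcomes.
#
# Parameter vector (K observed categories):
#   p = (b1, b2, th1, log diff(th), a0, a1, a2, log sv, atanh r)

fiml_nll <- function(x1, x2, x3, k, K) {
  obs <- !is.na(k)
  ko <- k[obs]
  function(p) {
    b1 <- p[1L]; b2 <- p[2L]
    th <- cumsum(c(p[3L], exp(p[seq_len(K - 2L) + 3L])))
    a <- p[(K + 2L):(K + 4L)]
    sv <- exp(p[K + 5L]); r <- tanh(p[K + 6L])
    mu3 <- a[1L] + a[2L] * x1 + a[3L] * x2
    ll <- stats::dnorm(x3, mu3, sv, log = TRUE)
    muc <- (b1 * x1 + b2 * x2 + r * (x3 - mu3) / sv)[obs]
    s <- sqrt(1 - r^2)
    thpad <- c(-Inf, th, Inf)
    pr <- stats::pnorm((thpad[ko + 1L] - muc) / s) -
      stats::pnorm((thpad[ko] - muc) / s)
    ll[obs] <- ll[obs] + log(pmax(pr, 1e-300))
    -sum(ll)
  }
}

#' @rdname fit_probit_cc
#' @param auxiliary Name of the auxiliary-variable column used by the
#'   FIML joint model (default `"x3"`).
#' @param control List of optimizer settings passed to
#'   [stats::nlminb()] for the FIML likelihood.
#' @export
fit_probit_fiml <- function(data, predictors = c("x1", "x2"),
                            auxiliary = "x3",
                            control = list(rel.tol = 1e-10,
                                           iter.max = 500L)) {
  stopifnot(all(c(predictors, auxiliary, "y_cat") %in% names(data)))
  if (length(predictors) != 2L)
    stop("the FIML joint model is parameterized for two risk factors",
         call. = FALSE)
  k <- data$y_cat
  lev <- sort(unique(k[!is.na(k)]))
  if (length(lev) < 2L)
    return(failed_fit("FIML", predictors, nrow(data),
                      "fewer than 2 observed categories"))
  k <- match(k, lev)          # collapse any empty categories
  K <- length(lev)
  x1 <- data[[predictors[1L]]]; x2 <- data[[predictors[2L]]]
  x3 <- data[[auxiliary]]
  nll <- fiml_nll(x1, x2, x3, k, K)

  cc <- ordered_probit(k, cbind(x1 = x1, x2 = x2))
  lm3 <- stats::lm(x3 ~ x1 + x2)
  sig3 <- sqrt(sum(stats::resid(lm3)^2) / max(lm3$df.residual, 1L))
  starts <- list()
  if (cc$ok)
    starts[[1L]] <- c(cc$coef, cc$zeta[1L], log(diff(cc$zeta)),
                      stats::coef(lm3), log(sig3), 0)
  p_cum <- cumsum(prop.table(table(k)))
  zeta0 <- stats::qnorm(p_cum[-K])
  starts[[length(starts) + 1L]] <-
    c(0, 0, zeta0[1L], if (K > 2L) log(diff(zeta0)),
      stats::coef(lm3), log(sig3), 0)

  best <- NULL
  for (p0 in starts) {
    o <- tryCatch(stats::nlminb(p0, nll, control = control),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best))
    return(failed_fit("FIML", predictors, nrow(data),
                      "likelihood optimization failed"))
  r_hat <- tanh(best$par[K + 6L])
  notes <- character()
  if (abs(r_hat) > 0.99)
    notes <- "auxiliary residual correlation at boundary"
  H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
  V <- if (is.null(H)) NULL else tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(diag(V)[1:2] <= 0))
    return(failed_fit("FIML", predictors, nrow(data),
                      "singular Hessian"))
  S <- stats::cov(data[predictors])   # all rows: predictors fully observed
  finish_probit_fit("FIML", best$par[1:2], sqrt(diag(V)[1:2]), S,
                    nrow(data),
                    converged = best$convergence == 0, predictors,
                    notes = notes,
                    raw = list(par = best$par, nll = best$objective,
                               K = K))
}
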