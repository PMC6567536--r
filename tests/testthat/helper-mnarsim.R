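# Shared fixtures, built in code.

default_pop <- population_params()
default_mom <- theoretical_moments(default_pop)

# A small observed sample with the 4-category outcome attached,
# reproducible by seed.
make_obs <- function(n = 800, b_non1 = 0.3, b_non2 = 0.3,
                     response_rate = 0.7, extremes_removed = FALSE,
                     seed = 42, pop = default_pop) {
  smp <- generate_complete_sample(pop, n = n, seed = seed)
  scen <- missingness_scenario(b_non1, b_non2, response_rate,
                               extremes_removed)
  obs <- apply_missingness(smp, scen, seed = seed + 1)
  obs$y_cat <- ordinalize(obs$y_obs, ordinal_spec(4),
                          sd_y = theoretical_moments(pop)$sd_y)
  obs
}

# Independent ordered-probit negative log-likelihood, parameterized
# directly in (beta, increasing thresholds via th1 + exp-increments).
# Used as an optimizer-independent oracle against the package's fits.
oracle_probit_nll <- function(k, X, K) {
  obs <- !is.na(k)
  k <- k[obs]
  X <- X[obs, , drop = FALSE]
  p0 <- ncol(X)
  function(p) {
    beta <- p[seq_len(p0)]
    th <- cumsum(c(p[p0 + 1L], exp(p[(p0 + 2L):(p0 + K - 1L)])))
    eta <- drop(X %*% beta)
    pad <- c(-Inf, th, Inf)
    pr <- pnorm(pad[k + 1L] - eta) - pnorm(pad[k] - eta)
    -sum(log(pmax(pr, 1e-300)))
  }
}

# Multi-start oracle optimum for the ordered probit.
oracle_probit_opt <- function(k, X, K) {
  nll <- oracle_probit_nll(k, X, K)
  tab <- cumsum(prop.table(table(k[!is.na(k)])))
  z0 <- qnorm(tab[-K])
  starts <- list(c(rep(0, ncol(X)), z0[1], if (K > 2) log(diff(z0))),
                 c(rep(0.1, ncol(X)), -1, rep(0, K - 2)))
  best <- NULL
  for (p0 in starts) {
    o <- nlminb(p0, nll, control = list(rel.tol = 1e-12))
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  best
}
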