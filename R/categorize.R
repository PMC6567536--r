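#' Ordinal measurement specification for the health outcome
#'
#' The continuous population outcome is observed through an ordinal
#' scale.  Thresholds are given in SD units of the outcome and anchored
#' to its theoretical population mean and SD (not to post-missingness
#' sample moments).  The presets follow the study design:
#'
#' * 4 categories: cuts at -1, 0, +1 SD,
#' * 5 categories: cuts at -1, -0.5, +0.5, +1 SD,
#' * 2 categories: one cut at the mean.
#'
#' `continuous = TRUE` requests no categorization at all; the outcome
#' is analyzed on its continuous scale (used by the follow-up linear
#' analyses).
#'
#' @param n_categories 2, 4, or 5 (ignored when `thresholds` given).
#' @param thresholds Optional custom cut-points in SD units; strictly
#'   increasing, one fewer than the number of categories.
#' @param continuous Pass the outcome through unchanged?
#' @return An object of class `ordinal_spec`.
#' @export
ordinal_spec <- function(n_categories = 4L, thresholds = NULL,
                         continuous = FALSE) {
  if (isTRUE(continuous))
    return(structure(list(n_categories = NA_integer_,
                          thresholds = NULL, continuous = TRUE),
                     class = "ordinal_spec"))
  if (is.null(thresholds)) {
    thresholds <- switch(as.character(n_categories),
                         "2" = 0,
                         "4" = c(-1, 0, 1),
                         "5" = c(-1, -0.5, 0.5, 1),
                         stop("no preset thresholds for ", n_categories,
                              " categories; supply `thresholds`",
                              call. = FALSE))
  }
  if (any(diff(thresholds) <= 0))
    stop("`thresholds` must be strictly increasing", call. = FALSE)
  structure(list(n_categories = length(thresholds) + 1L,
                 thresholds = as.numeric(thresholds),
                 continuous = FALSE),
            class = "ordinal_spec")
}

#' @export
print.ordinal_spec <- function(x, ...) {
  if (x$continuous) cat("Ordinal spec: continuous pass-through\n")
  else cat(sprintf("Ordinal spec: %d categories, cuts at %s SD\n",
                   x$n_categories,
                   paste(format(x$thresholds), collapse = ", ")))
  invisible(x)
}

#' Convert the continuous outcome to its observed ordinal scale
#'
#' Assigns category \eqn{k} when \eqn{\theta_{k-1} < y \le \theta_k},
#' with \eqn{\theta_0 = -\infty} and \eqn{\theta_K = +\infty}
#' (right-closed intervals: a value exactly one SD below the mean falls
#' in the first category of the 4-point scale).  Thresholds in SD units
#' are converted with the theoretical mean and SD of the outcome.
#' Missing entries stay missing; categorization never creates or
#' removes missingness.
#'
#' @param y Numeric vector, possibly with `NA`s (e.g. `y_obs` from an
#'   observed sample).
#' @param spec An [ordinal_spec()].
#' @param sd_y Theoretical SD of the continuous outcome used to anchor
#'   the thresholds; defaults to the SD implied by `params`.
#' @param mean_y Theoretical mean of the outcome (default 0).
#' @param params Population parameters from which `sd_y` is derived
#'   when not given explicitly (default [population_params()]).
#' @return Integer vector of categories `1..K` (or `y` unchanged for a
#'   continuous spec), `NA` where `y` is `NA`.
#' @export
#' @examples
#' sp <- ordinal_spec(4)
#' ordinalize(c(-1.5, -0.2, 0.4, 1.5) * sqrt(1.1495), sp)  # 1 2 3 4
ordinalize <- function(y, spec, sd_y = NULL, mean_y = 0,
                       params = population_params()) {
  stopifnot(inherits(spec, "ordinal_spec"))
  if (spec$continuous) return(y)
  sd_y <- sd_y %||% theoretical_moments(params)$sd_y
  cuts <- mean_y + spec$thresholds * sd_y
  k <- findInterval(y, cuts, left.open = TRUE) + 1L
  k[is.na(y)] <- NA_integer_
  k
}
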