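# Figure helpers.  Data preparation is plain base R; rendering needs
# ggplot2 (in Suggests) and errors with a clear message without it.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("package 'ggplot2' is required for plotting", call. = FALSE)
}

dep_label <- function(d) {
  factor(sprintf("b1=%.1f\nb2=%.1f", d$b_non1, d$b_non2),
         levels = unique(sprintf("b1=%.1f\nb2=%.1f",
                                 d$b_non1, d$b_non2)))
}

extremes_label <- function(x) {
  factor(ifelse(x, "totally missing", "present"),
         levels = c("present", "totally missing"))
}

#' Bar charts of scenario summaries
#'
#' `plot_relative_bias()` and `plot_coverage()` show, per dependency
#' pair and response rate, solid versus hatched bars for conditions
#' with extreme scorers present versus totally missing (solid/dotted
#' in the original figures).  `plot_prevention()` decomposes the
#' totally-missing bias into a prevented part and a residual part.
#'
#' @param summary Combined summary table from [run_grid()].
#' @param method Estimator to display (default `"CC"`).
#' @return A ggplot object.
#' @export
plot_relative_bias <- function(summary, method = "CC") {
  need_ggplot()
  d <- summary[summary$method == method, , drop = FALSE]
  d$dep <- dep_label(d)
  d$extremes <- extremes_label(d$extremes_removed)
  d$rr <- sprintf("%.0f%% response", 100 * d$response_rate)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dep,
                                  y = .data$relative_bias,
                                  fill = .data$extremes)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(rr ~ predictor) +
    ggplot2::scale_fill_manual(values = c("grey25", "grey75")) +
    ggplot2::labs(x = "dependency of non-response liability",
                  y = "relative bias (%)",
                  fill = "extreme scores",
                  title = sprintf("Relative bias (%s)", method)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_relative_bias
#' @export
plot_coverage <- function(summary, method = "CC") {
  need_ggplot()
  d <- summary[summary$method == method, , drop = FALSE]
  d$dep <- dep_label(d)
  d$extremes <- extremes_label(d$extremes_removed)
  d$rr <- sprintf("%.0f%% response", 100 * d$response_rate)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dep,
                                  y = .data$coverage95,
                                  fill = .data$extremes)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 95, linetype = 2) +
    ggplot2::facet_grid(rr ~ predictor) +
    ggplot2::scale_fill_manual(values = c("grey25", "grey75")) +
    ggplot2::labs(x = "dependency of non-response liability",
                  y = "95% coverage (%)",
                  fill = "extreme scores",
                  title = sprintf("95%% coverage (%s)", method)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_relative_bias
#' @param prevention Output of [prevention_table()].
#' @export
plot_prevention <- function(prevention, method = "CC") {
  need_ggplot()
  d <- prevention[prevention$method == method, , drop = FALSE]
  d$dep <- dep_label(d)
  d$rr <- sprintf("%.0f%% response", 100 * d$response_rate)
  long <- rbind(
    data.frame(d[c("dep", "rr", "predictor")],
               part = "prevented", value = d$R1 - d$R2),
    data.frame(d[c("dep", "rr", "predictor")],
               part = "remaining", value = d$R2))
  long$part <- factor(long$part, levels = c("remaining", "prevented"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dep, y = .data$value,
                                     fill = .data$part)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rr ~ predictor) +
    ggplot2::scale_fill_manual(values = c("grey30", "grey80")) +
    ggplot2::labs(x = "dependency of non-response liability",
                  y = "relative bias (%)", fill = NULL,
                  title = sprintf(
                    "Bias prevented by retaining extreme scorers (%s)",
                    method)) +
    ggplot2::theme_minimal()
}
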