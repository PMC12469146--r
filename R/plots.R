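#' Plot a simulation performance table
#'
#' Dot plot of per-method bias or standard error for sensitivity and
#' specificity, faceted by scenario, from the output of [run_scenario()]
#' or [run_grid()].
#'
#' @param object A `pvb_performance` tibble.
#' @param metric `"bias"` or `"se"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvb_performance <- function(object, metric = c("bias", "se"), ...) {
  metric <- match.arg(metric)
  cols <- paste0(metric, c("_sn", "_sp"))
  long <- object |>
    filter(!is.na(.data$method)) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "term",
                        values_to = "value") |>
    mutate(
      term = ifelse(endsWith(.data$term, "_sn"), "sensitivity", "specificity"),
      scenario = sprintf("p=%.1f, Sn=%.1f, Sp=%.1f, n=%d",
                         .data$p, .data$sn_true, .data$sp_true, .data$n),
      method = factor(.data$method, levels = all_methods())
    )
  pl <- ggplot2::ggplot(long,
                        ggplot2::aes(x = .data$value, y = .data$method,
                                     colour = .data$term)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(
      x = if (metric == "bias") "Bias (mean estimate - truth)" else
        "Standard error across replications",
      y = NULL, colour = NULL
    )
  if (metric == "bias") {
    pl <- pl + ggplot2::geom_vline(xintercept = 0, linetype = 2,
                                   colour = "grey40")
  }
  pl
}

#' Plot clinical analysis results
#'
#' Forest-style plot of per-method point estimates and confidence
#' intervals from [analyze_clinical()].
#'
#' @param results The tibble returned by [analyze_clinical()].
#' @return A ggplot object.
#' @export
plot_clinical <- function(results) {
  stopifnot(all(c("method", "term", "estimate") %in% names(results)))
  res <- filter(results, !is.na(.data$estimate))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$estimate, y = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::facet_wrap(~term) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL)
}
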