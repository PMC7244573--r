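bf_reference_lines <- log10(c(1 / 10000, 1 / 1000, 1 / 100, 1 / 20, 1 / 3,
                              3, 20, 100, 1000))

#' Per-participant log10 Bayes factor chart
#'
#' One bar per participant on the log10 scale, with the conventional
#' evidence reference lines at 1/10000, 1/1000, 1/100, 1/20, 1/3, 3, 20, 100
#' and 1000. Positive bars favour the region (monotone model or constraint
#' validity), negative bars its complement.
#'
#' @param object An `st_gbf` from [grouped_bf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.st_gbf <- function(object, ...) {
  tab <- tidy(object)
  tab$participant <- factor(tab$participant, levels = tab$participant)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$participant, y = .data$log10_bf)) +
    ggplot2::geom_hline(yintercept = bf_reference_lines,
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(
      x = NULL, y = expression(log[10] ~ "Bayes factor"),
      subtitle = sprintf("Grouped BF = %.3g (log10 = %.2f)",
                         object$gbf, object$log10_gbf)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' State-trace plot of observed cell proportions
#'
#' Plots each lag's pooled accuracy proportion against its pooled
#' high-visibility proportion — the state-trace plot whose monotonicity the
#' Bayes factors quantify.
#'
#' @param cells A cells tibble from [to_cells()].
#' @return A ggplot object.
#' @export
plot_state_trace <- function(cells) {
  check_cells(cells)
  pooled <- cells |>
    group_by(.data$measure, .data$lag) |>
    summarise(p = sum(.data$successes) / sum(.data$trials), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "p")
  measures <- setdiff(names(pooled), "lag")
  ggplot2::ggplot(pooled, ggplot2::aes(x = .data[[measures[1]]],
                                       y = .data[[measures[2]]])) +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$lag), vjust = -0.8) +
    ggplot2::labs(x = measures[1], y = measures[2]) +
    ggplot2::theme_minimal()
}

#' Per-lag behaviour and virtual P3 plots for a simulated experiment
#'
#' `autoplot()` on a `sese_experiment` shows T2|T1 accuracy, the
#' high-visibility proportion and (rescaled) mean visibility by lag;
#' `plot_virtual_erp()` overlays the condition-averaged gated virtual P3
#' traces by lag and visibility bin.
#'
#' @param object A `sese_experiment` from [run_sese_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sese_experiment <- function(object, ...) {
  long <- object$summary |>
    mutate(mean_visibility_scaled = (.data$mean_visibility - 1) / 5) |>
    select("lag", "t2_given_t1_acc", "p_high_vis", "mean_visibility_scaled") |>
    tidyr::pivot_longer(-"lag", names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag, y = .data$value,
                                     colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$lag)) +
    ggplot2::labs(x = "Lag", y = "Proportion / scaled rating", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sese_experiment
#' @param x A `sese_experiment`.
#' @export
plot_virtual_erp <- function(x) {
  stopifnot(inherits(x, "sese_experiment"))
  ggplot2::ggplot(x$erp, ggplot2::aes(x = .data$time_ms, y = .data$amplitude,
                                      colour = .data$visibility_bin)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~lag, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (ms)", y = "Gated grand trace",
                  colour = "T2 visibility") +
    ggplot2::theme_minimal()
}
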