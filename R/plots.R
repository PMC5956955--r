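#' Plot standardized errors across simulation scenarios
#'
#' Box plots of standardized rate errors per scenario, faceted by
#' estimation method, with the zero line (exact recovery) marked — the
#' standard at-a-glance view of a scenario grid's accuracy.
#'
#' @param results Results tibble from [run_scenario_grid()].
#' @return A ggplot object.
#' @export
plot_standardized_errors <- function(results) {
  ggplot2::ggplot(
    results[!is.na(results$std_error), ],
    ggplot2::aes(
      x = interaction(.data$variance_fraction, .data$clustering, sep = " / "),
      y = .data$std_error,
      fill = factor(.data$mean_rate)
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~method, ncol = 1) +
    ggplot2::labs(
      x = "variance fraction / clustering",
      y = "standardized error (est - true) / true",
      fill = "mean rate (subs/site/year)"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_standardized_errors Root-to-tip regression scatter for
#'   a `rate_estimate` that carries per-tip data (distance vs age, with the
#'   fitted line).
#' @param object A `rate_estimate` from [rtt_regression()].
#' @param ... Unused.
#' @method autoplot rate_estimate
#' @export
autoplot.rate_estimate <- function(object, ...) {
  if (is.null(object$data)) {
    rlang::abort("this rate_estimate carries no per-tip regression data.")
  }
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = -.data$age_years_bp, y = .data$distance)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "sampling time (years, 0 = present)",
      y = "root-to-tip distance (subs/site)",
      title = sprintf("RTT regression: rate = %.3g subs/site/year, R2 = %.3f",
                      object$rate, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_standardized_errors Null distribution of the
#'   phylo-temporal clustering statistic with the observed value marked.
#' @method autoplot ptc_test
#' @export
autoplot.ptc_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$perm_rho)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$rho, colour = "firebrick") +
    ggplot2::labs(
      x = "permutation null of rho",
      title = sprintf("phylo-temporal clustering: rho = %.3f, P = %.3g",
                      object$rho, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
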