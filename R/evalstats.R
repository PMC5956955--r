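#' Standardized error of a rate estimate
#'
#' `(estimate - true_rate) / true_rate`: 0 is exact recovery, 1 is a 100%
#' overestimate, -1 the floor for non-negative estimates.
#'
#' @param estimate Estimated rate(s), subs/site/year (vectorised).
#' @param true_rate True simulated rate (> 0), recycled.
#' @return Dimensionless numeric vector.
#' @export
standardized_error <- function(estimate, true_rate) {
  if (any(true_rate <= 0)) rlang::abort("`true_rate` must be positive.")
  (estimate - true_rate) / true_rate
}

#' One-sample Wilcoxon test of standardized errors against zero
#'
#' Two-sided Wilcoxon signed-rank test of whether the distribution of
#' errors is centred away from zero (exact distribution for small,
#' tie-free samples, as in [stats::wilcox.test()]).
#'
#' @param errors Numeric vector; at least one nonzero value.
#' @return A tibble with `statistic` (V), `p_value`, `n` (nonzero count).
#' @export
wilcoxon_vs_zero <- function(errors) {
  nz <- errors[errors != 0]
  if (length(nz) == 0) rlang::abort("all errors are zero: test degenerate.")
  ht <- stats::wilcox.test(errors, mu = 0, alternative = "two.sided")
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n = length(nz))
}

#' Kruskal-Wallis test of standardized errors across scenarios
#'
#' Rank-based one-way analysis of variance of the per-replicate
#' standardized errors across the scenario groups of a results table, for
#' one estimation method. Degrees of freedom are the number of scenario
#' groups minus one (11 for the full 12-scenario grid).
#'
#' @param results Results tibble from [run_scenario_grid()] (needs columns
#'   `scenario_id`, `method`, `std_error`).
#' @param method Method tag to subset on (`"rtt"` or `"lsd"`).
#' @return A tibble with `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
kruskal_wallis_errors <- function(results, method) {
  sub <- results[results$method == method & !is.na(results$std_error), ]
  groups <- unique(sub$scenario_id)
  if (length(groups) < 2) {
    rlang::abort("at least 2 scenario groups are required.")
  }
  ht <- stats::kruskal.test(sub$std_error, factor(sub$scenario_id))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 n_groups = length(groups))
}

#' Pairwise Mann-Whitney-Wilcoxon tests between scenarios
#'
#' All pairwise two-sided rank-sum tests of standardized errors between
#' scenario groups for one method, with Holm correction by default.
#'
#' @inheritParams kruskal_wallis_errors
#' @param correction `"holm"` (default) or `"none"`.
#' @return A symmetric matrix of P-values with unit diagonal, rows and
#'   columns named by scenario id.
#' @export
pairwise_mwu <- function(results, method, correction = c("holm", "none")) {
  correction <- match.arg(correction)
  sub <- results[results$method == method & !is.na(results$std_error), ]
  groups <- sort(unique(sub$scenario_id))
  if (length(groups) < 2) rlang::abort("at least 2 groups are required.")
  vals <- split(sub$std_error, sub$scenario_id)
  if (any(lengths(vals) == 0)) rlang::abort("empty scenario group.")
  pairs <- utils::combn(groups, 2)
  raw <- apply(pairs, 2, function(gp) {
    suppressWarnings(
      stats::wilcox.test(vals[[gp[1]]], vals[[gp[2]]],
                         alternative = "two.sided")$p.value
    )
  })
  adj <- if (correction == "holm") stats::p.adjust(raw, "holm") else raw
  m <- matrix(1, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (k in seq_len(ncol(pairs))) {
    m[pairs[1, k], pairs[2, k]] <- adj[k]
    m[pairs[2, k], pairs[1, k]] <- adj[k]
  }
  m
}

#' Proportion of rate estimates above the true rate
#'
#' Fraction of replicates in each scenario-method cell whose estimate
#' exceeds the simulated rate (0.5 for an unbiased, symmetric estimator).
#'
#' @inheritParams kruskal_wallis_errors
#' @param scenario,method Optional filters (scenario id / method tag).
#' @return A tibble with `scenario_id`, `method`, `n`, `prop_above`.
#' @export
proportion_above_true <- function(results, scenario = NULL, method = NULL) {
  sub <- results[!is.na(results$estimate), ]
  if (!is.null(scenario)) sub <- sub[sub$scenario_id %in% scenario, ]
  if (!is.null(method)) sub <- sub[sub$method %in% method, ]
  if (nrow(sub) == 0) rlang::abort("no records in the requested cell.")
  dplyr::summarise(
    dplyr::group_by(sub, .data$scenario_id, .data$method),
    n = dplyr::n(),
    prop_above = mean(.data$estimate > .data$true_rate),
    .groups = "drop"
  )
}

#' Interval width relative to the true rate
#'
#' `(upper - lower) / true_rate`, the uncertainty measure used to compare
#' interval widths across simulation conditions.
#'
#' @param estimate A [rate_estimate()] carrying an interval.
#' @param true_rate True simulated rate (> 0).
#' @return Dimensionless scalar.
#' @export
interval_width_ratio <- function(estimate, true_rate) {
  if (!inherits(estimate, "rate_estimate") || is.null(estimate$interval)) {
    rlang::abort("`estimate` must be a rate_estimate with an interval.")
  }
  if (true_rate <= 0) rlang::abort("`true_rate` must be positive.")
  unname(diff(estimate$interval)) / true_rate
}

#' Correlation between stemminess and absolute standardized error
#'
#' Pearson correlation (with its two-sided P-value) between per-replicate
#' phylogram stemminess and the magnitude of the standardized rate error,
#' within an optional scenario/method cell.
#'
#' @inheritParams proportion_above_true
#' @return A tibble with `r`, `p_value`, `n`.
#' @export
stemminess_error_correlation <- function(results, scenario = NULL,
                                         method = NULL) {
  sub <- results
  if (!is.null(scenario)) sub <- sub[sub$scenario_id %in% scenario, ]
  if (!is.null(method)) sub <- sub[sub$method %in% method, ]
  sub <- sub[!is.na(sub$std_error) & !is.na(sub$stemminess), ]
  if (nrow(sub) < 3) rlang::abort("at least 3 records are required.")
  if (stats::sd(sub$stemminess) == 0 || stats::sd(abs(sub$std_error)) == 0) {
    rlang::abort("zero variance: correlation degenerate.")
  }
  ht <- stats::cor.test(sub$stemminess, abs(sub$std_error))
  tibble::tibble(r = unname(ht$estimate), p_value = ht$p.value,
                 n = nrow(sub))
}

#' Congruence between two sets of paired rate estimates
#'
#' For paired estimates from two methods: the proportional difference of
#' each pair, `(y - x) / x`, and the bias, the fraction of pairs in which
#' `x` exceeds `y`. Pairs with a zero `x` estimate are excluded with a
#' warning.
#'
#' @param estimates_x,estimates_y Equal-length numeric vectors.
#' @return A list with `prop_diff` (per-pair vector), `bias` (scalar) and
#'   `n_excluded`.
#' @export
compare_methods <- function(estimates_x, estimates_y) {
  if (length(estimates_x) != length(estimates_y)) {
    rlang::abort("estimate vectors must have equal length.")
  }
  keep <- estimates_x != 0 & !is.na(estimates_x) & !is.na(estimates_y)
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    rlang::warn(sprintf("%d pair(s) with zero or missing x estimate excluded.",
                        n_excl))
  }
  x <- estimates_x[keep]
  y <- estimates_y[keep]
  list(prop_diff = (y - x) / x, bias = mean(x > y), n_excluded = n_excl)
}
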