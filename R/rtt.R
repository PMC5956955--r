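#' Rate-estimate records
#'
#' Container for a method-tagged substitution-rate estimate with optional
#' bootstrap interval and ancillary statistics. Use [tidy()] / [glance()]
#' to get tibble views.
#'
#' @param method `"rtt"` or `"lsd"`.
#' @param rate Point estimate (subs/site/year).
#' @param tmrca_age Inferred age of the root (years BP), if any.
#' @param rss Residual sum of squares (RTT) or minimised weighted objective
#'   (LSD).
#' @param r_squared Regression R-squared (RTT only).
#' @param interval Optional numeric `c(lower, upper)`.
#' @param level Interval level in (0, 1), when `interval` is present.
#' @param boot_rates Optional vector of bootstrap replicate rates.
#' @param data Optional tibble of the per-tip regression data.
#' @return An object of class `rate_estimate`.
#' @export
rate_estimate <- function(method, rate, tmrca_age = NA_real_,
                          rss = NA_real_, r_squared = NA_real_,
                          interval = NULL, level = NULL,
                          boot_rates = NULL, data = NULL) {
  method <- match.arg(method, c("rtt", "lsd"))
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2, interval[1] <= interval[2])
    if (is.null(level) || level <= 0 || level >= 1) {
      rlang::abort("`level` must lie in (0, 1) when an interval is given.")
    }
  }
  structure(
    list(method = method, rate = rate, tmrca_age = tmrca_age, rss = rss,
         r_squared = r_squared, interval = interval, level = level,
         boot_rates = boot_rates, data = data),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> method = %s, rate = %.6g subs/site/year\n",
              x$method, x$rate))
  if (!is.null(x$interval)) {
    cat(sprintf("  %g%% bootstrap interval: [%.6g, %.6g]\n",
                100 * x$level, x$interval[1], x$interval[2]))
  }
  if (is.finite(x$r_squared)) cat(sprintf("  R-squared: %.4f\n", x$r_squared))
  if (is.finite(x$tmrca_age)) {
    cat(sprintf("  inferred TMRCA: %.6g years BP\n", x$tmrca_age))
  }
  invisible(x)
}

#' Root-to-tip regression rate estimate
#'
#' Ordinary least squares of root-to-tip distance (subs/site) on forward
#' sampling time (minus age): the slope estimates the substitution rate,
#' and the time at which the fitted line crosses zero distance estimates
#' the TMRCA. A negative slope is returned as-is, with a warning, since
#' absence of a positive slope is itself diagnostic of missing temporal
#' signal.
#'
#' @param tree A rooted `phylo` phylogram.
#' @param dates Tip-date tibble with at least two distinct ages.
#' @return A [rate_estimate()] with `r_squared`, `tmrca_age`, `rss`, and
#'   the per-tip regression `data`.
#' @export
rtt_regression <- function(tree, dates) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) rlang::abort("tree has no branch lengths.")
  if (!ape::is.rooted(tree)) rlang::abort("`tree` must be rooted.")
  dates <- tip_dates(dates)
  n <- ape::Ntip(tree)
  ages <- date_vector(dates, tree$tip.label)
  if (length(unique(ages)) < 2) {
    rlang::abort("all tip dates are equal: no temporal spread to regress on.")
  }
  dist_rt <- ape::node.depth.edgelength(tree)[seq_len(n)]
  x <- -ages
  fit <- stats::lm(dist_rt ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0) {
    rlang::warn("root-to-tip regression failed to yield a positive rate estimate.")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((dist_rt - mean(dist_rt))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  tmrca <- if (slope != 0) intercept / slope else NA_real_
  rate_estimate(
    method = "rtt", rate = slope, tmrca_age = tmrca, rss = ss_res,
    r_squared = r2,
    data = tibble::tibble(name = tree$tip.label, age_years_bp = unname(ages),
                          distance = dist_rt)
  )
}
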