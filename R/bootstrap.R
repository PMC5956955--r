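#' Bootstrap interval for a substitution-rate estimate
#'
#' Nonparametric bootstrap over alignment columns: each replicate resamples
#' columns with replacement, re-infers the phylogram, re-places the root,
#' and re-runs the chosen estimator; the interval is the percentile
#' interval of the replicate rates at the requested level, reported around
#' the original-data point estimate.
#'
#' @param aln A `DNAbin` alignment matrix.
#' @param dates Tip-date tibble.
#' @param method `"rtt"` or `"lsd"`.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param level Interval level in (0, 1).
#' @param seed Integer seed.
#' @param tree Optional pre-inferred phylogram for the point estimate (the
#'   bootstrap replicates always re-infer); inferred from `aln` when
#'   omitted.
#' @param dist_model Distance model for [infer_phylogram()].
#' @param site_count,variance_offset_c Passed to [lsd_estimate()] when
#'   `method = "lsd"`; `site_count` defaults to the alignment width.
#' @return A [rate_estimate()] carrying `interval`, `level` and the
#'   replicate rates (`boot_rates`).
#' @export
bootstrap_interval <- function(aln, dates, method = c("rtt", "lsd"),
                               n_boot = 100L, level = 0.95, seed = 1L,
                               tree = NULL, dist_model = "TN93",
                               site_count = NULL, variance_offset_c = 10) {
  method <- match.arg(method)
  if (n_boot < 2) rlang::abort("`n_boot` must be >= 2.")
  if (level <= 0 || level >= 1) rlang::abort("`level` must lie in (0, 1).")
  dates <- tip_dates(dates)
  if (is.null(site_count)) site_count <- ncol(aln)

  estimate_once <- function(a, phy = NULL) {
    if (is.null(phy)) phy <- infer_phylogram(a, dist_model)
    rooted <- find_best_root(phy, dates)
    if (method == "rtt") {
      rtt_regression(rooted, dates)
    } else {
      lsd_estimate(rooted, dates, site_count = site_count,
                   variance_offset_c = variance_offset_c)$estimate
    }
  }

  point <- suppressWarnings(estimate_once(aln, tree))
  boot_rates <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      tryCatch(
        suppressWarnings(estimate_once(aln[, cols, drop = FALSE])$rate),
        error = function(e) NA_real_
      )
    }, numeric(1))
  })
  ok <- boot_rates[!is.na(boot_rates)]
  if (length(ok) < n_boot / 2) {
    rlang::abort("estimator failed in more than half of the bootstrap replicates.")
  }
  qs <- stats::quantile(ok, probs = c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  rate_estimate(
    method = method, rate = point$rate, tmrca_age = point$tmrca_age,
    rss = point$rss, r_squared = point$r_squared,
    interval = qs, level = level, boot_rates = boot_rates, data = point$data
  )
}
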