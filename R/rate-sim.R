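#' Assign branch rates under a white-noise relaxed clock
#'
#' Draws an independent substitution rate for every branch of a genealogy.
#' Under the default white-noise parameterisation the rate variance on a
#' branch of duration `d` (years) is `v * mu / (d * L)` with `L` the
#' alignment length, so that the expected substitution count
#' `n = r * d * L` has `Var(n) = v * E[n]` — the branch-length-inverse
#' variance scaling characteristic of a white-noise clock, with `v` the
#' variance expressed as a fraction of the expected number of
#' substitutions. The alternative `mode = "rate_cv"` keeps the rate
#' coefficient of variation constant across branches
#' (`Var(r) = v * mu^2`). Rates are Gamma-distributed (matching the mean
#' and variance exactly, support strictly positive); `family = "lognormal"`
#' uses a lognormal with the same two moments. `variance_fraction = 0`
#' returns the strict-clock rate `mu` on every branch.
#'
#' @param tree A [time_tree()].
#' @param mean_rate Mean substitution rate `mu` (subs/site/year, > 0).
#' @param variance_fraction Variance fraction `v` (>= 0).
#' @param seq_length Alignment length `L` (nt) entering the white-noise
#'   variance calibration.
#' @param seed Integer seed.
#' @param mode `"white_noise"` (default) or `"rate_cv"`.
#' @param family `"gamma"` (default) or `"lognormal"`.
#' @return A tibble with one row per branch: `node` (ape child-node id
#'   keying the branch), `duration` (years), `rate` (subs/site/year).
#' @export
assign_branch_rates <- function(tree, mean_rate, variance_fraction,
                                seq_length = 15000, seed = 1L,
                                mode = c("white_noise", "rate_cv"),
                                family = c("gamma", "lognormal")) {
  stopifnot(inherits(tree, "time_tree"))
  mode <- match.arg(mode)
  family <- match.arg(family)
  if (mean_rate <= 0) rlang::abort("`mean_rate` must be positive.")
  if (variance_fraction < 0) rlang::abort("`variance_fraction` must be >= 0.")
  if (seq_length < 1) rlang::abort("`seq_length` must be >= 1.")
  phy <- tree$phy
  dur <- tree$ages[phy$edge[, 1]] - tree$ages[phy$edge[, 2]]
  if (any(dur <= 0)) rlang::abort("branch durations must be positive.")
  rate <- if (variance_fraction == 0) {
    rep(mean_rate, length(dur))
  } else {
    v <- switch(mode,
      white_noise = variance_fraction * mean_rate / (dur * seq_length),
      rate_cv = rep(variance_fraction * mean_rate^2, length(dur))
    )
    withr_seed(seed, draw_positive(length(dur), mean_rate, v, family))
  }
  tibble::tibble(node = phy$edge[, 2], duration = dur, rate = rate)
}

draw_positive <- function(n, mean, var, family) {
  if (family == "gamma") {
    shape <- mean^2 / var
    stats::rgamma(n, shape = shape, rate = shape / mean)
  } else {
    sdlog <- sqrt(log1p(var / mean^2))
    stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  }
}

#' Convert a genealogy plus branch rates into a phylogram
#'
#' Multiplies each branch duration (years) by its assigned rate
#' (subs/site/year) to give branch lengths in expected substitutions per
#' site, preserving the topology.
#'
#' @param tree A [time_tree()].
#' @param rates Branch-rate tibble from [assign_branch_rates()], keyed by
#'   child node.
#' @return A `phylo` with branch lengths in subs/site.
#' @export
to_phylogram <- function(tree, rates) {
  stopifnot(inherits(tree, "time_tree"))
  phy <- tree$phy
  idx <- match(phy$edge[, 2], rates$node)
  if (anyNA(idx)) {
    rlang::abort("`rates` is missing entries for some branches.")
  }
  dur <- tree$ages[phy$edge[, 1]] - tree$ages[phy$edge[, 2]]
  phy$edge.length <- rates$rate[idx] * dur
  phy
}
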