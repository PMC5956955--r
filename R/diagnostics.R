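#' Phylo-temporal clustering permutation test
#'
#' Measures whether similarly aged samples are phylogenetic neighbours —
#' a sampling structure that erodes the effective calibrating information
#' in tip-dated data. For every pair of tips the topological distance is
#' the number of edges on the path between them and the temporal distance
#' is the absolute difference in sampling ages; the statistic is Pearson's
#' correlation `rho` over all pairs. The null distribution is built by
#' permuting the ages across tips (`n_perm` label permutations, preserving
#' the multiset of ages) and the P-value uses the add-one correction
#' `P = (1 + #{|rho_perm| >= |rho_obs|}) / (1 + n_perm)` (two-sided by
#' default).
#'
#' @param tree A `phylo` (branch lengths ignored; topology only).
#' @param dates Tip-date tibble with at least two distinct ages.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   clustering only).
#' @return An object of class `ptc_test` with fields `rho`, `p_value`,
#'   `n_perm`, `perm_rho`.
#' @export
phylo_temporal_clustering <- function(tree, dates, n_perm = 1000L, seed = 1L,
                                      alternative = c("two.sided", "greater")) {
  stopifnot(inherits(tree, "phylo"))
  alternative <- match.arg(alternative)
  dates <- tip_dates(dates)
  n <- ape::Ntip(tree)
  if (n < 3) rlang::abort("at least 3 tips are required.")
  if (n_perm < 1) rlang::abort("`n_perm` must be >= 1.")
  ages <- unname(date_vector(dates, tree$tip.label))
  if (length(unique(ages)) < 2) {
    rlang::abort("all ages equal: clustering statistic undefined.")
  }
  topo <- tree
  topo$edge.length <- rep(1, nrow(topo$edge))
  ut <- upper.tri(matrix(0, n, n))
  d_topo <- ape::dist.nodes(topo)[seq_len(n), seq_len(n)][ut]
  age_diff <- function(a) abs(outer(a, a, "-"))[ut]
  rho_obs <- stats::cor(d_topo, age_diff(ages))
  perm_rho <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stats::cor(d_topo, age_diff(ages[sample.int(n)]))
    }, numeric(1))
  })
  extreme <- if (alternative == "two.sided") {
    abs(perm_rho) >= abs(rho_obs) - 1e-15
  } else {
    perm_rho >= rho_obs - 1e-15
  }
  structure(
    list(rho = rho_obs, p_value = (1 + sum(extreme)) / (1 + n_perm),
         n_perm = as.integer(n_perm), perm_rho = perm_rho,
         alternative = alternative),
    class = "ptc_test"
  )
}

#' @export
print.ptc_test <- function(x, ...) {
  cat(sprintf(
    "<ptc_test> rho = %.4f, P = %.4g (%d permutations, %s)\n",
    x$rho, x$p_value, x$n_perm, x$alternative
  ))
  invisible(x)
}

#' Stemminess of a phylogram
#'
#' Proportion of the total tree length contributed by internal
#' (non-pendant) branches. Trees with high stemminess have short terminal
#' branches and carry less calibrating information per tip.
#'
#' @param tree A `phylo` with branch lengths.
#' @return A proportion in \[0, 1\].
#' @export
stemminess <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) rlang::abort("tree has no branch lengths.")
  total <- sum(tree$edge.length)
  if (total <= 0) rlang::abort("total tree length is zero: stemminess undefined.")
  internal <- tree$edge[, 2] > ape::Ntip(tree)
  sum(tree$edge.length[internal]) / total
}

#' Date-randomization test (DRT)
#'
#' Tests for temporal signal by comparing the rate estimated with the true
#' sampling dates against rates estimated after randomly permuting the
#' dates across tips. The original estimate and each of the `n_reps`
#' date-randomized estimates carry a bootstrap interval
#' ([bootstrap_interval()]). Two pass criteria are evaluated: CR1 — the
#' original point estimate lies outside the interval of every randomized
#' replicate; CR2 (stricter) — the original interval is disjoint from
#' every randomized replicate's interval. CR2 implies CR1.
#'
#' @param aln A `DNAbin` alignment matrix.
#' @param tree Pre-inferred phylogram for the point estimates (bootstrap
#'   replicates re-infer from resampled columns); inferred from `aln` when
#'   `NULL`.
#' @param dates Tip-date tibble.
#' @param method `"rtt"` or `"lsd"`.
#' @param n_reps Number of date-randomized replicates (default 20).
#' @param level Interval level (default 0.95).
#' @param n_boot Bootstrap replicates per interval.
#' @param seed Integer seed (controls both the date permutations and the
#'   bootstrap resampling).
#' @param dist_model Distance model for re-inference.
#' @return An object of class `drt_result`: the original [rate_estimate()],
#'   the list of replicate estimates, and logical `cr1` / `cr2` flags.
#' @export
date_randomization_test <- function(aln, tree = NULL, dates,
                                    method = c("rtt", "lsd"),
                                    n_reps = 20L, level = 0.95,
                                    n_boot = 100L, seed = 1L,
                                    dist_model = "TN93") {
  method <- match.arg(method)
  if (n_reps < 1) rlang::abort("`n_reps` must be >= 1.")
  dates <- tip_dates(dates)
  if (is.null(tree)) tree <- infer_phylogram(aln, dist_model)

  original <- bootstrap_interval(aln, dates, method, n_boot = n_boot,
                                 level = level, seed = seed, tree = tree,
                                 dist_model = dist_model)
  perms <- withr_seed(seed, {
    purrr::map(seq_len(n_reps), function(i) sample.int(nrow(dates)))
  })
  replicates <- purrr::imap(perms, function(p, i) {
    d_perm <- dates
    d_perm$age_years_bp <- dates$age_years_bp[p]
    bootstrap_interval(aln, d_perm, method, n_boot = n_boot, level = level,
                       seed = seed + i, tree = tree, dist_model = dist_model)
  })
  cr <- drt_criteria(original, replicates)
  structure(
    list(original = original, replicates = replicates,
         cr1 = cr$cr1, cr2 = cr$cr2, n_reps = as.integer(n_reps),
         level = level, method = method),
    class = "drt_result"
  )
}

# CR1: original point outside every replicate interval;
# CR2: original interval disjoint from every replicate interval
drt_criteria <- function(original, replicates) {
  outside <- vapply(replicates, function(r) {
    original$rate < r$interval[1] || original$rate > r$interval[2]
  }, logical(1))
  disjoint <- vapply(replicates, function(r) {
    original$interval[2] < r$interval[1] || original$interval[1] > r$interval[2]
  }, logical(1))
  list(cr1 = all(outside), cr2 = all(disjoint))
}

#' @export
print.drt_result <- function(x, ...) {
  cat(sprintf(
    "<drt_result> method = %s, original rate = %.6g, %d date-randomized replicates\n",
    x$method, x$original$rate, x$n_reps
  ))
  cat(sprintf("  CR1 (point outside all intervals): %s\n",
              ifelse(x$cr1, "pass", "fail")))
  cat(sprintf("  CR2 (intervals all disjoint):      %s\n",
              ifelse(x$cr2, "pass", "fail")))
  invisible(x)
}
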