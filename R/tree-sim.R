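#' Simulate a serial (heterochronous) coalescent genealogy
#'
#' Runs the constant-size coalescent backward in time with lineages entering
#' at their sampling ages: while `k >= 2` lineages are active the waiting
#' time to the next coalescence is Exponential with rate
#' `k (k - 1) / (2 N)`, truncated at the next tip-entry epoch, and the pair
#' to merge is chosen uniformly. `N` (`effective_size`) is the coalescent
#' time-scale parameter in years, so for two contemporaneous tips the TMRCA
#' is Exponential with mean `N`.
#'
#' @param dates Tip-date tibble (see [tip_dates()]).
#' @param effective_size Coalescent time-scale parameter `N`, in years (> 0).
#' @param seed Integer seed.
#' @return A [time_tree()].
#' @examples
#' d <- simulate_tip_ages(10, 0.5, 50000, seed = 1)
#' simulate_serial_coalescent(d, effective_size = 250000, seed = 2)
#' @export
simulate_serial_coalescent <- function(dates, effective_size = 250000,
                                       seed = 1L) {
  dates <- tip_dates(dates)
  if (effective_size <= 0) rlang::abort("`effective_size` must be positive.")
  withr_seed(seed, {
    lineages <- purrr::map2(dates$name, dates$age_years_bp, lineage_tip)
    root <- serial_coalescent_core(lineages, effective_size)
    record_to_time_tree(root, dates)
  })
}

# core backward-in-time pass over a list of lineage records (each carries
# its own entry age); returns the root record
serial_coalescent_core <- function(lineages, effective_size) {
  if (length(lineages) < 2) {
    rlang::abort("at least 2 lineages are required.")
  }
  entry_age <- vapply(lineages, function(l) l$age, numeric(1))
  ord <- order(entry_age)
  pending <- lineages[ord]
  pending_age <- entry_age[ord]

  time <- pending_age[1]
  active <- list()
  repeat {
    # activate everything that has entered by `time`
    while (length(pending_age) > 0 && pending_age[1] <= time) {
      active[[length(active) + 1L]] <- pending[[1]]
      pending <- pending[-1]
      pending_age <- pending_age[-1]
    }
    k <- length(active)
    if (k <= 1 && length(pending_age) == 0) break
    next_entry <- if (length(pending_age) > 0) pending_age[1] else Inf
    if (k < 2) {
      time <- next_entry
      next
    }
    wait <- stats::rexp(1, rate = k * (k - 1) / (2 * effective_size))
    if (time + wait < next_entry) {
      time <- time + wait
      pair <- sample.int(k, 2L)
      merged <- lineage_join(active[[pair[1]]], active[[pair[2]]], time)
      active <- c(active[-pair], list(merged))
    } else {
      time <- next_entry
    }
  }
  active[[1]]
}

#' Simulate a genealogy with phylo-temporal clustering
#'
#' Emulates sampling schemes in which similarly aged samples are
#' phylogenetic neighbours. Under `clustering = "high"` all present-day
#' (age-0) tips are constrained to form a monophyletic group; under
#' `"low"` only a designated half of them (the lexicographically first half
#' of the modern labels, for a seed-independent clade identity) is; under
#' `"none"` the unconstrained serial coalescent is returned, identical to
#' [simulate_serial_coalescent()] at the same seed. Monophyly is enforced
#' by coalescing the constrained subset to its MRCA first and entering that
#' MRCA as a single lineage into the serial coalescent of the remaining
#' lineages.
#'
#' @inheritParams simulate_serial_coalescent
#' @param clustering One of `"none"`, `"low"`, `"high"`.
#' @return A [time_tree()].
#' @export
simulate_clustered_genealogy <- function(dates,
                                         clustering = c("none", "low", "high"),
                                         effective_size = 250000, seed = 1L) {
  dates <- tip_dates(dates)
  clustering <- match.arg(clustering)
  if (clustering == "none") {
    return(simulate_serial_coalescent(dates, effective_size, seed))
  }
  modern <- sort(dates$name[dates$age_years_bp == 0])
  constrained <- if (clustering == "high") {
    modern
  } else {
    modern[seq_len(floor(length(modern) / 2))]
  }
  if (length(constrained) < 2) {
    rlang::abort("clustering constraints need at least 2 modern tips.")
  }
  withr_seed(seed, {
    ages <- date_vector(dates)
    clade_tips <- purrr::map(constrained, function(nm) lineage_tip(nm, ages[[nm]]))
    clade_mrca <- serial_coalescent_core(clade_tips, effective_size)
    rest <- setdiff(dates$name, constrained)
    others <- purrr::map(rest, function(nm) lineage_tip(nm, ages[[nm]]))
    root <- serial_coalescent_core(c(list(clade_mrca), others), effective_size)
    record_to_time_tree(root, dates)
  })
}

#' Fix the root age of a simulated genealogy
#'
#' Rescales all internal-node ages (measured from the present) by
#' `target_root_age / root_age(tree)` while leaving tip ages untouched, so
#' the returned genealogy has exactly the requested root age. When the
#' factor is below 1 the rescaling can push an internal node below the age
#' of its oldest descendant tip; such genealogies are rejected and
#' resimulated via the `resimulate` callback, up to `max_rejections` times.
#'
#' @param tree A [time_tree()].
#' @param target_root_age Desired root age in years BP; must exceed the
#'   oldest tip age.
#' @param max_rejections Maximum number of resimulation attempts.
#' @param resimulate Optional `function(attempt)` returning a fresh
#'   `time_tree` for rejection attempt `attempt`; required if rejections
#'   can occur.
#' @return A `time_tree` whose root age equals `target_root_age` (relative
#'   tolerance 1e-12).
#' @export
condition_root_age <- function(tree, target_root_age = 500000,
                               max_rejections = 100L, resimulate = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (target_root_age <= max(tree$dates$age_years_bp)) {
    rlang::abort("`target_root_age` must exceed the oldest tip age.")
  }
  attempt <- 0L
  current <- tree
  repeat {
    scaled <- rescale_internal_ages(current, target_root_age)
    if (!is.null(scaled)) return(scaled)
    attempt <- attempt + 1L
    if (attempt > max_rejections) {
      rlang::abort(paste0(
        "root-age conditioning failed: rescaling violated tip-precedence ",
        "constraints in ", max_rejections, " consecutive genealogies."
      ))
    }
    if (is.null(resimulate)) {
      rlang::abort(
        "rescaling violates a tip-precedence constraint and no `resimulate` callback was supplied."
      )
    }
    current <- resimulate(attempt)
  }
}

# NULL signals a tip-precedence violation (child tip older than its
# rescaled parent)
rescale_internal_ages <- function(tree, target_root_age) {
  n <- ape::Ntip(tree$phy)
  f <- target_root_age / root_age(tree)
  ages <- tree$ages
  ages[-seq_len(n)] <- ages[-seq_len(n)] * f
  dur <- ages[tree$phy$edge[, 1]] - ages[tree$phy$edge[, 2]]
  if (any(dur <= 0)) return(NULL)
  set_node_ages(tree, ages)
}
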