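#' Time-calibrated genealogy objects
#'
#' A `time_tree` couples a rooted binary topology with node ages in years
#' before present (BP): branch lengths of the embedded `phylo` are durations
#' in years, every parent is strictly older than its children, and tip ages
#' equal the attached tip-date table exactly. It is the simulators' truth
#' object and the least-squares dater's output container.
#'
#' @param phy A rooted `phylo` whose edge lengths are durations in years.
#' @param dates Tip-date tibble (see [tip_dates()]).
#' @param ages Optional numeric vector of node ages (years BP) indexed by
#'   ape node number (`1..Ntip+Nnode`); computed from `phy` and `dates`
#'   when omitted.
#' @return An object of class `time_tree`.
#' @export
time_tree <- function(phy, dates, ages = NULL) {
  dates <- tip_dates(dates)
  if (!inherits(phy, "phylo")) rlang::abort("`phy` must be a `phylo` tree.")
  if (!setequal(phy$tip.label, dates$name)) {
    rlang::abort("tip labels of `phy` and `dates` must match.")
  }
  if (is.null(ages)) {
    ages <- ages_from_phylo(phy, dates)
  }
  obj <- structure(
    list(phy = phy, dates = dates, ages = ages),
    class = "time_tree"
  )
  validate_time_tree(obj)
  obj
}

ages_from_phylo <- function(phy, dates) {
  depths <- ape::node.depth.edgelength(phy)
  tip_age <- date_vector(dates, phy$tip.label)
  # every tip anchors the same root age up to float noise
  root_age <- max(depths[seq_along(tip_age)] + tip_age)
  ages <- root_age - depths
  ages[seq_along(tip_age)] <- tip_age
  ages
}

validate_time_tree <- function(x) {
  phy <- x$phy
  ages <- x$ages
  n <- ape::Ntip(phy)
  if (length(ages) != n + phy$Nnode) {
    rlang::abort("`ages` must have one entry per node.")
  }
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  if (any(dur <= 0)) {
    rlang::abort("every parent must be strictly older than its children.")
  }
  tip_age <- date_vector(x$dates, phy$tip.label)
  if (!isTRUE(all.equal(unname(ages[seq_len(n)]), unname(tip_age),
                        tolerance = 1e-12))) {
    rlang::abort("tip ages must match the attached tip dates.")
  }
  invisible(x)
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf(
    "<time_tree> %d tips, root age %.6g years BP, %d ancient tip(s)\n",
    ape::Ntip(x$phy), root_age(x), sum(x$dates$age_years_bp > 0)
  ))
  invisible(x)
}

#' Node ages of a time tree
#'
#' @param tree A `time_tree`.
#' @return Numeric vector of ages (years BP) indexed by ape node number.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  tree$ages
}

#' @rdname node_ages
#' @export
root_age <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  unname(tree$ages[ape::Ntip(tree$phy) + 1L])
}

# rebuild edge lengths (durations in years) from a node-age vector
set_node_ages <- function(tree, ages) {
  phy <- tree$phy
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  time_tree(phy, tree$dates, ages)
}

# ---- internal recursive lineage records -------------------------------

lineage_tip <- function(label, age) {
  list(tip = TRUE, label = label, age = age)
}

lineage_join <- function(left, right, age) {
  list(tip = FALSE, left = left, right = right, age = age)
}

# convert the simulator's recursive record into a time_tree; tips numbered
# in DFS encounter order, internals in preorder (root = Ntip+1), which is
# ape's cladewise convention
record_to_time_tree <- function(root_rec, dates) {
  n_tip <- nrow(dates)
  edge <- matrix(0L, nrow = 2L * n_tip - 2L, ncol = 2L)
  edge_len <- numeric(2L * n_tip - 2L)
  tip_label <- character(n_tip)
  ages <- numeric(2L * n_tip - 1L)
  env <- new.env()
  env$next_tip <- 1L
  env$next_int <- n_tip + 1L
  env$next_edge <- 1L

  visit <- function(rec) {
    if (isTRUE(rec$tip)) {
      id <- env$next_tip
      env$next_tip <- id + 1L
      tip_label[id] <<- rec$label
      ages[id] <<- rec$age
      return(id)
    }
    id <- env$next_int
    env$next_int <- id + 1L
    ages[id] <<- rec$age
    for (child in list(rec$left, rec$right)) {
      e <- env$next_edge
      env$next_edge <- e + 1L
      cid <- visit(child)
      edge[e, ] <<- c(id, cid)
      edge_len[e] <<- rec$age - ages[cid]
    }
    id
  }
  visit(root_rec)

  phy <- structure(
    list(edge = edge, edge.length = edge_len, tip.label = tip_label,
         Nnode = n_tip - 1L),
    class = "phylo", order = "cladewise"
  )
  time_tree(phy, dates, ages)
}
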