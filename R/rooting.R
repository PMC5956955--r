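#' Optimal root placement for root-to-tip regression
#'
#' Finds the root position (edge and fractional position along it) that
#' minimises the residual sum of squares of the regression of root-to-tip
#' distance on sampling time. Because every root-to-tip distance is affine
#' in the position along a fixed edge, the RSS is an exact quadratic in the
#' position and each edge's minimiser is available in closed form; the
#' global optimum is the best edge. Ties are broken by the smallest edge
#' index in ape's serialisation-stable edge ordering.
#'
#' @param tree An (un)rooted `phylo` phylogram with >= 3 tips.
#' @param dates Tip-date tibble; at least two distinct ages.
#' @return A rooted `phylo` with attributes `root_edge_index`,
#'   `root_position` (distance from the edge's parent endpoint, in
#'   branch-length units) and `rss` (the minimised RSS).
#' @export
find_best_root <- function(tree, dates) {
  stopifnot(inherits(tree, "phylo"))
  dates <- tip_dates(dates)
  n <- ape::Ntip(tree)
  if (n < 3) rlang::abort("at least 3 tips are required.")
  ages <- date_vector(dates, tree$tip.label)
  if (length(unique(ages)) < 2) {
    rlang::abort("all tip dates are equal: no temporal spread to regress on.")
  }
  x <- -ages                     # forward time
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  resid_of <- function(v) {
    beta <- sum(xc * v) / sxx
    v - mean(v) - beta * xc
  }

  d_nodes <- ape::dist.nodes(tree)
  best <- list(rss = Inf, edge = NA_integer_, t = NA_real_)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]
    b <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    # tips whose path to a runs through b see the root move toward them
    on_b_side <- abs(d_nodes[a, seq_len(n)] -
                       (len + d_nodes[b, seq_len(n)])) < 1e-9 * (1 + len)
    y0 <- d_nodes[a, seq_len(n)]
    s <- ifelse(on_b_side, -1, 1)
    r0 <- resid_of(y0)
    rs <- resid_of(s)
    denom <- sum(rs^2)
    t_star <- if (denom < 1e-300) 0 else -sum(r0 * rs) / denom
    t_star <- min(max(t_star, 0), len)
    rss <- sum((r0 + t_star * rs)^2)
    if (rss < best$rss - 1e-15) {
      best <- list(rss = rss, edge = e, t = t_star)
    }
  }

  rooted <- root_on_edge(tree, best$edge, best$t)
  attr(rooted, "root_edge_index") <- best$edge
  attr(rooted, "root_position") <- best$t
  attr(rooted, "rss") <- best$rss
  rooted
}

# root `tree` along edge `e`, at distance `t` from the parent endpoint
root_on_edge <- function(tree, e, t) {
  child <- tree$edge[e, 2]
  len <- tree$edge.length[e]
  # phytools::reroot measures position from the rootward (parent) end
  pos <- min(max(t, 0), len)
  rooted <- phytools::reroot(tree, node.number = child, position = pos)
  rooted$edge.length[rooted$edge.length < 0] <- 0
  rooted
}
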