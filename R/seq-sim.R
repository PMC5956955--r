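#' Simulate a nucleotide alignment along a phylogram
#'
#' Evolves sequences down a tree whose branch lengths are expected
#' substitutions per site, under HKY+Gamma: the root sequence is drawn from
#' the stationary frequencies, each site is independently assigned one of
#' the model's equal-probability discrete gamma categories (fixed across
#' the whole tree), and each site evolves along every branch with
#' transition matrix `P(b * rate_cat)`.
#'
#' @param tree A rooted `phylo` with branch lengths in subs/site, or a
#'   [time_tree()] (whose branch durations are then interpreted via
#'   `rate`).
#' @param model An [hky_model()].
#' @param seq_length Number of sites (>= 1).
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   alignments.
#' @return A `DNAbin` matrix (tips x sites) with rownames equal to the
#'   tree's tip labels.
#' @export
simulate_alignment <- function(tree, model = hky_model(), seq_length = 15000,
                               seed = 1L) {
  if (inherits(tree, "time_tree")) {
    rlang::abort("`tree` must be a phylogram (subs/site); see `to_phylogram()`.")
  }
  stopifnot(inherits(tree, "phylo"))
  if (seq_length < 1) rlang::abort("`seq_length` must be >= 1.")
  if (anyDuplicated(tree$tip.label)) {
    rlang::abort("tip labels must be unique.")
  }
  phy <- stats::reorder(tree, "cladewise")
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  cat_rates <- gamma_category_rates(model$gamma_shape, model$n_cat)
  eig <- hky_eigen(model)

  states <- withr_seed(seed, {
    n_cat <- length(cat_rates)
    site_cat <- sample.int(n_cat, seq_length, replace = TRUE)
    s <- matrix(0L, nrow = n_node, ncol = seq_length)
    root <- n_tip + 1L
    s[root, ] <- sample.int(4L, seq_length, replace = TRUE,
                            prob = model$base_freq)
    cum_op <- upper.tri(diag(4), diag = TRUE)
    cat_offset <- (site_cat - 1L) * 4L
    for (e in seq_len(nrow(phy$edge))) {
      parent <- phy$edge[e, 1]
      child <- phy$edge[e, 2]
      bl <- phy$edge.length[e]
      # stacked row-cumulative transition matrices, one 4-row block per
      # gamma category; row index = 4 * (category - 1) + parent state
      cum <- do.call(rbind, lapply(cat_rates, function(cr) {
        tp_from_eigen(eig, bl * cr) %*% cum_op
      }))
      rix <- cat_offset + s[parent, ]
      u <- stats::runif(seq_length)
      # inverse-CDF draw of the child state, vectorised over sites
      s[child, ] <- 1L + (u > cum[cbind(rix, 1L)]) +
        (u > cum[cbind(rix, 2L)]) + (u > cum[cbind(rix, 3L)])
    }
    s
  })

  chars <- matrix(DNA_BASES[states[seq_len(n_tip), , drop = FALSE]],
                  nrow = n_tip)
  rownames(chars) <- phy$tip.label
  ape::as.DNAbin(chars)
}

tp_from_eigen <- function(eig, branch_length) {
  p <- eig$right %*% diag(exp(eig$values * branch_length)) %*% eig$left
  p[p < 0] <- 0
  p / rowSums(p)
}
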