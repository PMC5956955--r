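#' Pairwise maximum-likelihood distances
#'
#' Closed-form pairwise distances between aligned sequences. `"TN93"` (the
#' default) is the standard closed-form distance under the
#' Tamura-Nei model, which contains HKY as a special case; `"JC69"` gives
#' the Jukes-Cantor distance `-(3/4) log(1 - 4p/3)`; `"raw"` the
#' uncorrected mismatch proportion.
#'
#' @param aln A `DNAbin` matrix.
#' @param dist_model One of `"TN93"`, `"JC69"`, `"raw"`.
#' @param gamma Gamma shape for among-site rate-variation correction of the
#'   distance (`NULL` or `Inf` for none); ignored for `"raw"`.
#' @return A `dist` object of pairwise distances (subs/site).
#' @export
ml_distances <- function(aln, dist_model = c("TN93", "JC69", "raw"),
                         gamma = NULL) {
  dist_model <- match.arg(dist_model)
  g <- if (is.null(gamma) || is.infinite(gamma) || dist_model == "raw") {
    FALSE
  } else {
    gamma
  }
  ape::dist.dna(aln, model = switch(dist_model, raw = "raw", dist_model),
                gamma = g, pairwise.deletion = TRUE)
}

#' Infer a phylogram from an alignment
#'
#' Stand-in for a full maximum-likelihood tree search: neighbour-joining on
#' closed-form pairwise ML distances, with negative branch lengths clamped
#' to zero. The result is unrooted; root placement is a separate step
#' ([find_best_root()]), and an externally inferred phylogram can be used
#' instead via [read_newick()].
#'
#' @param aln A `DNAbin` matrix with >= 3 sequences.
#' @param dist_model Distance model passed to [ml_distances()].
#' @param gamma Gamma-shape correction passed to [ml_distances()].
#' @return An unrooted `phylo` with branch lengths in subs/site.
#' @export
infer_phylogram <- function(aln, dist_model = "TN93", gamma = NULL) {
  if (nrow(aln) < 3) rlang::abort("at least 3 sequences are required.")
  d <- ml_distances(aln, dist_model, gamma = gamma)
  if (anyNA(d) || any(!is.finite(d))) {
    rlang::abort("undefined pairwise distances (saturated or empty overlap).")
  }
  if (all(d == 0)) {
    rlang::warn("all sequences identical: returning a zero-length tree.")
  }
  phy <- ape::nj(d)
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}
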