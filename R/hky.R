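#' HKY+Gamma substitution model
#'
#' Bundles the parameters of the HKY85 nucleotide model with discrete-gamma
#' among-site rate variation: transition/transversion rate ratio `kappa`,
#' stationary base frequencies `pi` (order A, C, G, T), gamma shape
#' `alpha`, and the number of equal-probability gamma categories. Defaults
#' are typical of vertebrate mitochondrial genomes. `gamma_shape = Inf`
#' turns rate heterogeneity off (a single unit-rate category).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freq Stationary frequencies, length 4, order A, C, G, T,
#'   summing to 1.
#' @param gamma_shape Gamma shape `alpha` (> 0, or `Inf` for no
#'   heterogeneity).
#' @param n_cat Number of discrete gamma categories (>= 1).
#' @return An object of class `hky_model`.
#' @examples
#' hky_model(kappa = 10, gamma_shape = 0.5)
#' @export
hky_model <- function(kappa = 10,
                      base_freq = c(A = 0.31, C = 0.31, G = 0.13, T = 0.25),
                      gamma_shape = 0.5, n_cat = 4L) {
  base_freq <- as.numeric(base_freq)
  if (length(base_freq) != 4 || any(base_freq <= 0) ||
      abs(sum(base_freq) - 1) > 1e-12) {
    rlang::abort("`base_freq` must be 4 positive values summing to 1.")
  }
  if (kappa <= 0) rlang::abort("`kappa` must be positive.")
  if (gamma_shape <= 0) rlang::abort("`gamma_shape` must be positive.")
  if (n_cat < 1) rlang::abort("`n_cat` must be >= 1.")
  structure(
    list(kappa = kappa, base_freq = stats::setNames(base_freq, DNA_BASES),
         gamma_shape = gamma_shape, n_cat = as.integer(n_cat)),
    class = "hky_model"
  )
}

DNA_BASES <- c("A", "C", "G", "T")

#' @export
print.hky_model <- function(x, ...) {
  cat(sprintf(
    "<hky_model> kappa = %g, pi = (%s), alpha = %g, %d gamma categories\n",
    x$kappa, paste(signif(x$base_freq, 3), collapse = ", "),
    x$gamma_shape, x$n_cat
  ))
  invisible(x)
}

#' HKY instantaneous rate matrix
#'
#' Builds the 4x4 HKY generator: off-diagonal rates proportional to
#' `kappa * pi_y` for transitions (A<->G, C<->T) and `pi_y` for
#' transversions, diagonal set to minus the row sums, normalised so the
#' stationary substitution rate `sum_x pi_x * (-q_xx)` equals 1 (branch
#' lengths are then expected substitutions per site).
#'
#' @param model An [hky_model()].
#' @return A 4x4 matrix with dimnames A, C, G, T.
#' @export
hky_rate_matrix <- function(model) {
  stopifnot(inherits(model, "hky_model"))
  pi <- model$base_freq
  k <- model$kappa
  is_transition <- matrix(FALSE, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  is_transition["A", "G"] <- is_transition["G", "A"] <- TRUE
  is_transition["C", "T"] <- is_transition["T", "C"] <- TRUE
  q <- matrix(rep(pi, each = 4), 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  q[is_transition] <- q[is_transition] * k
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  scale <- -sum(pi * diag(q))
  q / scale
}

# symmetric eigendecomposition of the reversible generator, for stable
# matrix exponentials
hky_eigen <- function(model) {
  q <- hky_rate_matrix(model)
  sp <- sqrt(model$base_freq)
  s <- diag(sp) %*% q %*% diag(1 / sp)
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  list(
    values = e$values,
    right = diag(1 / sp) %*% e$vectors,
    left = t(e$vectors) %*% diag(sp)
  )
}

#' HKY transition-probability matrix
#'
#' Computes `P = exp(Q * branch_length)` for the normalised HKY generator
#' via its symmetric eigendecomposition.
#'
#' @param model An [hky_model()].
#' @param branch_length Branch length in expected substitutions per site
#'   (>= 0).
#' @return A 4x4 row-stochastic matrix.
#' @export
transition_probabilities <- function(model, branch_length) {
  if (branch_length < 0) rlang::abort("`branch_length` must be >= 0.")
  e <- hky_eigen(model)
  p <- e$right %*% diag(exp(e$values * branch_length)) %*% e$left
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- list(DNA_BASES, DNA_BASES)
  p
}

#' Discrete-gamma category rates
#'
#' Mean rates of `n_cat` equal-probability categories of a
#' Gamma(shape = alpha, mean = 1) distribution (the usual discrete
#' approximation using category means), normalised to overall mean 1.
#'
#' @param alpha Gamma shape (> 0, or `Inf` for a single unit category).
#' @param n_cat Number of categories.
#' @return Numeric vector of length `n_cat` with mean exactly 1.
#' @export
gamma_category_rates <- function(alpha, n_cat = 4L) {
  if (is.infinite(alpha) || n_cat == 1L) return(rep(1, max(1L, n_cat)))
  if (alpha <= 0) rlang::abort("`alpha` must be positive.")
  breaks <- stats::qgamma(seq(0, 1, length.out = n_cat + 1),
                          shape = alpha, rate = alpha)
  upper <- stats::pgamma(breaks[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(breaks[-length(breaks)], shape = alpha + 1,
                         rate = alpha)
  rates <- n_cat * (upper - lower)
  rates / mean(rates)
}
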