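test_that("zero-length trees copy the root sequence to every tip", {
  phy <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln <- simulate_alignment(phy, flat_model(), 200, seed = 1)
  ch <- as.character(aln)
  for (i in 2:4) expect_identical(ch[i, ], ch[1, ])
})

test_that("alignments have the requested dimensions and labels", {
  fx <- clocklike_fixture(n_tips = 8, seed = 5)
  aln <- simulate_alignment(fx$phylogram, hky_model(), 500, seed = 2)
  expect_equal(dim(aln), c(8L, 500L))
  expect_setequal(rownames(aln), fx$dates$name)
})

test_that("pairwise mismatch proportion matches the analytic expectation", {
  m <- flat_model(kappa = 6)
  phy <- ape::read.tree(text = "(A:0.08,B:0.12);")
  L <- 200000
  aln <- simulate_alignment(phy, m, L, seed = 3)
  ch <- as.character(aln)
  observed <- mean(ch[1, ] != ch[2, ])
  p1 <- transition_probabilities(m, 0.08)
  p2 <- transition_probabilities(m, 0.12)
  # P(match) = sum_s pi_s * (P1 P2^T)[s,s]
  expected <- 1 - sum(m$base_freq * diag(p1 %*% t(p2)))
  expect_lt(abs(observed - expected), 0.005)
})

test_that("simulated base composition converges to the stationary pi", {
  m <- hky_model()
  phy <- ape::read.tree(text = "((a:0.05,b:0.05):0.02,c:0.07);")
  rejections <- 0
  for (seed in 1:3) {
    aln <- simulate_alignment(phy, m, 100000, seed = seed)
    bf <- ape::base.freq(aln)[c("a", "c", "g", "t")]
    counts <- round(bf * 3 * 100000)
    p <- stats::chisq.test(counts, p = m$base_freq)$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1)
})

test_that("identical seeds give byte-identical FASTA output", {
  fx <- clocklike_fixture(n_tips = 6, seed = 9)
  a1 <- simulate_alignment(fx$phylogram, hky_model(), 300, seed = 11)
  a2 <- simulate_alignment(fx$phylogram, hky_model(), 300, seed = 11)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(a1, f1); write_fasta(a2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("a JC simulation is recovered by the JC distance", {
  phy <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- simulate_alignment(phy, jc_model(), 100000, seed = 4)
  d <- ml_distances(aln, "JC69")
  expect_lt(abs(as.numeric(d) - 0.2), 0.01)
})

test_that("gamma rate heterogeneity changes site patterns as expected", {
  # with strong heterogeneity (alpha = 0.1) many sites are nearly
  # invariant, so the mismatch proportion drops below the homogeneous case
  phy <- ape::read.tree(text = "(A:0.3,B:0.3);")
  hom <- simulate_alignment(phy, flat_model(), 50000, seed = 6)
  het <- simulate_alignment(
    phy, hky_model(kappa = 4, base_freq = c(0.31, 0.31, 0.13, 0.25),
                   gamma_shape = 0.1, n_cat = 8),
    50000, seed = 6
  )
  mis <- function(a) { ch <- as.character(a); mean(ch[1, ] != ch[2, ]) }
  expect_lt(mis(het), mis(hom))
})

test_that("the simulator agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  # same HKY parameters, no rate heterogeneity; compare pairwise mismatch
  # proportions on a two-tip tree against phangorn's simulator
  kappa <- 6
  bf <- c(0.31, 0.31, 0.13, 0.25)
  phy <- ape::read.tree(text = "(A:0.1,B:0.1);")
  L <- 30000
  ours <- simulate_alignment(phy, flat_model(kappa = kappa, base_freq = bf),
                             L, seed = 8)
  ch <- as.character(ours)
  mis_ours <- mean(ch[1, ] != ch[2, ])

  set.seed(8)
  # phangorn's HKY exchange rates in order AC, AG, AT, CG, CT, GT
  other <- phangorn::simSeq(phy, l = L, Q = c(1, kappa, 1, 1, kappa, 1),
                            bf = bf, type = "DNA")
  m <- as.character(other)
  mis_other <- mean(m[1, ] != m[2, ])
  # both estimate the same mismatch probability; 4 pooled binomial SEs
  se <- sqrt(2 * mis_ours * (1 - mis_ours) / L)
  expect_lt(abs(mis_ours - mis_other), 4 * se + 0.002)
})
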