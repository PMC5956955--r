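test_that("constructed age-clustered clades give a significant rho", {
  # two balanced 8-tip clades, one all modern, one all ancient
  tip_block <- function(prefix) {
    paste0("((", prefix, "1:1,", prefix, "2:1):1,(", prefix, "3:1,",
           prefix, "4:1):1)")
  }
  nwk <- sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);",
                 tip_block("m"), tip_block("n"),
                 tip_block("a"), tip_block("b"))
  phy <- ape::read.tree(text = nwk)
  ages <- ifelse(grepl("^[mn]", phy$tip.label), 0, 50000)
  dates <- tip_dates(stats::setNames(ages, phy$tip.label))
  hits <- 0
  for (seed in 1:5) {
    res <- phylo_temporal_clustering(phy, dates, n_perm = 1000, seed = seed)
    if (res$rho > 0 && res$p_value <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("rho matches a naive double loop over all pairs", {
  set.seed(3)
  phy <- ape::rtree(10)
  dates <- tip_dates(stats::setNames(stats::runif(10, 0, 50000),
                                     phy$tip.label))
  res <- phylo_temporal_clustering(phy, dates, n_perm = 9, seed = 1)
  ages <- dates$age_years_bp[match(phy$tip.label, dates$name)]
  topo <- phy
  topo$edge.length <- rep(1, nrow(phy$edge))
  dmat <- ape::dist.nodes(topo)
  dd <- c(); aa <- c()
  for (i in 1:9) {
    for (j in (i + 1):10) {
      dd <- c(dd, dmat[i, j])
      aa <- c(aa, abs(ages[i] - ages[j]))
    }
  }
  expect_equal(res$rho, stats::cor(dd, aa), tolerance = 1e-12)
})

test_that("the clustering P-value is uniform under the null", {
  set.seed(42)
  phy <- ape::rtree(10)
  base_ages <- stats::runif(10, 0, 50000)
  pvals <- vapply(1:400, function(i) {
    dates <- tip_dates(stats::setNames(sample(base_ages), phy$tip.label))
    phylo_temporal_clustering(phy, dates, n_perm = 199,
                              seed = 1000 + i)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("stemminess follows its definition", {
  two <- ape::read.tree(text = "(a:1,b:2);")
  expect_equal(stemminess(two), 0)

  four <- ape::read.tree(text = "((a:2,b:2):1,(c:2,d:2):1);")
  expect_equal(stemminess(four), 0.2)

  # complementary-sum oracle and invariances on random trees
  for (seed in 1:5) {
    set.seed(seed)
    phy <- ape::rtree(12)
    pendant <- phy$edge[, 2] <= 12
    oracle <- 1 - sum(phy$edge.length[pendant]) / sum(phy$edge.length)
    expect_equal(stemminess(phy), oracle, tolerance = 1e-12)
    scaled <- phy
    scaled$edge.length <- phy$edge.length * 7.3
    expect_equal(stemminess(scaled), stemminess(phy), tolerance = 1e-12)
  }

  zero <- ape::read.tree(text = "(a:0,b:0);")
  expect_error(stemminess(zero), "undefined")
})

test_that("date randomization separates signal from its absence", {
  # positive control: strong clock signal, wide date spread, enough tips
  # that a random date permutation rarely mimics the truth
  passes <- 0
  for (s in 1:3) {
    fx <- clocklike_fixture(n_tips = 40, rate = 1e-6, seed = 20 + s)
    aln <- simulate_alignment(fx$phylogram, flat_model(), 5000, seed = s)
    drt <- date_randomization_test(aln, dates = fx$dates, method = "rtt",
                                   n_reps = 10, n_boot = 30, seed = s)
    expect_length(drt$replicates, 10)
    # CR2 implies CR1 and the flags are recomputable from the estimates
    cr <- tipclock:::drt_criteria(drt$original, drt$replicates)
    expect_identical(cr$cr1, drt$cr1)
    expect_identical(cr$cr2, drt$cr2)
    if (drt$cr2) expect_true(drt$cr1)
    passes <- passes + drt$cr1
  }
  expect_gte(passes, 2)

  # negative control: contemporaneous evolution with fabricated dates
  fx <- clocklike_fixture(n_tips = 10, rate = 1e-6, seed = 21)
  phy <- fx$phylogram
  depths <- ape::node.depth.edgelength(phy)
  n <- ape::Ntip(phy)
  # make the tree ultrametric (all tips contemporaneous), then lie about ages
  for (e in seq_len(nrow(phy$edge))) {
    if (phy$edge[e, 2] <= n) {
      tip <- phy$edge[e, 2]
      phy$edge.length[e] <- phy$edge.length[e] + max(depths[1:n]) - depths[tip]
    }
  }
  aln2 <- simulate_alignment(phy, flat_model(), 4000, seed = 3)
  fails <- 0
  for (seed in 1:3) {
    drt2 <- suppressWarnings(
      date_randomization_test(aln2, dates = fx$dates, method = "rtt",
                              n_reps = 10, n_boot = 30, seed = seed)
    )
    if (!drt2$cr1) fails <- fails + 1
  }
  expect_gte(fails, 2)
})

test_that("date randomization is deterministic given the seed", {
  fx <- clocklike_fixture(n_tips = 8, rate = 1e-6, seed = 31)
  aln <- simulate_alignment(fx$phylogram, flat_model(), 1500, seed = 1)
  d1 <- date_randomization_test(aln, dates = fx$dates, method = "rtt",
                                n_reps = 4, n_boot = 15, seed = 9)
  d2 <- date_randomization_test(aln, dates = fx$dates, method = "rtt",
                                n_reps = 4, n_boot = 15, seed = 9)
  expect_identical(glance(d1), glance(d2))
  expect_equal(purrr::map_dbl(d1$replicates, "rate"),
               purrr::map_dbl(d2$replicates, "rate"))
})

test_that("degenerate diagnostic inputs raise clear errors", {
  phy <- ape::rtree(5)
  same <- tip_dates(stats::setNames(rep(7, 5), phy$tip.label))
  expect_error(phylo_temporal_clustering(phy, same), "ages equal")
})
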