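test_that("two contemporaneous tips have Exponential(mean N) TMRCA", {
  n_rep <- 4000
  N <- 1000
  d <- tip_dates(c(a = 0, b = 0))
  h <- vapply(seq_len(n_rep), function(i) {
    root_age(simulate_serial_coalescent(d, N, seed = i))
  }, numeric(1))
  se <- stats::sd(h) / sqrt(n_rep)
  expect_lt(abs(mean(h) - N), 3 * se)
  # distributional check: KS against Exponential(1/N), generous alpha
  expect_gt(stats::ks.test(h, "pexp", 1 / N)$p.value, 1e-4)
})

test_that("the TMRCA of serially sampled tips respects the oldest entry", {
  d <- tip_dates(c(a = 0, b = 30000))
  h <- vapply(1:200, function(i) {
    root_age(simulate_serial_coalescent(d, 1000, seed = i))
  }, numeric(1))
  expect_true(all(h >= 30000))
})

test_that("three contemporaneous tips have mean height N(1 + 1/3)", {
  n_rep <- 4000
  N <- 1000
  d <- tip_dates(c(a = 0, b = 0, c = 0))
  h <- vapply(seq_len(n_rep), function(i) {
    root_age(simulate_serial_coalescent(d, N, seed = 10000 + i))
  }, numeric(1))
  se <- stats::sd(h) / sqrt(n_rep)
  expect_lt(abs(mean(h) - N * (1 + 1 / 3)), 3 * se)
})

test_that("simulated genealogies are valid time trees with exact tip ages", {
  for (seed in 1:20) {
    d <- simulate_tip_ages(20, 0.5, 50000, seed = seed)
    tt <- simulate_serial_coalescent(d, 250000, seed = seed)
    ages <- node_ages(tt)
    dur <- ages[tt$phy$edge[, 1]] - ages[tt$phy$edge[, 2]]
    expect_true(all(dur > 0))
    expect_identical(
      unname(ages[seq_len(20)][match(d$name, tt$phy$tip.label)]),
      d$age_years_bp
    )
  }
})

test_that("clustering constraints make the requested tips monophyletic", {
  d <- simulate_tip_ages(100, 0.5, 50000, seed = 4)
  modern <- sort(d$name[d$age_years_bp == 0])

  high <- simulate_clustered_genealogy(d, "high", 250000, seed = 5)
  expect_true(ape::is.monophyletic(high$phy, modern))

  low <- simulate_clustered_genealogy(d, "low", 250000, seed = 5)
  designated <- modern[seq_len(25)]
  expect_true(ape::is.monophyletic(low$phy, designated))

  none <- simulate_clustered_genealogy(d, "none", 250000, seed = 5)
  plain <- simulate_serial_coalescent(d, 250000, seed = 5)
  expect_identical(ape::write.tree(none$phy), ape::write.tree(plain$phy))
})

test_that("clustering requires at least two modern tips", {
  d <- tip_dates(c(a = 0, b = 100, c = 200))
  expect_error(simulate_clustered_genealogy(d, "high", 1000, 1),
               "at least 2 modern tips")
})

test_that("root-age conditioning rescales internals and keeps tips fixed", {
  fx <- clocklike_fixture(n_tips = 10, seed = 11)
  tt <- fx$time_tree
  # identity when the root is already at the target
  same <- condition_root_age(tt, root_age(tt), 10)
  expect_equal(node_ages(same), node_ages(tt), tolerance = 1e-12)

  # pure scaling with all-modern tips: internal ages double
  st <- simulate_serial_coalescent(
    tip_dates(stats::setNames(rep(0, 8), letters[1:8])), 1000, seed = 2
  )
  doubled <- condition_root_age(st, 2 * root_age(st), 10)
  n <- ape::Ntip(st$phy)
  expect_equal(node_ages(doubled)[-(1:n)], 2 * node_ages(st)[-(1:n)],
               tolerance = 1e-12)
  expect_equal(node_ages(doubled)[1:n], node_ages(st)[1:n])
})

test_that("conditioned genealogies hit the target root age exactly", {
  for (seed in 1:50) {
    d <- simulate_tip_ages(20, 0.5, 50000, seed = seed)
    sim <- function(a) simulate_serial_coalescent(d, 250000, seed = seed + 1000 * a)
    tt <- condition_root_age(sim(0), 500000, 100, resimulate = sim)
    expect_equal(root_age(tt), 500000, tolerance = 1e-12)
    dur <- tt$ages[tt$phy$edge[, 1]] - tt$ages[tt$phy$edge[, 2]]
    expect_true(all(dur > 0))
  }
})

test_that("conditioning fails loudly when rejection budget is exhausted", {
  # shrinking the root to 50,000 y pulls the (a,c) ancestor below its
  # ancient child (40,000 y), so every attempt must be rejected
  phy <- ape::read.tree(text = "((a:100000,c:60000):100000,b:200000);")
  tt <- time_tree(phy, tip_dates(c(a = 0, c = 40000, b = 0)))
  expect_error(condition_root_age(tt, 50000, 3,
                                  resimulate = function(a) tt),
               "conditioning failed")
  expect_error(condition_root_age(tt, 50000, 3), "resimulate")
})

test_that("genealogy simulation is deterministic given the seed", {
  d <- simulate_tip_ages(30, 0.5, 50000, seed = 9)
  t1 <- simulate_clustered_genealogy(d, "high", 250000, seed = 42)
  t2 <- simulate_clustered_genealogy(d, "high", 250000, seed = 42)
  expect_identical(ape::write.tree(t1$phy), ape::write.tree(t2$phy))
})
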