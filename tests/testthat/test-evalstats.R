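test_that("standardized error follows its definition", {
  expect_equal(standardized_error(1e-7, 1e-7), 0)
  expect_equal(standardized_error(2e-8, 1e-8), 1)
  expect_equal(standardized_error(0, 1e-8), -1)
  expect_equal(standardized_error(c(2e-8, 0), 1e-8), c(1, -1))
  expect_error(standardized_error(1e-8, 0), "positive")
})

test_that("the one-sample Wilcoxon behaves under symmetry and shift", {
  # perfect x / -x symmetry: no evidence against zero
  sym <- c(-4, -3, -2, -1, 1, 2, 3, 4) / 10
  res <- suppressWarnings(wilcoxon_vs_zero(sym))
  expect_gt(res$p_value, 0.9)

  # shifted samples are detected
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    if (wilcoxon_vs_zero(stats::rnorm(100, 0.5))$p_value < 0.01) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)

  expect_error(wilcoxon_vs_zero(rep(0, 5)), "degenerate")
})

test_that("the Wilcoxon P matches exhaustive sign enumeration (n <= 10)", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- round(stats::rnorm(8), 3)
    x <- x[x != 0]
    while (anyDuplicated(abs(x))) x <- x + 1e-4 * seq_along(x)
    expect_equal(wilcoxon_vs_zero(x)$p_value, wilcoxon_enum_oracle(x),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis over the grid has groups-minus-one df", {
  set.seed(1)
  fake <- tidyr::expand_grid(scenario_id = sprintf("s%02d", 1:12),
                             replicate = 1:5, method = c("rtt", "lsd"))
  fake$std_error <- stats::rnorm(nrow(fake))
  kw <- kruskal_wallis_errors(fake, "rtt")
  expect_equal(kw$df, 11)
  expect_equal(kw$n_groups, 12)

  # rank-sum arithmetic oracle on a fixed small table with no ties
  tbl <- tibble::tibble(
    scenario_id = rep(c("a", "b", "c"), each = 4),
    method = "rtt",
    std_error = c(0.1, 0.4, 0.7, 1.1, 0.2, 0.5, 0.9, 1.3, 0.3, 0.6, 1.0, 1.4)
  )
  kw2 <- kruskal_wallis_errors(tbl, "rtt")
  r <- rank(tbl$std_error)
  n <- length(r)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, tbl$scenario_id, function(g) length(g) * mean(g)^2)) -
    3 * (n + 1)
  expect_equal(unname(kw2$statistic), h, tolerance = 1e-12)
})

test_that("Kruskal-Wallis P-values are uniform under the null", {
  set.seed(5)
  pvals <- vapply(1:1000, function(i) {
    stats::kruskal.test(stats::rnorm(240),
                        factor(rep(1:12, each = 20)))$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("pairwise rank-sum matrices are symmetric with Holm correction", {
  set.seed(2)
  tbl <- tibble::tibble(
    scenario_id = rep(c("a", "b", "c"), each = 10),
    method = "lsd",
    std_error = stats::rnorm(30)
  )
  m <- pairwise_mwu(tbl, "lsd")
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))

  same <- tbl
  same$std_error <- rep(c(1.2, 3.1, -0.5, 0.8, 2.2, -1.1, 0.3, 1.9, -0.2, 0.6), 3)
  m2 <- suppressWarnings(pairwise_mwu(same, "lsd"))
  expect_true(all(m2 == 1))
})

test_that("the rank-sum P matches exhaustive enumeration (n <= 8)", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- round(stats::rnorm(4), 3)
    y <- round(stats::rnorm(4, 0.5), 3) + 1e-4
    if (anyDuplicated(c(x, y))) next
    p_ours <- stats::wilcox.test(x, y, alternative = "two.sided")$p.value
    expect_equal(p_ours, mwu_enum_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("proportions above truth match an independent ECDF", {
  set.seed(7)
  tbl <- tibble::tibble(
    scenario_id = "s1", method = "rtt",
    estimate = stats::rlnorm(40, log(1e-7), 0.5),
    true_rate = 1e-7
  )
  got <- proportion_above_true(tbl)$prop_above
  ecdf_oracle <- 1 - stats::ecdf(tbl$estimate)(1e-7)
  expect_equal(got, ecdf_oracle, tolerance = 1e-12)

  all_over <- tbl
  all_over$estimate <- 2e-7
  expect_equal(proportion_above_true(all_over)$prop_above, 1)
})

test_that("interval width ratios are computed from the stored interval", {
  est <- rate_estimate("rtt", 1e-7, interval = c(0.5e-7, 1.5e-7),
                       level = 0.95)
  expect_equal(interval_width_ratio(est, 1e-7), 1)
  degenerate <- rate_estimate("rtt", 1e-7, interval = c(1e-7, 1e-7),
                              level = 0.95)
  expect_equal(interval_width_ratio(degenerate, 1e-7), 0)
  no_int <- rate_estimate("rtt", 1e-7)
  expect_error(interval_width_ratio(no_int, 1e-7), "interval")
})

test_that("stemminess-error correlations follow the definitional formula", {
  tbl <- tibble::tibble(
    scenario_id = "s1", method = "lsd",
    stemminess = c(0.1, 0.25, 0.4, 0.55, 0.7),
    std_error = 2 * c(0.1, 0.25, 0.4, 0.55, 0.7)
  )
  res <- stemminess_error_correlation(tbl)
  expect_equal(res$r, 1, tolerance = 1e-12)

  set.seed(9)
  tbl2 <- tibble::tibble(
    scenario_id = "s1", method = "lsd",
    stemminess = stats::runif(5),
    std_error = stats::rnorm(5)
  )
  res2 <- stemminess_error_correlation(tbl2)
  x <- tbl2$stemminess; y <- abs(tbl2$std_error)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$r, r_oracle, tolerance = 1e-12)
})

test_that("method comparison statistics behave under identity and swap", {
  x <- c(1e-7, 2e-7, 3e-7)
  same <- compare_methods(x, x)
  expect_equal(same$prop_diff, rep(0, 3))
  expect_equal(same$bias, 0)

  doubled <- compare_methods(x, 2 * x)
  expect_equal(doubled$prop_diff, rep(1, 3))
  expect_equal(doubled$bias, 0)

  set.seed(4)
  a <- stats::rlnorm(20); b <- stats::rlnorm(20)
  expect_equal(compare_methods(a, b)$bias,
               1 - compare_methods(b, a)$bias)
  expect_warning(compare_methods(c(0, 1), c(1, 2)), "excluded")
})
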