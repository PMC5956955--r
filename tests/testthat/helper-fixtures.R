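# shared fixtures: all built in code at test time

# HKY model without site-rate heterogeneity, for analytic oracles
flat_model <- function(kappa = 4, base_freq = c(0.31, 0.31, 0.13, 0.25)) {
  hky_model(kappa = kappa, base_freq = base_freq, gamma_shape = Inf,
            n_cat = 1L)
}

jc_model <- function() {
  hky_model(kappa = 1, base_freq = rep(0.25, 4), gamma_shape = Inf,
            n_cat = 1L)
}

# conditioned clocklike truth: time tree + strict-clock phylogram + dates
clocklike_fixture <- function(n_tips = 12, rate = 1e-7, seed = 3,
                              root_age = 500000) {
  dates <- simulate_tip_ages(n_tips, 0.5, 50000, seed = seed)
  tt <- condition_root_age(
    simulate_serial_coalescent(dates, 250000, seed = seed + 1),
    root_age, 100,
    resimulate = function(a) {
      simulate_serial_coalescent(dates, 250000, seed = seed + 1 + a)
    }
  )
  rates <- assign_branch_rates(tt, rate, 0, 15000, seed = seed)
  list(dates = dates, time_tree = tt, phylogram = to_phylogram(tt, rates),
       rate = rate)
}

# star time-tree with n contemporaneous tips and a given root age; useful
# for controlled branch-duration experiments (polytomies are allowed in
# time_tree, only parent > child ages are required)
star_time_tree <- function(n, root_age = 1e6) {
  phy <- structure(
    list(
      edge = cbind(rep(n + 1L, n), seq_len(n)),
      edge.length = rep(root_age, n),
      tip.label = sprintf("t%03d", seq_len(n)),
      Nnode = 1L
    ),
    class = "phylo", order = "cladewise"
  )
  dates <- tip_dates(stats::setNames(rep(0, n), phy$tip.label))
  time_tree(phy, dates)
}

# ordinary least squares through explicit normal equations (independent of
# lm), returning c(intercept, slope)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# exact one-sample Wilcoxon signed-rank P (two-sided) by enumeration of
# all 2^n sign assignments; requires tie-free |x| and no zeros
wilcoxon_enum_oracle <- function(x) {
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  v_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# exact two-sample Mann-Whitney P (two-sided) by enumeration of all
# rank partitions; tie-free pooled samples only
mwu_enum_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(pooled), nx)
  w_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
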