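# tipclock

Substitution-rate estimation and temporal-signal diagnostics for
tip-dated (heterochronous) sequence data.

## The problem

When a sequence data set mixes modern samples with radiocarbon-dated
ancient ones, the sampling ages of the sequences themselves can calibrate
a molecular clock — no fossil node calibrations are needed. This works
only if the population is *measurably evolving*: the sampling window must
span enough time for detectable change to accumulate. For vertebrate
mitogenomes (rates around 10⁻⁷–10⁻⁸ substitutions/site/year, sampling
windows of tens of thousands of years against roots hundreds of thousands
of years deep) that condition is marginal, and rate estimates are easily
distorted by among-lineage rate variation and by *phylo-temporal
clustering* — similarly aged samples sitting together in the tree.

`tipclock` provides, in one tested package:

* **Simulators** that generate exactly this regime: heterochronous tip
  ages; constant-size serial-coalescent genealogies, optionally with the
  modern samples constrained to be monophyletic (high/low clustering) and
  the root age fixed; independent per-branch rates under a white-noise
  relaxed clock with `Var(n_i) = v · E[n_i]` on the expected substitution
  count of each branch; and HKY+Γ sequence evolution.
* **Estimators**: root-to-tip (RTT) regression with closed-form optimal
  root placement (the root position minimising the regression RSS is
  found exactly on every edge, since each root-to-tip distance is affine
  in the position), and strict-clock least-squares dating (LSD) that
  minimises `Σ wᵢ (bᵢ − r·(τ_child − τ_parent))²` with `wᵢ = 1/(bᵢ + c/s)`
  subject to temporal-precedence constraints, solved by alternating a
  closed-form rate update with an active-set quadratic program. Column
  bootstrap gives percentile intervals for either estimator.
* **Diagnostics**: the date-randomization test with CR1/CR2 pass
  criteria, the phylo-temporal clustering permutation test (Pearson ρ of
  pairwise topological distance vs age difference), and stemminess.
* **Evaluation layer**: standardized errors `(est − true)/true`, their
  one-sample Wilcoxon tests, Kruskal–Wallis and pairwise
  Mann–Whitney–Wilcoxon comparisons across a 12-scenario factorial grid
  (2 rates × 3 variance levels × 2 clustering treatments), proportions of
  estimates above the truth, interval-width ratios, stemminess–error
  correlations, and between-method congruence statistics.

Trees are ape `phylo`/`DNAbin` objects; tabular results are tibbles, and
fitted objects support `tidy()`, `glance()`, and `autoplot()`.

## Worked example

One replicate of the default study conditions — 100 tips, half modern and
half uniform on (0, 50 000] years BP, root fixed at 500 000 years, true
rate 10⁻⁷ subs/site/year with 0.1 % white-noise variance, low clustering,
15 000 nt of HKY+Γ sequence:

```r
library(tipclock)

dates <- simulate_tip_ages(n_tips = 100, frac_modern = 0.5,
                           max_ancient_age = 50000, seed = 1)
sim <- function(a) simulate_clustered_genealogy(dates, "low",
                                                effective_size = 250000,
                                                seed = 2 + a)
genealogy <- condition_root_age(sim(0), target_root_age = 500000,
                                resimulate = sim)
genealogy
#> <time_tree> 100 tips, root age 500000 years BP, 50 ancient tip(s)

rates <- assign_branch_rates(genealogy, mean_rate = 1e-7,
                             variance_fraction = 0.001,
                             seq_length = 15000, seed = 3)
truth <- to_phylogram(genealogy, rates)
aln   <- simulate_alignment(truth, hky_model(), seq_length = 15000, seed = 4)

phy    <- infer_phylogram(aln, gamma = 0.5)   # NJ on gamma-corrected TN93
rooted <- find_best_root(phy, dates)

rtt_regression(rooted, dates)
#> <rate_estimate> method = rtt, rate = 1.04306e-07 subs/site/year
#>   R-squared: 0.5705
#>   inferred TMRCA: 508915 years BP

lsd_estimate(rooted, dates, site_count = 15000)$estimate
#> <rate_estimate> method = lsd, rate = 1.09743e-07 subs/site/year
#>   inferred TMRCA: 481602 years BP

phylo_temporal_clustering(phy, dates, n_perm = 1000, seed = 5)
#> <ptc_test> rho = -0.1190, P = 0.001998 (1000 permutations, two.sided)
```

Both estimators land close to the simulated 10⁻⁷: the standardized errors
are +0.043 (RTT) and +0.097 (LSD), and both inferred root ages bracket
the true 500 000 years. The clustering test reports a small negative ρ —
under low clustering, similarly aged tips are, if anything, slightly
over-dispersed in this replicate.

The full factorial study is one call:

```r
results <- run_scenario_grid(scenario_grid(), n_replicates = 20, seed = 1)
kruskal_wallis_errors(results, "lsd")     # H, df = 11, P
proportion_above_true(results)            # per scenario x method
plot_standardized_errors(results)         # boxplots, faceted by method
```

A thin command-line front end over the same functions ships in
`inst/scripts/tipclock.R` (subcommands `simulate-trees`, `simulate-seqs`,
`estimate`, `diagnose`, `run-grid`, `evaluate`).

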