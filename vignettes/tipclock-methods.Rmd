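---
title: "Models and methods behind tipclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tipclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tipclock)
```

`tipclock` is a simulation-and-estimation toolkit for molecular-clock
calibration from heterochronous sequence data: data sets in which the
sequences themselves were sampled at appreciably different times, as in
ancient-DNA studies of vertebrate mitogenomes. This vignette is the
package's own account of its models, the choices behind them, and what the
tests do and do not establish.

## 1. The sampling scheme and the serial coalescent

`simulate_tip_ages()` draws the sampling design: a fraction `frac_modern`
of tips at age exactly 0 (present-day samples) and the rest i.i.d. uniform
on `(0, max_ancient_age]` years before present. The defaults — 100 tips,
half modern, ancient ages to 50,000 years — describe a typical ancient
mitogenome compilation in which the sampling window is about 10% of the
root age.

`simulate_serial_coalescent()` runs the constant-size coalescent backward
in time. Lineages enter at their sampling ages; while `k ≥ 2` lineages are
active the waiting time to the next coalescence is Exponential with rate
`k(k−1)/(2N)`, truncated at the next tip-entry epoch, and the merging pair
is uniform. `N` (`effective_size`) is the coalescent time-scale parameter
expressed directly in years, so two contemporaneous tips have TMRCA
~ Exponential(mean `N`) — the property the unit tests verify against the
textbook expectations `E[TMRCA] = N` (n = 2) and `N(1 + 1/3)` (n = 3).

**Phylo-temporal clustering** is imposed structurally:
`simulate_clustered_genealogy(level = "high")` first coalesces all modern
tips to their most recent common ancestor and then enters that ancestor as
a single lineage into the serial coalescent of the remaining lineages, so
the modern samples are exactly a clade. `"low"` constrains only half of
the modern tips; *which* half is not determined by the constraint itself,
so we fix the lexicographically first half of the modern labels — the
clade's identity is then deterministic and seed-independent. No
anti-monophyly constraint is imposed on the unconstrained tips: the
treatment is a positive constraint only.

**Root-age conditioning.** The study design fixes the root age (default
500,000 years) but a mechanism has to be chosen. `condition_root_age()`
rescales all internal-node ages by `target/current` while leaving tip ages
untouched. This preserves the coalescent tree shape up to a uniform time
dilation and keeps the calibrating information (the tip ages) exact. When
the factor is below 1 an internal node can be pulled below the age of an
ancient descendant; such genealogies are rejected and resimulated through
a caller-supplied callback, up to `max_rejections` times. An alternative
pure-rejection scheme (accept only genealogies whose unconditioned root
lands within a tolerance window) was considered and not taken: its
acceptance probability is impractically small for a point target. The
default `effective_size = 250000` makes the *expected* unconditioned root
age for 100 tips about `2N(1 − 1/n) ≈ 495,000` years, so the rescale
factor is typically near 1 and rejections are rare.

## 2. Branch rates: the white-noise relaxed clock

`assign_branch_rates()` draws an independent rate for every branch. The
design statement "variance equal to a fraction *v* of the expected number
of substitutions" admits two readings, and both are implemented:

* `mode = "white_noise"` (default): on a branch of duration `d` years with
  `L` sites, the rate variance is `v·μ/(d·L)`, so the expected
  substitution count `n = r·d·L` satisfies `Var(n) = v·E[n]`. The
  inverse-duration variance is the defining signature of a white-noise
  clock: long branches average over more independent rate fluctuation, so
  their *realised* mean rate is closer to μ.
* `mode = "rate_cv"`: constant rate coefficient of variation,
  `Var(r) = v·μ²`, duration-independent.

Rates are Gamma-distributed (two parameters match the mean and variance
exactly; support strictly positive); a lognormal with the same two moments
is available via `family`. `v = 0` returns exactly μ on every branch — the
strict-clock limit used by the identifiability tests. The variance
calibration uses the *configured* `seq_length`; if alignments of another
length are later simulated the rates are not redrawn.

`to_phylogram()` multiplies each duration by its rate to give the true
phylogram in expected substitutions per site.

## 3. Sequence simulation: HKY+Γ

`hky_model()` bundles κ (transition/transversion rate ratio), stationary
base frequencies π (A, C, G, T), the gamma shape α and the number of
discrete categories. The study design specifies HKY+Γ but not its
parameter values; the defaults κ = 10, π = (0.31, 0.31, 0.13, 0.25),
α = 0.5 are values typical of vertebrate mitochondrial genomes, and no
test or acceptance quantity conditions on them. The generator is
normalised so branch lengths are expected substitutions per site
(`Σ πₓ(−qₓₓ) = 1`); transition probabilities come from the symmetric
eigendecomposition of the reversible generator, which is numerically
stable for any branch length. Discrete gamma uses four equal-probability
categories with category-mean rates normalised to mean 1 (the most common
convention); `gamma_shape = Inf` switches heterogeneity off, which the
analytic two-tip mismatch oracle in the tests relies on. Site categories
are i.i.d. per site and fixed across the tree (the standard +Γ
assumption). `simulate_alignment()` is deterministic given its seed down
to byte-identical FASTA output.

## 4. Tree inference stand-in

A full maximum-likelihood tree search is out of scope; the estimators'
input tree comes from neighbour-joining on closed-form pairwise distances
(`ape::dist.dna`), with negative branch lengths clamped to zero. The
default distance is TN93 — the closed-form family that contains HKY — with
an optional gamma-shape correction; the pipeline passes the generating
model's α so the distances account for among-site rate variation (without
the correction, distances and hence both rate estimators are biased
downward by a few percent at these divergences). Any externally inferred
phylogram can be supplied through `read_newick()` instead, reproducing a
two-stage design in which tree inference is done by a dedicated tool.

## 5. Root-to-tip regression with optimal root placement

For a candidate root at position `t` along a fixed edge, every root-to-tip
distance is affine in `t` with slope ±1 (tips on the far side of the edge
get closer, tips behind it get farther). The residual sum of squares of
the regression of distance on time is therefore an exact quadratic in `t`,
minimised in closed form and clamped to the edge; `find_best_root()` scans
all edges and returns the global minimiser, breaking ties by the smallest
edge index in ape's serialisation-stable edge ordering. Root placement
optimises RSS specifically (other software offers R² or correlation
objectives as well; RSS is fixed here and the choice is documented). The
brute-force grid search over every edge × 101 positions is kept as a test
oracle.

`rtt_regression()` is ordinary least squares of root-to-tip distance on
forward time (−age). The slope is the rate; the x-intercept converts to
the TMRCA in years BP. A negative slope is *returned*, with a warning, not
an error — failure to find a positive slope is itself a diagnostic
outcome for data without temporal signal.

## 6. Least-squares dating

`lsd_estimate()` minimises

\[
\sum_i w_i\,\bigl(b_i - r\,(\tau_{c(i)} - \tau_{p(i)})\bigr)^2,
\qquad w_i = \frac{1}{b_i + c/s},
\]

over the rate `r > 0` and forward-time node positions τ, with tip times
fixed at their dates and `τ_child ≥ τ_parent` on every branch. The weights
approximate the inverse variance of a branch length estimated from `s`
sites (Poisson sampling noise, plus the offset `c`, default 10, guarding
short branches). The solver alternates:

1. **Time step** (fixed `r`): a convex QP in τ, solved by a primal
   active-set method in substitution-scaled time `θ = r·τ`. Nodes joined
   by active (binding) precedence constraints are contracted into groups;
   groups containing a tip are anchored at the tip's time; the free groups
   solve a small dense weighted-Laplacian system. A feasibility line
   search adds the first blocking constraint; Lagrange multipliers —
   computed as gradient sums over the child-side component of each active
   edge — decide releases. The active set is warm-started between
   iterations.
2. **Rate step** (fixed τ): the closed form
   `r = Σ wᵢbᵢΔᵢ / Σ wᵢΔᵢ²`, projected onto `r ≥ 10⁻¹⁵` (rate positivity
   by projection; RTT, by contrast, is deliberately allowed to go
   negative).

Iteration stops when the objective improves by less than 10⁻¹² relative.
The rate is initialised from the RTT slope, which makes the noiseless
strict-clock case converge essentially in one step. Documented properties,
all tested: exact recovery on noiseless clocklike input; invariance under
uniform date translation; inverse scaling of the rate under uniform date
scaling; agreement with a brute-force grid minimiser on 3–4-tip
instances. Equivalence is asserted against the stated objective, not
against any particular external implementation's iteration schedule.

The dated tree keeps tip ages exact and may contain zero-duration
branches where precedence constraints bind.

## 7. Temporal-signal diagnostics

**Phylo-temporal clustering.** For all tip pairs, distance is the number
of *edges* on the path between them. (A "number of nodes separating two
tips" convention differs by exactly one per pair — a constant shift that
leaves the correlation almost unchanged; the edge count is used because it
is the stable convention across tree libraries.) The statistic is
Pearson's ρ against the absolute age difference over all pairs; raw pairs
are used without decorrelation, since the permutation null — ages permuted
across tips, preserving the age multiset — absorbs the pair
non-independence. The P-value uses the add-one correction
`(1 + #extreme)/(1 + B)` so it can never be zero, and is two-sided by
default (`alternative = "greater"` gives the positive-clustering
one-sided version).

**Date-randomization test.** The rate is estimated with the true dates,
then `n_reps` times (default 20) with dates permuted uniformly across
tips; every estimate carries a column-bootstrap percentile interval. CR1
passes when the original *point* estimate lies outside **all** replicate
intervals — the strict reading of the criterion; an "outside ≥95% of
intervals" relaxation was considered and rejected as the weaker reading.
CR2 passes when the original *interval* is disjoint from all replicate
intervals, so CR2 ⇒ CR1 structurally. The bootstrap replicate count is a
separate knob from the randomization count: the former controls interval
resolution, the latter the test's resolution (with 20 replicates the
smallest achievable "P" is effectively 1/21).

**Stemminess** is the proportion of total tree length in internal edges;
trees with high stemminess have short terminal branches and carry less
calibrating information per tip.

## 8. The evaluation layer and the scenario grid

`standardized_error()` is `(estimate − true)/true`. `run_scenario_grid()`
crosses {10⁻⁷, 10⁻⁸ subs/site/year} × {0.1%, 1%, 10% variance} ×
{low, high clustering} — 12 scenarios — and runs the full pipeline per
replicate, deriving per-replicate, per-stage seeds arithmetically from the
master seed so a rerun is byte-identical. A replicate whose estimation
fails contributes a missing record, never a sentinel value. Hypothesis
tests ride on base R: `wilcox.test` (one-sample, exact for small tie-free
samples), `kruskal.test` (tie-corrected H, df = groups − 1, so 11 on the
full grid), and pairwise Mann–Whitney tests with Holm correction by
default (raw P-values are also available — no correction convention is
assumed for the pairwise tables). "Spread" summaries use the
interquartile range.

## 9. Problem sizes, tolerances and degenerate inputs

The packaged experiments run at deliberately reduced replication chosen as
sensible demonstration sizes: the structural Kruskal–Wallis check uses
12 scenarios × 5 replicates at 2,000 nt; the parameter-recovery check
(rate 10⁻⁷, v = 0.1%, low clustering) and the directional-bias check
(rate 10⁻⁸, high clustering, all three v levels) use 20 replicates per
scenario at the full 15,000 nt. Monte-Carlo tests use 3-standard-error
bands or Kolmogorov–Smirnov calibration at α = 0.01.

Numerical conventions: root-age conditioning is exact to relative 10⁻¹²;
transition-probability rows are clamped to [0, 1] and renormalised after
the eigendecomposition round trip; NJ's negative branch lengths are
clamped to zero; LSD ties at precedence boundaries are contracted exactly;
all-equal tip dates raise a no-temporal-spread error in every estimator
and diagnostic; a zero-length tree makes stemminess error rather than
return 0/0; an all-identical alignment infers a zero-length star with a
warning and yields a degenerate (zero-width) bootstrap interval.

## 10. What the simulations do and do not show

The generator emulates the structure of ancient-DNA mitogenome studies:
heterochronous sampling with a bounded window, a deep fixed-age root,
constant population size, a single non-recombining locus, white-noise rate
variation, and HKY+Γ substitution. It does **not** simulate post-mortem
damage, sequencing error, indels, partition structure, demographic change
(bottlenecks, growth), autocorrelated rate variation, or recombination.
Passing tests therefore establish internal correctness of the methods and
reproduce the qualitative behaviour of the estimators under the stated
regime — accurate recovery at high rates with low clustering, systematic
LSD underestimation at low rates with high clustering — but say nothing
about robustness to damage patterns or demographic misspecification in
real data. Bayesian inference (relaxed clocks, MCMC, marginal-likelihood
model selection) is intentionally outside the package's scope; the
bootstrap intervals here generalise interval-based criteria to the two
fast estimators but are not posterior credibility intervals.
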