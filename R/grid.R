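#' Default simulation scenario grid
#'
#' Full cross of mean substitution rate, white-noise variance fraction, and
#' phylo-temporal clustering level: the default 2 x 3 x 2 = 12 scenarios
#' span high (1e-7) and low (1e-8 subs/site/year) rates, low/medium/high
#' rate variation (0.1%, 1%, 10% of the expected number of substitutions)
#' and low/high clustering.
#'
#' @param mean_rates Mean rates (subs/site/year).
#' @param variance_fractions White-noise variance fractions.
#' @param clustering Clustering levels (subset of `"none"`, `"low"`,
#'   `"high"`).
#' @return A tibble with columns `scenario_id`, `mean_rate`,
#'   `variance_fraction`, `clustering`.
#' @export
scenario_grid <- function(mean_rates = c(1e-7, 1e-8),
                          variance_fractions = c(0.001, 0.01, 0.1),
                          clustering = c("low", "high")) {
  grid <- tidyr::expand_grid(
    mean_rate = mean_rates,
    variance_fraction = variance_fractions,
    clustering = clustering
  )
  dplyr::mutate(
    grid,
    scenario_id = sprintf("rate%s_v%s_clust%s",
                          format(.data$mean_rate, scientific = TRUE),
                          format(.data$variance_fraction),
                          .data$clustering),
    .before = 1
  )
}

#' Run the full simulation-estimation pipeline over a scenario grid
#'
#' For every scenario and replicate: simulate tip ages, a (possibly
#' clustered) serial-coalescent genealogy conditioned on the root age,
#' white-noise branch rates, and an HKY+Gamma alignment; infer a phylogram,
#' place the root, and estimate the rate by root-to-tip regression and
#' least-squares dating; attach stemminess and the phylo-temporal
#' clustering statistic of the inferred tree. Per-replicate seeds are
#' derived deterministically from `seed`, so a re-run reproduces the table
#' exactly. Replicates whose estimation fails are recorded with missing
#' estimates rather than aborting the grid.
#'
#' @param grid Scenario tibble from [scenario_grid()].
#' @param n_replicates Replicates per scenario.
#' @param seed Master seed.
#' @param n_tips,frac_modern,max_ancient_age,root_age Sampling-scheme and
#'   conditioning parameters (defaults: 100 tips, half modern, ancient ages
#'   to 50,000 y, root fixed at 500,000 y).
#' @param effective_size Coalescent time-scale parameter (years).
#' @param seq_length Alignment length (nt).
#' @param model An [hky_model()].
#' @param dist_model Distance model for tree inference.
#' @param lsd_c LSD weight offset.
#' @param n_perm Permutations for the clustering diagnostic.
#' @param max_rejections Root-age conditioning rejection budget.
#' @return A long-format tibble: one row per scenario x replicate x method
#'   with `estimate`, `true_rate`, `std_error`, `stemminess`, `clust_rho`,
#'   `clust_p`, and the true genealogy's root age.
#' @export
run_scenario_grid <- function(grid = scenario_grid(), n_replicates = 5L,
                              seed = 1L, n_tips = 100L, frac_modern = 0.5,
                              max_ancient_age = 50000, root_age = 500000,
                              effective_size = 250000, seq_length = 15000,
                              model = hky_model(), dist_model = "TN93",
                              lsd_c = 10, n_perm = 1000L,
                              max_rejections = 100L) {
  if (n_replicates < 1) rlang::abort("`n_replicates` must be >= 1.")
  rows <- purrr::map(seq_len(nrow(grid)), function(si) {
    sc <- grid[si, ]
    purrr::map(seq_len(n_replicates), function(rep_i) {
      res <- tryCatch(
        run_single_replicate(
          mean_rate = sc$mean_rate, variance_fraction = sc$variance_fraction,
          clustering = sc$clustering,
          seed = derive_seed(seed, si, rep_i),
          n_tips = n_tips, frac_modern = frac_modern,
          max_ancient_age = max_ancient_age, root_age = root_age,
          effective_size = effective_size, seq_length = seq_length,
          model = model, dist_model = dist_model, lsd_c = lsd_c,
          n_perm = n_perm, max_rejections = max_rejections
        ),
        error = function(e) {
          rlang::warn(sprintf("replicate failed (%s, rep %d): %s",
                              sc$scenario_id, rep_i, conditionMessage(e)))
          NULL
        }
      )
      if (is.null(res)) return(NULL)
      dplyr::mutate(res, scenario_id = sc$scenario_id,
                    mean_rate = sc$mean_rate,
                    variance_fraction = sc$variance_fraction,
                    clustering = sc$clustering, replicate = rep_i,
                    .before = 1)
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

# deterministic per-replicate seed spawning, kept below 2^31
derive_seed <- function(master, scenario_idx, replicate, stage = 0L) {
  (as.numeric(master) * 1000003 + scenario_idx * 1009 +
     replicate * 7919 + stage * 101) %% 2147483629
}

run_single_replicate <- function(mean_rate, variance_fraction, clustering,
                                 seed, n_tips, frac_modern, max_ancient_age,
                                 root_age, effective_size, seq_length, model,
                                 dist_model, lsd_c, n_perm, max_rejections) {
  dates <- simulate_tip_ages(n_tips, frac_modern, max_ancient_age,
                             seed = derive_seed(seed, 0, 0, 1))
  sim_tree <- function(attempt) {
    simulate_clustered_genealogy(dates, clustering, effective_size,
                                 seed = derive_seed(seed, 0, attempt, 2))
  }
  tt <- condition_root_age(sim_tree(0), root_age, max_rejections,
                           resimulate = sim_tree)
  rates <- assign_branch_rates(tt, mean_rate, variance_fraction,
                               seq_length = seq_length,
                               seed = derive_seed(seed, 0, 0, 3))
  truth <- to_phylogram(tt, rates)
  aln <- simulate_alignment(truth, model, seq_length,
                            seed = derive_seed(seed, 0, 0, 4))
  phy <- infer_phylogram(aln, dist_model, gamma = model$gamma_shape)
  rooted <- find_best_root(phy, dates)
  stem <- stemminess(phy)
  ptc <- phylo_temporal_clustering(phy, dates, n_perm = n_perm,
                                   seed = derive_seed(seed, 0, 0, 5))
  ests <- list(
    rtt = tryCatch(suppressWarnings(rtt_regression(rooted, dates)$rate),
                   error = function(e) NA_real_),
    lsd = tryCatch(
      lsd_estimate(rooted, dates, site_count = seq_length,
                   variance_offset_c = lsd_c)$estimate$rate,
      error = function(e) NA_real_
    )
  )
  tibble::tibble(
    method = names(ests),
    estimate = unlist(ests, use.names = FALSE),
    true_rate = mean_rate,
    std_error = standardized_error(unlist(ests, use.names = FALSE), mean_rate),
    stemminess = stem,
    clust_rho = ptc$rho,
    clust_p = ptc$p_value,
    true_root_age = unname(tt$ages[ape::Ntip(tt$phy) + 1L])
  )
}
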