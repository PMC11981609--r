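# Shared fixture builders. All data are generated in code at test time.

# simulate and assemble one ready-to-fit position dataset
sim_position_dataset <- function(position = 1, ..., offsets = "stop") {
  cfg <- sim_config(...)
  sim <- simulate_counts(cfg)
  samples <- if (offsets == "stop") compute_offsets(sim$counts, sim$samples)
             else { sim$samples$offset <- 0; sim$samples }
  list(pd = build_position_dataset(sim$counts, position, samples),
       sim = sim, samples = samples)
}

# small fixtures for the likelihood-oracle comparisons (<= 10 barcodes)
tiny_fixture_configs <- function() {
  list(
    list(n_positions = 1, n_variants_per_position = 2,
         barcodes_per_variant = 3, wt_barcodes_per_subregion = 4,
         conditions = "c1", condition_effects = 0,
         replicates_per_condition = 4, sigma = 0.4, theta = 8,
         baseline_mean = 100, offset_jitter = 0.1, seed = 101),
    list(n_positions = 1, n_variants_per_position = 2,
         barcodes_per_variant = 3, wt_barcodes_per_subregion = 4,
         conditions = c("c1", "c2"), condition_effects = c(0, log(2)),
         replicates_per_condition = 2, sigma = 0.3, theta = 10,
         baseline_mean = 80, offset_jitter = 0.2, seed = 102),
    list(n_positions = 1, n_variants_per_position = 2,
         barcodes_per_variant = 4, wt_barcodes_per_subregion = 2,
         conditions = "c1", condition_effects = 0,
         replicates_per_condition = 6, sigma = 0.6, theta = 5,
         baseline_mean = 60, offset_jitter = 0.1, seed = 103),
    list(n_positions = 1, n_variants_per_position = 3,
         barcodes_per_variant = 2, wt_barcodes_per_subregion = 4,
         conditions = "c1", condition_effects = 0,
         replicates_per_condition = 4, sigma = 0.5, theta = 12,
         baseline_mean = 120, offset_jitter = 0.15, seed = 104),
    list(n_positions = 1, n_variants_per_position = 2,
         barcodes_per_variant = 3, wt_barcodes_per_subregion = 3,
         conditions = c("c1", "c2"), condition_effects = c(0, log(3)),
         replicates_per_condition = 3, sigma = 0.4, theta = 6,
         baseline_mean = 90, offset_jitter = 0.1, seed = 105))
}

# hand-constructed position_fit for arithmetic checks of downstream
# operations (marginal means, contrasts, effect conversion)
fake_fit <- function(beta, cov, conditions, variants, position = 1,
                     mean_offset = 0) {
  estimable <- matrix(TRUE, length(variants), length(conditions),
                      dimnames = list(variants, conditions))
  structure(list(beta = beta, cov = cov, sigma2 = 0.1, theta = 5,
                 loglik = 0, converged = TRUE, estimable = estimable,
                 conditions = conditions, variants = variants,
                 position = position, subregion = "S1",
                 mean_offset = mean_offset, n_obs = 0, n_barcodes = 0),
            class = "position_fit")
}
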