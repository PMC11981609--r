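test_that("configuration validation rejects degenerate parameters", {
  expect_error(sim_config(theta = 0), "theta")
  expect_error(sim_config(theta = -2), "theta")
  expect_error(sim_config(baseline_mean = 0), "baseline_mean")
  expect_error(sim_config(dropout_prob = 1), "dropout_prob")
  expect_error(sim_config(sigma = -0.1), "sigma")
  expect_error(sim_config(conditions = c("a", "b"),
                          condition_effects = 0), "condition_effects")
})

test_that("null configuration reproduces the baseline mean and is deterministic", {
  cfg <- sim_config(n_positions = 2, n_variants_per_position = 3,
                    barcodes_per_variant = 40, conditions = "c1",
                    condition_effects = 0, replicates_per_condition = 4,
                    sigma = 0, theta = 1e6, baseline_mean = 50,
                    offset_jitter = 0, seed = 11)
  sim <- simulate_counts(cfg)
  cnt <- as.matrix(sim$counts[, sim$samples$sample_id])
  mc_se <- sd(cnt) / sqrt(length(cnt))
  expect_lt(abs(mean(cnt) - 50), 3 * mc_se)

  sim2 <- simulate_counts(cfg)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$truth$barcode_intercepts,
                   sim2$truth$barcode_intercepts)
})

test_that("counts obey the NB mean/dispersion variance identity", {
  # theta = 2, mu = 50: Var = 50 + 50^2/2 = 1300
  cfg <- sim_config(n_positions = 1, n_variants_per_position = 2,
                    barcodes_per_variant = 1500,
                    wt_barcodes_per_subregion = 2000, conditions = "c1",
                    condition_effects = 0, replicates_per_condition = 2,
                    sigma = 0, theta = 2, baseline_mean = 50,
                    offset_jitter = 0, seed = 21)
  sim <- simulate_counts(cfg)
  cnt <- as.matrix(sim$counts[, sim$samples$sample_id])
  expect_gte(length(cnt), 10000)
  expect_lt(abs(var(as.numeric(cnt)) / 1300 - 1), 0.10)
})

test_that("barcode intercepts are shared across all samples of a barcode", {
  cfg <- sim_config(n_positions = 1, n_variants_per_position = 3,
                    barcodes_per_variant = 50, conditions = "c1",
                    condition_effects = 0, replicates_per_condition = 8,
                    sigma = 0.8, theta = 1e6, baseline_mean = 200,
                    offset_jitter = 0, seed = 31)
  sim <- simulate_counts(cfg)
  cnt <- as.matrix(sim$counts[, sim$samples$sample_id])
  alpha <- sim$truth$barcode_intercepts[sim$counts$barcode]
  # per-barcode mean across samples tracks exp(alpha_k)
  expect_gt(cor(log(rowMeans(cnt)), alpha), 0.99)
})

test_that("stop variants are shifted by exactly the configured effect on the mean scale", {
  cfg <- sim_config(n_positions = 2, n_variants_per_position = 4,
                    barcodes_per_variant = 400,
                    conditions = c("basal", "stim"),
                    condition_effects = c(0, log(4)),
                    replicates_per_condition = 2, sigma = 0, theta = 50,
                    baseline_mean = 100, offset_jitter = 0,
                    nonsense_effect = -1.5, seed = 41)
  sim <- simulate_counts(cfg)
  is_stop <- grepl("\\*$", sim$counts$variant)
  stim_cols <- sim$samples$sample_id[sim$samples$condition == "stim"]
  stop_mean <- mean(as.matrix(sim$counts[is_stop, stim_cols]))
  expected <- 100 * exp(log(4) - 1.5)
  expect_lt(abs(stop_mean / expected - 1), 0.05)
})

test_that("default nonsense rule keeps stop counts constant across conditions", {
  cfg <- sim_config(n_positions = 1, n_variants_per_position = 4,
                    barcodes_per_variant = 500,
                    conditions = c("basal", "stim"),
                    condition_effects = c(0, log(4)),
                    replicates_per_condition = 2, sigma = 0, theta = 50,
                    baseline_mean = 100, offset_jitter = 0, seed = 42)
  sim <- simulate_counts(cfg)
  is_stop <- grepl("\\*$", sim$counts$variant)
  basal <- sim$samples$sample_id[sim$samples$condition == "basal"]
  stim <- sim$samples$sample_id[sim$samples$condition == "stim"]
  ratio <- mean(as.matrix(sim$counts[is_stop, stim])) /
    mean(as.matrix(sim$counts[is_stop, basal]))
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("dropout removes barcodes from the map entirely", {
  cfg <- sim_config(n_positions = 2, n_variants_per_position = 4,
                    barcodes_per_variant = 100, dropout_prob = 0.3,
                    seed = 51)
  sim <- simulate_counts(cfg)
  full <- simulate_counts(sim_config(n_positions = 2,
                                     n_variants_per_position = 4,
                                     barcodes_per_variant = 100,
                                     dropout_prob = 0, seed = 51))
  expect_lt(nrow(sim$counts), nrow(full$counts))
  # every surviving barcode maps to exactly one variant
  expect_false(anyDuplicated(sim$truth$variant_barcode_assignment$barcode) > 0)
  # WT truth is 0 everywhere
  expect_true(all(sim$truth$true_effects["WT", ] == 0))
})

test_that("simulate_reads emits barcode+insert with controlled chimera and error rates", {
  cfg <- sim_config(n_positions = 2, n_variants_per_position = 3,
                    barcodes_per_variant = 5, seed = 61)
  sim <- simulate_counts(cfg)
  rd <- simulate_reads(sim$truth, sim$design, n_reads = 2000,
                       chimera_rate = 0, error_rate = 0, seed = 7)
  ass <- sim$truth$variant_barcode_assignment
  ex <- extract_barcodes(rd$reads)
  expect_identical(ex$barcode, rd$read_info$barcode)
  oligo <- sim$design$oligo_id[match(ex$insert, sim$design$insert_seq)]
  expect_identical(oligo, ass$oligo_id[match(ex$barcode, ass$barcode)])

  rd2 <- simulate_reads(sim$truth, sim$design, n_reads = 4000,
                        chimera_rate = 0.5, error_rate = 0, seed = 8)
  frac <- mean(rd2$read_info$chimeric)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))

  rd3 <- simulate_reads(sim$truth, sim$design, n_reads = 500,
                        chimera_rate = 0.1, error_rate = 0.01, seed = 9)
  rd4 <- simulate_reads(sim$truth, sim$design, n_reads = 500,
                        chimera_rate = 0.1, error_rate = 0.01, seed = 9)
  expect_identical(rd3$reads, rd4$reads)

  expect_error(simulate_reads(sim$truth, sim$design[0, ], 10, 0, 0, 1),
               "empty design")
  expect_error(simulate_reads(sim$truth, sim$design, 10,
                              chimera_rate = 1, error_rate = 0), "chimera")
})

test_that("FASTQ round trip preserves sequences byte-for-byte", {
  reads <- c("ACGTACGTAA", "TTTTCCCCGG")
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  expect_identical(read_fastq(path), reads)
})
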