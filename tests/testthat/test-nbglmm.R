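test_that("analytic fixed-effect gradient matches the numeric gradient", {
  fx <- sim_position_dataset(n_positions = 1, n_variants_per_position = 3,
                             barcodes_per_variant = 4,
                             replicates_per_condition = 2, seed = 201)
  pd <- fx$pd
  long <- pd$long[order(pd$long$barcode, pd$long$sample_id), ]
  conds <- pd$conditions
  dev_names <- as.vector(t(outer(pd$variants, conds, paste, sep = "|")))
  cond_i <- as.integer(match(long$condition, conds))
  key <- paste(long$variant, long$condition, sep = "|")
  dev_i <- ifelse(long$variant == "WT", 0L,
                  length(conds) + match(key, dev_names))
  bs <- as.integer(c(0, cumsum(table(factor(long$barcode,
                                            levels = unique(long$barcode))))))
  par <- c(rep(2.5, length(conds)), rnorm(length(dev_names), 0, 0.3),
           log(0.4), log(5))
  g_fast <- bardms:::nbml_nll_grad(par, as.numeric(long$count), cond_i,
                                   as.integer(dev_i), long$offset, bs)
  g_num <- bardms:::nbml_grad(par, as.numeric(long$count), cond_i,
                              as.integer(dev_i), long$offset, bs)
  expect_equal(g_fast$grad, g_num, tolerance = 1e-5)
  nll <- bardms:::nbml_nll(par, as.numeric(long$count), cond_i,
                           as.integer(dev_i), long$offset, bs)
  expect_equal(g_fast$nll, nll)
})

test_that("position dataset includes subregion WT barcodes and counts rows", {
  fx <- sim_position_dataset(n_positions = 2, n_variants_per_position = 4,
                             barcodes_per_variant = 5,
                             wt_barcodes_per_subregion = 7, seed = 202)
  pd <- fx$pd
  n_bc <- length(unique(pd$long$barcode))
  expect_equal(n_bc, 4 * 5 + 7)
  expect_equal(nrow(pd$long), n_bc * nrow(fx$samples))
  expect_true("WT" %in% pd$long$variant)
  expect_error(build_position_dataset(fx$sim$counts, 999, fx$samples),
               "no variants")
})

test_that("degenerate limit matches the closed-form log mean ratio", {
  # sigma = 0, theta huge, one condition, equal offsets: the ML deviation
  # is exactly log(mean variant counts) - log(mean WT counts)
  fx <- sim_position_dataset(n_positions = 1, n_variants_per_position = 3,
                             barcodes_per_variant = 20,
                             conditions = "c1", condition_effects = 0,
                             replicates_per_condition = 4, sigma = 0,
                             theta = 1e6, baseline_mean = 100,
                             offset_jitter = 0, seed = 203,
                             offsets = "zero")
  pd <- fx$pd
  fit <- fit_position_model(pd)
  expect_lt(fit$sigma2, 1e-3)
  long <- pd$long
  wt_mean <- mean(long$count[long$variant == "WT"])
  for (v in pd$variants) {
    closed <- log(mean(long$count[long$variant == v])) - log(wt_mean)
    expect_lt(abs(fit$beta[paste0(v, "|c1")] - closed), 1e-3)
  }
})

test_that("sigma = 0 data reduce to the fixed-effect NB GLM oracle", {
  skip_if_not_installed("MASS")
  fx <- sim_position_dataset(n_positions = 1, n_variants_per_position = 4,
                             barcodes_per_variant = 15,
                             replicates_per_condition = 3, sigma = 0,
                             theta = 8, baseline_mean = 60, seed = 204)
  fit <- fit_position_model(fx$pd)
  expect_lt(fit$sigma2, 1e-3)
  oracle <- glm_nb_oracle(fx$pd)
  shared <- intersect(names(oracle), names(fit$beta))
  expect_gt(length(shared), 5)
  expect_lt(max(abs(fit$beta[shared] - oracle[shared])), 1e-2)
})

test_that("effect_table converts natural-log fits to log2 Wald inference", {
  beta <- c(c1 = log(50), "1_AK|c1" = 0.6931472)
  cov <- diag(c(0.01, 0.3466^2))
  dimnames(cov) <- list(names(beta), names(beta))
  fit <- fake_fit(beta, cov, conditions = "c1", variants = "1_AK")
  eff <- effect_table(fit)
  expect_equal(eff$log2fc, 1.0, tolerance = 1e-6)
  expect_equal(eff$se, 0.5, tolerance = 1e-4)
  expect_equal(eff$z, 2.0, tolerance = 1e-3)
  expect_equal(eff$p, 2 * pnorm(-2), tolerance = 1e-3)
  # zero estimate -> p = 1
  fit0 <- fake_fit(c(c1 = log(50), "1_AK|c1" = 0), cov,
                   conditions = "c1", variants = "1_AK")
  expect_equal(effect_table(fit0)$p, 1)
})

test_that("BH adjustment is the standard step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               ignore_attr = TRUE)
  expect_equal(bh_adjust(0.2), 0.2, ignore_attr = TRUE)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5), ignore_attr = TRUE)
  q <- bh_adjust(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(attr(q, "n_na"), 1)
  expect_error(bh_adjust(c(0.5, 1.2)), "must be in")
  # q >= p always
  set.seed(1)
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("classification follows the sign/FDR rule", {
  eff <- data.frame(log2fc = c(-2, 1, 0.5, -1), se = 1,
                    q = c(0.001, 0.5, 0.005, NA),
                    estimable = c(TRUE, TRUE, TRUE, FALSE))
  cls <- classify_variants(eff, fdr = 0.01)$class
  expect_equal(cls, c("LoF", "WT-like", "GoF", "NA"))
})

test_that("residue sensitivity follows the stated formula", {
  eff <- data.frame(variant = c("5_AK", "5_AL", "5_A*"), position = 5,
                    condition = "c1", log2fc = c(-1, -2, -6),
                    se = c(0.1, 0.2, 0.1), estimable = TRUE)
  # nonsense excluded: mean(-1,-2)/sqrt(0.01+0.04)
  expect_equal(residue_sensitivity(eff, 5), -1.5 / sqrt(0.05),
               tolerance = 1e-9)
  eff$log2fc <- c(0, 0, -6)
  expect_equal(residue_sensitivity(eff, 5), 0)
  eff$estimable <- c(FALSE, FALSE, TRUE)
  expect_true(is.na(residue_sensitivity(eff, 5)))
})

test_that("downsampling is a seeded uniform subset with guards", {
  fx <- sim_position_dataset(n_positions = 1, n_variants_per_position = 3,
                             barcodes_per_variant = 10, seed = 205)
  pd <- fx$pd
  all_bc <- unique(pd$long$barcode)
  full <- downsample_barcodes(pd, 10, seed = 1)
  expect_setequal(unique(full$long$barcode), all_bc)
  d1 <- downsample_barcodes(pd, 4, seed = 2)
  d2 <- downsample_barcodes(pd, 4, seed = 2)
  expect_identical(d1$long, d2$long)
  per_var <- table(unique(d1$long[, c("barcode", "variant")])$variant)
  expect_true(all(per_var == 4))
  expect_error(downsample_barcodes(pd, 1, seed = 1), ">= 2")
  expect_error(downsample_barcodes(pd, 11, seed = 1), "exceeds")
})

test_that("effect estimates are invariant to per-sample depth rescaling", {
  fx <- sim_position_dataset(n_positions = 1, n_variants_per_position = 3,
                             barcodes_per_variant = 8,
                             replicates_per_condition = 2,
                             baseline_mean = 40, seed = 206)
  fit1 <- fit_position_model(fx$pd)
  # quadruple every count and add log(4) to every offset: the offset
  # absorbs the depth change and all effects are preserved
  counts2 <- fx$sim$counts
  samples2 <- fx$samples
  for (s in samples2$sample_id) counts2[[s]] <- counts2[[s]] * 4L
  samples2$offset <- samples2$offset + log(4)
  fit2 <- fit_position_model(build_position_dataset(counts2, 1, samples2))
  key <- grep("\\|", names(fit1$beta), value = TRUE)
  # scaling counts deterministically perturbs the fitted dispersion (a
  # 4x-scaled NB draw is itself overdispersed), which reweights samples
  # within a cell; the offset absorbs the depth change up to that ~<1%
  # second-order effect, exact only with the dispersion held fixed
  expect_equal(fit1$beta[key], fit2$beta[key], tolerance = 0.01)
})

test_that("all-zero variant-condition cells are flagged non-estimable", {
  fx <- sim_position_dataset(n_positions = 1, n_variants_per_position = 3,
                             barcodes_per_variant = 5,
                             replicates_per_condition = 2, seed = 207)
  counts <- fx$sim$counts
  v <- fx$pd$variants[1]
  cond1 <- unique(fx$samples$condition)[1]
  cols <- fx$samples$sample_id[fx$samples$condition == cond1]
  counts[counts$variant == v, cols] <- 0L
  fit <- fit_position_model(build_position_dataset(counts, 1, fx$samples))
  expect_false(fit$estimable[v, cond1])
  eff <- effect_table(fit)
  row <- eff[eff$variant == v & eff$condition == cond1, ]
  expect_false(row$estimable)
  expect_true(is.na(row$log2fc))
  # non-estimable rows are excluded from the BH denominator
  expect_true(all(is.na(eff$q[!eff$estimable])))
})

test_that("null simulation yields roughly standard-normal Wald statistics", {
  fx <- sim_position_dataset(n_positions = 3, n_variants_per_position = 5,
                             barcodes_per_variant = 10,
                             replicates_per_condition = 2,
                             condition_effects = c(0, 0), seed = 208)
  fits <- lapply(1:3, function(p)
    fit_position_model(build_position_dataset(fx$sim$counts, p,
                                              fx$samples)))
  eff <- effect_table(fits)
  z <- eff$z[eff$estimable]
  expect_lt(abs(mean(z)), 0.35)
  expect_gt(sd(z), 0.7)
  expect_lt(sd(z), 1.35)
})
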