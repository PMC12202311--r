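test_that("invalid generator configurations name the violated invariant", {
  expect_error(generator_config(n_informative = 20, n_metabolites = 10),
               "n_informative")
  expect_error(generator_config(target_auc_range = c(0.4, 0.7)),
               "target_auc_range")
  expect_error(generator_config(block_sizes = rep(100L, 10L),
                                n_metabolites = 50), "block_sizes")
  expect_error(generator_config(missing_rate = 0.6), "missing_rate")
  expect_error(generator_config(within_block_correlation = 1),
               "within_block_correlation")
})

test_that("identical config and seed reproduce the dataset bit-for-bit", {
  cfg <- generator_config(n_group_a = 20, n_group_b = 30, n_metabolites = 25,
                          n_informative = 5, n_days = 4, seed = 7)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$matrix, d2$matrix)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$truth, d2$truth)
})

test_that("no planted effect gives empty truth and chance-level AUC", {
  ds <- generate_dataset(generator_config(
    n_group_a = 150, n_group_b = 150, n_metabolites = 20, n_informative = 0,
    missing_rate = 0, outlier_rate = 0, day_effect_sd = 0,
    weight_slope_sd = 0, n_days = 3, seed = 3))
  expect_length(ds$truth$informative_ids, 0)
  expect_false(anyNA(ds$matrix))
  raw_auc <- apply(ds$matrix, 2L, metabolite_auc, y = ds$metadata$group,
                   fold = FALSE)
  # Monte-Carlo error of a null AUC at n = 150/150 is ~0.033
  expect_true(all(abs(raw_auc - 0.5) < 0.12))
  expect_lt(abs(mean(raw_auc) - 0.5), 0.04)
})

test_that("shift_for_target_auc inverts the equal-variance normal AUC", {
  expect_identical(shift_for_target_auc(0.5), 0)
  expect_equal(shift_for_target_auc(0.70), 0.7416, tolerance = 1e-4)
  aucs <- seq(0.5, 0.95, by = 0.05)
  expect_true(all(diff(shift_for_target_auc(aucs)) > 0))
  expect_error(shift_for_target_auc(0.4), "0.5")
  expect_error(shift_for_target_auc(1), "0.5")
  # round trip: pnorm(d / sqrt(2)) recovers the AUC
  expect_equal(pnorm(shift_for_target_auc(0.65) / sqrt(2)), 0.65)
})

test_that("planted shifts reproduce their target AUC empirically", {
  ds <- generate_dataset(generator_config(
    n_group_a = 10000, n_group_b = 10000, n_metabolites = 2,
    n_informative = 1, target_auc_range = c(0.65, 0.65),
    block_sizes = integer(0), day_effect_sd = 0, weight_slope_sd = 0,
    missing_rate = 0, outlier_rate = 0, n_days = 2, seed = 21))
  id <- ds$truth$informative_ids
  auc <- metabolite_auc(ds$matrix[, id], ds$metadata$group)
  expect_gte(auc, 0.64)
  expect_lte(auc, 0.66)
})

test_that("class counts, day levels and weight moments match the config", {
  cfg <- generator_config(n_group_a = 200, n_group_b = 400,
                          n_metabolites = 10, n_informative = 2,
                          n_days = 6, weight_mean_kg = 155, weight_sd_kg = 5,
                          seed = 5)
  ds <- generate_dataset(cfg)
  expect_identical(as.integer(table(ds$metadata$group)), c(200L, 400L))
  expect_identical(nlevels(ds$metadata$day), 6L)
  expect_lt(abs(mean(ds$metadata$weight_kg) - 155), 5 / sqrt(600) * 4)
  expect_lt(abs(sd(ds$metadata$weight_kg) - 5), 1)
})

test_that("clean configs stay inside the 5xIQR bound; outliers are flagged", {
  clean <- generate_dataset(generator_config(
    n_group_a = 100, n_group_b = 100, n_metabolites = 30, n_informative = 0,
    missing_rate = 0, outlier_rate = 0, n_days = 3, seed = 9))
  masked <- mask_outliers(clean$matrix)
  expect_lte(masked$report$n_outliers_masked / length(clean$matrix), 0.002)

  dirty <- generate_dataset(generator_config(
    n_group_a = 100, n_group_b = 100, n_metabolites = 30, n_informative = 0,
    missing_rate = 0, outlier_rate = 0.01, n_days = 3, seed = 9))
  n_injected <- sum(dirty$matrix != clean$matrix, na.rm = TRUE)
  expect_gt(n_injected, 0)
  flagged <- mask_outliers(dirty$matrix)$report$n_outliers_masked
  expect_gte(flagged, n_injected) # every injected cell must be flagged
})

test_that("censored missingness hits low abundances preferentially", {
  cfg_base <- list(n_group_a = 150, n_group_b = 150, n_metabolites = 20,
                   n_informative = 0, n_days = 3, missing_rate = 0.2,
                   outlier_rate = 0, seed = 13)
  cens <- generate_dataset(do.call(generator_config,
                                   c(cfg_base, censor_fraction = 1)))
  complete <- generate_dataset(do.call(generator_config,
                                       c(cfg_base[-6], missing_rate = 0,
                                         censor_fraction = 1)))
  # mean percentile rank of cells that went missing, per metabolite
  ranks <- vapply(seq_len(ncol(cens$matrix)), function(j) {
    miss <- is.na(cens$matrix[, j])
    mean(rank(complete$matrix[, j])[miss]) / nrow(cens$matrix)
  }, numeric(1))
  expect_lt(mean(ranks), 0.4) # well below the 0.5 of MCAR
  expect_lt(abs(mean(is.na(cens$matrix)) - 0.2), 0.03)
})

test_that("written dataset round-trips through the TSV/JSON readers", {
  ds <- tiny_dataset(seed = 2)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  m <- read_abundance_tsv(file.path(dir, "abundance.tsv"))
  expect_equal(m, ds$matrix, tolerance = 1e-12)
  md <- read_metadata_tsv(file.path(dir, "metadata.tsv"))
  expect_identical(md$sample_id, ds$metadata$sample_id)
  expect_identical(as.character(md$group), as.character(ds$metadata$group))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(truth$informative_ids),
                   sort(ds$truth$informative_ids))
})
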