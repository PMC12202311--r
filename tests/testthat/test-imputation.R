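test_that("predictor selection ranks by |r| with explicit-formula oracle", {
  set.seed(42)
  n <- 40L
  t <- rnorm(n)
  mk <- function(rho) rho * scale(t)[, 1] + sqrt(1 - rho^2) * rnorm(n)
  m <- cbind(target = t, a_strong = mk(0.9), b_neg = -mk(0.8),
             c_weak = mk(0.3), d_noise = rnorm(n))
  rownames(m) <- sprintf("S%02d", seq_len(n))
  m <- m - min(m) # keep abundances non-negative
  # independent oracle: Pearson r from the explicit product-moment formula
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  r <- vapply(colnames(m)[-1L], function(j) pearson(m[, j], m[, "target"]),
              numeric(1))
  expected <- names(sort(abs(r), decreasing = TRUE))
  got <- select_predictors("target", m, k = 2L)
  expect_identical(got, expected[1:2])
  expect_identical(select_predictors("target", m, k = 10L), expected)
})

test_that("fewer candidates than k returns all; duplicates rank first", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 5),
             a_copy = c(1, 2, 3, 4, 5))
  rownames(m) <- sprintf("S%d", 1:5)
  got <- select_predictors("a", m, k = 10L, min_overlap = 3L)
  expect_length(got, 2L)
  expect_identical(got[1L], "a_copy")
  expect_error(select_predictors("a", cbind(a = m[, 1, drop = FALSE])),
               "at least 2 metabolites")
  const <- cbind(a = rep(1, 5), b = 1:5)
  rownames(const) <- sprintf("S%d", 1:5)
  expect_error(select_predictors("a", const, k = 1L, min_overlap = 3L),
               "zero variance.*a")
})

test_that("a complete matrix passes through imputation unchanged", {
  fix <- tiny_complete(seed = 5)
  cfg <- imputation_config(n_predictors = 5L, n_imputations = 2L,
                           n_seeds = 2L, seed_list = c(1L, 2L),
                           min_predictor_overlap = 5L)
  coll <- impute_pmm(fix$matrix, cfg)
  expect_length(coll$datasets, 4L)
  for (d in coll$datasets) expect_identical(d, fix$matrix)
})

test_that("every imputed value is an observed value of its metabolite", {
  ds <- tiny_dataset(seed = 23, missing_rate = 0.15)
  filt <- filter_matrix(ds$matrix, ds$annotation)$matrix
  cfg <- imputation_config(n_predictors = 5L, n_imputations = 2L,
                           n_seeds = 2L, seed_list = c(3L, 4L),
                           min_predictor_overlap = 5L)
  coll <- impute_pmm(filt, cfg)
  for (d in coll$datasets) {
    expect_false(anyNA(d))
    for (j in colnames(filt)) {
      miss <- is.na(filt[, j])
      if (!any(miss)) next
      expect_true(all(d[miss, j] %in% filt[!miss, j]))
    }
    expect_identical(d[!is.na(filt)], filt[!is.na(filt)])
  }
})

test_that("identical seed lists reproduce the collection exactly", {
  ds <- tiny_dataset(seed = 29, missing_rate = 0.1)
  filt <- filter_matrix(ds$matrix, ds$annotation)$matrix
  cfg <- imputation_config(n_predictors = 4L, n_imputations = 2L,
                           n_seeds = 2L, seed_list = c(7L, 8L),
                           min_predictor_overlap = 5L)
  c1 <- impute_pmm(filt, cfg)
  c2 <- impute_pmm(filt, cfg)
  expect_identical(c1$datasets, c2$datasets)
})

test_that("PMM with one perfect predictor copies the nearest donor", {
  # 6-row toy: target = 2 * x on observed rows, row 6 missing;
  # with coefficient noise off, predicted mean for row 6 is 2 * x6 = 9,
  # nearest observed prediction is row 3 (2 * x3 = 8), donor pool 1
  x <- c(1, 3, 4, 7, 10, 4.5)
  y <- c(2, 6, 8, 14, 20, NA)
  m <- cbind(target = y, pred = x)
  rownames(m) <- sprintf("S%d", 1:6)
  cfg <- imputation_config(n_predictors = 1L, n_imputations = 1L,
                           n_seeds = 1L, seed_list = 1L,
                           donor_pool_size = 1L, n_chain_iterations = 1L,
                           min_predictor_overlap = 3L, coef_noise = FALSE)
  coll <- impute_pmm(m, cfg)
  expect_identical(coll$datasets[[1L]]["S6", "target"], 8)
})

test_that("MCAR imputation preserves per-metabolite means", {
  fix <- tiny_complete(seed = 41, n_per_group = 100L, n_metabolites = 10L)
  complete <- fix$matrix
  set.seed(99)
  holed <- complete
  holed[matrix(runif(length(holed)) < 0.15, nrow(holed))] <- NA
  cfg <- imputation_config(n_predictors = 5L, n_imputations = 3L,
                           n_seeds = 2L, seed_list = c(5L, 6L),
                           min_predictor_overlap = 10L)
  coll <- impute_pmm(holed, cfg)
  imputed_means <- Reduce(`+`, lapply(coll$datasets, colMeans)) /
    length(coll$datasets)
  se <- apply(complete, 2L, sd) / sqrt(nrow(complete))
  expect_true(all(abs(imputed_means - colMeans(complete)) < 3 * se))
})

test_that("imputation config invariants are enforced", {
  expect_error(imputation_config(n_seeds = 2L, seed_list = 1L), "seed_list")
  expect_error(imputation_config(n_predictors = 0L), ">= 1")
  m <- cbind(a = c(1, 2, NA, NA, NA), b = c(1, 2, 3, 4, 5))
  rownames(m) <- sprintf("S%d", 1:5)
  expect_error(impute_pmm(m, imputation_config(
    n_seeds = 1L, seed_list = 1L, donor_pool_size = 5L,
    min_predictor_overlap = 2L)), "too few observed")
})
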