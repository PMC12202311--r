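# Small in-code fixtures shared across test files.

# quick two-group dataset with strong planted effects, light confounding
tiny_dataset <- function(seed = 11, n_per_group = 30L, n_metabolites = 15L,
                         n_informative = 4L, auc = c(0.85, 0.95),
                         missing_rate = 0.08) {
  generate_dataset(generator_config(
    n_group_a = n_per_group, n_group_b = n_per_group,
    n_metabolites = n_metabolites, n_informative = n_informative,
    target_auc_range = auc, block_sizes = c(4L, 4L),
    within_block_correlation = 0.7, n_days = 4L,
    missing_rate = missing_rate, outlier_rate = 0, seed = seed))
}

# complete (NA-free) matrix + metadata pair for selector-level tests
tiny_complete <- function(seed = 11, ...) {
  ds <- tiny_dataset(seed = seed, missing_rate = 0, ...)
  list(matrix = ds$matrix, metadata = ds$metadata, truth = ds$truth)
}

# wrap a complete matrix as a single-member imputed collection
as_collection <- function(matrices, config = NULL) {
  n <- length(matrices)
  config <- config %||% imputation_config(
    n_seeds = 1L, n_imputations = n, seed_list = 1L,
    min_predictor_overlap = 5L)
  structure(list(datasets = matrices, config = config,
                 predictors = list()),
            class = "imputed_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
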