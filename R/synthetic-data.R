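#' Configuration for the synthetic metabolomics generator
#'
#' Builds and validates the configuration of [generate_dataset()].  Defaults
#' emulate a slaughter-day cohort design: two imbalanced sex groups (228
#' castrated males vs 466 intact gilts), ~600 endogenous plasma metabolites in
#' correlated blocks, body weight around 155 +/- 5 kg, 23 collection days, a
#' planted subset of group-discriminative metabolites with per-metabolite AUC
#' in [0.54, 0.70], abundance-dependent missingness and rare gross outliers.
#'
#' Abundances are log-normal: effects are additive on the log scale and
#' exponentiated, so values are strictly positive and relative group
#' differences (Delta%) are well defined.
#'
#' @param n_group_a Samples in group A (castrated males).
#' @param n_group_b Samples in group B (intact gilts).
#' @param n_metabolites Number of metabolites on the panel.
#' @param n_informative Number of planted group-discriminative metabolites.
#' @param target_auc_range Length-2 AUC range in `[0.5, 1)` from which each
#'   planted metabolite's target AUC is drawn uniformly.
#' @param block_sizes Integer sizes of correlated metabolite blocks; their sum
#'   must not exceed `n_metabolites`.  The default covers about a third of
#'   the panel with blocks of 10 (20 blocks at the default panel size).
#' @param within_block_correlation Pairwise Pearson correlation inside each
#'   block, in `[0, 1)` (single-factor construction).
#' @param weight_mean_kg,weight_sd_kg Body-weight distribution.
#' @param n_days Number of collection-day levels (assigned uniformly).
#' @param day_effect_sd SD of per-(metabolite, day) additive effects on the
#'   log-abundance scale; 0 disables day confounding.
#' @param weight_slope_sd SD of per-metabolite weight slopes (log-abundance
#'   units per kg); 0 disables weight confounding.
#' @param log_sd Residual log-abundance SD; sets the scale that converts a
#'   standardized shift into a fold change.
#' @param missing_rate Expected fraction of missing cells per metabolite, in
#'   `[0, 0.5)`.
#' @param censor_fraction Fraction of missingness that is abundance-dependent
#'   (left-censoring-like), in `[0, 1]`.
#' @param outlier_rate Expected fraction of cells turned into gross outliers.
#' @param seed Master RNG seed for the dataset.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_group_a = 228L,
                             n_group_b = 466L,
                             n_metabolites = 600L,
                             n_informative = 40L,
                             target_auc_range = c(0.54, 0.70),
                             block_sizes = rep(10L, n_metabolites %/% 30L),
                             within_block_correlation = 0.6,
                             weight_mean_kg = 155,
                             weight_sd_kg = 5,
                             n_days = 23L,
                             day_effect_sd = 0.1,
                             weight_slope_sd = 0.01,
                             log_sd = 0.3,
                             missing_rate = 0.08,
                             censor_fraction = 0.5,
                             outlier_rate = 0.002,
                             seed = 1L) {
  config <- list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_metabolites = as.integer(n_metabolites),
    n_informative = as.integer(n_informative),
    target_auc_range = as.numeric(target_auc_range),
    block_sizes = as.integer(block_sizes),
    within_block_correlation = within_block_correlation,
    weight_mean_kg = weight_mean_kg, weight_sd_kg = weight_sd_kg,
    n_days = as.integer(n_days),
    day_effect_sd = day_effect_sd, weight_slope_sd = weight_slope_sd,
    log_sd = log_sd,
    missing_rate = missing_rate, censor_fraction = censor_fraction,
    outlier_rate = outlier_rate, seed = as.integer(seed))
  fail <- function(msg) stop("invalid generator config: ", msg, call. = FALSE)
  with(config, {
    if (n_group_a < 1L || n_group_b < 1L) fail("both group sizes must be >= 1")
    if (n_metabolites < 1L) fail("n_metabolites must be >= 1")
    if (n_informative < 0L || n_informative > n_metabolites)
      fail("n_informative must be in [0, n_metabolites]")
    if (length(target_auc_range) != 2L || any(target_auc_range < 0.5) ||
        any(target_auc_range >= 1) || diff(target_auc_range) < 0)
      fail("target_auc_range must be an increasing pair in [0.5, 1)")
    if (sum(block_sizes) > n_metabolites)
      fail("sum(block_sizes) must not exceed n_metabolites")
    if (within_block_correlation < 0 || within_block_correlation >= 1)
      fail("within_block_correlation must be in [0, 1)")
    if (weight_sd_kg < 0) fail("weight_sd_kg must be >= 0")
    if (n_days < 1L) fail("n_days must be >= 1")
    if (day_effect_sd < 0 || weight_slope_sd < 0)
      fail("confounder effect scales must be >= 0")
    if (log_sd <= 0) fail("log_sd must be > 0")
    if (missing_rate < 0 || missing_rate >= 0.5)
      fail("missing_rate must be in [0, 0.5)")
    if (censor_fraction < 0 || censor_fraction > 1)
      fail("censor_fraction must be in [0, 1]")
    if (outlier_rate < 0 || outlier_rate > 0.05)
      fail("outlier_rate must be in [0, 0.05]")
  })
  structure(config, class = "generator_config")
}

#' Standardized shift achieving a target two-group AUC
#'
#' For two equal-variance normal populations separated by a standardized mean
#' shift `d`, the probability that a random draw from the shifted group
#' exceeds one from the reference group is `pnorm(d / sqrt(2))`.  Inverting
#' gives the shift needed to plant a metabolite at a target AUC:
#' `d = sqrt(2) * qnorm(auc)`.
#'
#' @param auc Target AUC in `[0.5, 1)`.
#' @return Standardized shift `d >= 0`, monotone increasing in `auc`.
#' @export
shift_for_target_auc <- function(auc) {
  if (!is.numeric(auc) || any(auc < 0.5) || any(auc >= 1))
    stop("auc must lie in [0.5, 1)")
  sqrt(2) * qnorm(auc)
}

#' Generate a synthetic two-group metabolomics dataset with ground truth
#'
#' Draws log-normal abundances with planted group effects, correlated
#' metabolite blocks, weight and collection-day confounding, a mixture of
#' completely-at-random and abundance-dependent (censoring-like) missingness,
#' and injected gross outliers.  Each sub-step uses its own RNG stream derived
#' from `config$seed` via [derive_seeds()], so the result is bit-for-bit
#' reproducible and sub-steps are individually stable.
#'
#' The generative model per metabolite `m` and sample `i` is
#' `log y_im = mu_m + log_sd * (z_im + d_m * A_i) + b_m (w_i - w_bar) + c_m[day_i]`
#' where `z` is a unit-variance latent with within-block correlation, `d_m` the
#' planted standardized shift (nonzero only for informative metabolites),
#' `A_i` the group-A indicator, `b_m` the weight slope and `c_m` the day
#' effects.  Because the group shift acts on the unit-variance latent, the
#' large-sample AUC of metabolite `m` (before confounding and masking) is
#' `pnorm(|d_m| / sqrt(2))` exactly, which [shift_for_target_auc()] inverts.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_dataset` with elements `matrix` (samples
#'   x metabolites, NAs for missing), `metadata` (sample_id, group, weight_kg,
#'   day), `annotation` (metabolite_id, name, super_pathway, sub_pathway,
#'   hmdb_id, origin_class), and `truth` (informative_ids, effect_shift,
#'   direction, planted_edges).
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  n <- config$n_group_a + config$n_group_b
  p <- config$n_metabolites
  sample_ids <- sprintf("S%04d", seq_len(n))
  metab_ids <- sprintf("M%04d", seq_len(p))
  group <- factor(rep(c("castrated_male", "intact_gilt"),
                      c(config$n_group_a, config$n_group_b)),
                  levels = c("castrated_male", "intact_gilt"))

  # --- sample-level covariates ---------------------------------------------
  set.seed(derive_seeds(config$seed, "covariates"))
  weight <- rnorm(n, config$weight_mean_kg, config$weight_sd_kg)
  day <- factor(sprintf("D%02d", sample.int(config$n_days, n, replace = TRUE)),
                levels = sprintf("D%02d", seq_len(config$n_days)))

  # --- planted effects ------------------------------------------------------
  set.seed(derive_seeds(config$seed, "effects"))
  informative <- sort(sample.int(p, config$n_informative))
  d <- numeric(p)
  if (config$n_informative > 0L) {
    auc <- runif(config$n_informative,
                 config$target_auc_range[1L], config$target_auc_range[2L])
    d[informative] <- shift_for_target_auc(auc) *
      sample(c(-1, 1), config$n_informative, replace = TRUE)
  }

  # --- unit-variance latent with block correlation --------------------------
  set.seed(derive_seeds(config$seed, "latent"))
  rho <- config$within_block_correlation
  block_of <- rep(0L, p)
  if (length(config$block_sizes) && sum(config$block_sizes) > 0L)
    block_of[seq_len(sum(config$block_sizes))] <-
      rep(seq_along(config$block_sizes), config$block_sizes)
  z <- matrix(rnorm(n * p), n, p)
  if (rho > 0 && any(block_of > 0L)) {
    for (b in seq_along(config$block_sizes)) {
      members <- which(block_of == b)
      f <- rnorm(n)
      z[, members] <- sqrt(rho) * f + sqrt(1 - rho) * z[, members]
    }
  }
  z <- z + outer(as.numeric(group == "castrated_male"), d)

  # --- confounders and baseline --------------------------------------------
  set.seed(derive_seeds(config$seed, "confounders"))
  mu <- rnorm(p, 0, 0.5)
  slope <- rnorm(p, 0, config$weight_slope_sd)
  day_eff <- matrix(rnorm(config$n_days * p, 0, config$day_effect_sd),
                    config$n_days, p)
  log_abund <- sweep(config$log_sd * z, 2L, mu, `+`) +
    outer(weight - config$weight_mean_kg, slope) +
    day_eff[as.integer(day), , drop = FALSE]
  values <- exp(log_abund)

  # --- gross outliers (before missingness, so they can also go missing) ----
  set.seed(derive_seeds(config$seed, "outliers"))
  n_out <- rbinom(1L, n * p, config$outlier_rate)
  if (n_out > 0L) {
    cells <- sample.int(n * p, n_out)
    med <- apply(values, 2L, median)
    iqr <- apply(values, 2L, function(v) diff(quantile(v, c(0.25, 0.75))))
    col_idx <- ((cells - 1L) %/% n) + 1L
    # factor >= 8, inflated further if needed so the cell provably exceeds
    # median + 6 * IQR and the 5xIQR rule must flag it
    factor <- pmax(8, (med[col_idx] + 6 * iqr[col_idx]) / values[cells])
    values[cells] <- values[cells] * factor
  }

  # --- missingness: MCAR + abundance-dependent censoring -------------------
  set.seed(derive_seeds(config$seed, "missingness"))
  if (config$missing_rate > 0) {
    for (j in seq_len(p)) {
      n_miss <- rbinom(1L, n, config$missing_rate)
      if (n_miss == 0L) next
      n_cens <- rbinom(1L, n_miss, config$censor_fraction)
      miss <- integer(0)
      if (n_cens > 0L) {
        # lower-abundance cells preferentially censored (rank-squared weights)
        w <- (n + 1L - rank(values[, j], ties.method = "first"))^2
        miss <- sample.int(n, n_cens, prob = w)
      }
      if (n_miss - n_cens > 0L) {
        left <- setdiff(seq_len(n), miss)
        miss <- c(miss, sample(left, min(n_miss - n_cens, length(left))))
      }
      values[miss, j] <- NA_real_
    }
  }

  dimnames(values) <- list(sample_ids, metab_ids)
  metadata <- data.frame(sample_id = sample_ids, group = group,
                         weight_kg = weight, day = day,
                         stringsAsFactors = FALSE)
  super <- c("Amino Acid", "Lipid", "Nucleotide", "Peptide", "Carbohydrate",
             "Cofactors and Vitamins", "Energy")
  set.seed(derive_seeds(config$seed, "annotation"))
  sp <- sample(super, p, replace = TRUE)
  annotation <- data.frame(
    metabolite_id = metab_ids,
    name = paste0("metabolite_", seq_len(p)),
    super_pathway = sp,
    sub_pathway = paste0(sp, " subpathway ", sample.int(5L, p, replace = TRUE)),
    hmdb_id = sprintf("HMDB%07d", seq_len(p)),
    origin_class = "endogenous",
    stringsAsFactors = FALSE)

  planted_edges <- NULL
  if (any(block_of > 0L)) {
    pairs <- do.call(rbind, lapply(seq_along(config$block_sizes), function(b) {
      members <- metab_ids[block_of == b]
      if (length(members) < 2L) return(NULL)
      t(utils::combn(members, 2L))
    }))
    planted_edges <- data.frame(metabolite_1 = pairs[, 1L],
                                metabolite_2 = pairs[, 2L],
                                stringsAsFactors = FALSE)
  } else {
    planted_edges <- data.frame(metabolite_1 = character(0),
                                metabolite_2 = character(0))
  }
  truth <- list(
    informative_ids = metab_ids[informative],
    effect_shift = setNames(d[informative], metab_ids[informative]),
    direction = setNames(
      ifelse(d[informative] > 0, "castrated_male", "intact_gilt"),
      metab_ids[informative]),
    planted_edges = planted_edges)

  structure(list(matrix = values, metadata = metadata,
                 annotation = annotation, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic metabolomics dataset: %d samples (%d/%d) x %d metabolites\n",
    nrow(x$matrix), x$config$n_group_a, x$config$n_group_b, ncol(x$matrix)))
  cat(sprintf("  informative: %d | missing cells: %.1f%% | seed: %d\n",
              length(x$truth$informative_ids),
              100 * mean(is.na(x$matrix)), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes the abundance matrix, metadata and annotation as TSV ("NA" missing
#' token, `.` decimal point) and the ground truth as JSON.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_tsv(dataset$matrix, file.path(dir, "abundance.tsv"))
  data.table::fwrite(dataset$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", na = "NA")
  data.table::fwrite(dataset$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", na = "NA")
  truth <- dataset$truth
  truth$effect_shift <- as.list(truth$effect_shift)
  truth$direction <- as.list(truth$direction)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
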