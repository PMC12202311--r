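#' Configuration for chained predictive-mean-matching imputation
#'
#' Defaults follow the study design: each metabolite with missing values is
#' imputed from its 10 most highly correlated endogenous metabolites, 5
#' imputations are drawn under each of 5 random-state seeds (25 completed
#' datasets in total), with 5 chained-equation sweeps and a donor pool of 5.
#'
#' @param n_predictors Number of correlated predictor metabolites per target.
#' @param n_imputations Imputations per seed.
#' @param n_seeds Number of imputation seeds.
#' @param n_chain_iterations Chained-equation sweeps per imputation.
#' @param donor_pool_size Observed donors from which each imputed value is
#'   drawn (nearest predicted means, uniform choice).
#' @param seed_list Explicit RNG seeds, length `n_seeds`.
#' @param min_predictor_overlap Minimum pairwise-complete observations for a
#'   metabolite to qualify as a predictor (guards spurious |r| = 1 from tiny
#'   overlaps).
#' @param coef_noise Perturb regression coefficients by a draw from their
#'   least-squares sampling distribution (standard PMM behaviour); disable
#'   only for deterministic debugging.
#' @return A validated `imputation_config` list.
#' @export
imputation_config <- function(n_predictors = 10L,
                              n_imputations = 5L,
                              n_seeds = 5L,
                              n_chain_iterations = 5L,
                              donor_pool_size = 5L,
                              seed_list = seq_len(n_seeds),
                              min_predictor_overlap = 10L,
                              coef_noise = TRUE) {
  config <- list(n_predictors = as.integer(n_predictors),
                 n_imputations = as.integer(n_imputations),
                 n_seeds = as.integer(n_seeds),
                 n_chain_iterations = as.integer(n_chain_iterations),
                 donor_pool_size = as.integer(donor_pool_size),
                 seed_list = as.integer(seed_list),
                 min_predictor_overlap = as.integer(min_predictor_overlap),
                 coef_noise = isTRUE(coef_noise))
  counts <- config[c("n_predictors", "n_imputations", "n_seeds",
                     "n_chain_iterations", "donor_pool_size")]
  if (any(unlist(counts) < 1L))
    stop("all imputation counts must be >= 1")
  if (length(config$seed_list) != config$n_seeds)
    stop("seed_list must have length n_seeds")
  structure(config, class = "imputation_config")
}

#' Select the most correlated predictor metabolites for a target
#'
#' Ranks all other metabolites by absolute Pearson correlation with the
#' target, computed on pairwise-complete observations, and returns the top
#' `k`.  Candidates with fewer than `min_overlap` paired observations are
#' excluded; ties in |r| are broken by lexical metabolite-id order.
#'
#' @param target_id Metabolite id of the imputation target.
#' @param matrix Abundance matrix (NA allowed).
#' @param k Number of predictors requested.
#' @param min_overlap Minimum paired observations to admit a candidate.
#' @return Character vector of up to `k` metabolite ids, strongest first.
#' @export
select_predictors <- function(target_id, matrix, k,
                              min_overlap = 10L) {
  validate_abundance_matrix(matrix)
  if (!target_id %in% colnames(matrix))
    stop("target metabolite not in matrix: ", target_id)
  if (ncol(matrix) < 2L)
    stop("predictor selection needs at least 2 metabolites")
  y <- matrix[, target_id]
  if (sum(!is.na(y)) < 2L || var(y, na.rm = TRUE) == 0)
    stop("target metabolite has zero variance: ", target_id)
  others <- setdiff(colnames(matrix), target_id)
  overlap <- colSums(!is.na(matrix[, others, drop = FALSE]) & !is.na(y))
  r <- suppressWarnings(
    cor(matrix[, others, drop = FALSE], y, use = "pairwise.complete.obs"))[, 1L]
  ok <- !is.na(r) & overlap >= min_overlap
  cand <- others[ok]
  if (!length(cand)) return(character(0))
  cand <- cand[order(-abs(r[cand]), cand)]
  head(cand, k)
}

#' Impute missing abundances by chained equations with PMM
#'
#' Produces `n_seeds x n_imputations` completed copies of the matrix.  Each
#' copy initializes the missing cells with random draws from the metabolite's
#' observed values, then runs `n_chain_iterations` sweeps; in each sweep every
#' metabolite with missing values is regressed (with intercept) on its
#' pre-selected predictors over the originally observed rows, the
#' coefficients are perturbed by a normal draw with the least-squares
#' covariance, predicted means are formed for observed and missing rows, and
#' every missing cell receives the observed value of one of the
#' `donor_pool_size` observed rows with nearest predicted mean, chosen
#' uniformly.  Every imputed value is therefore an observed value of the same
#' metabolite (the PMM donor property).
#'
#' Predictors are selected once on the incomplete input matrix (single
#' selection step), not refreshed per sweep.  Collinear predictors are
#' dropped with a warning; a target with no admissible predictors falls back
#' to random observed-value draws.
#'
#' @param matrix Filtered abundance matrix with NAs.
#' @param config An [imputation_config()].
#' @return An `imputed_collection`: list with `datasets` (complete matrices
#'   named `seed{S}_imp{I}`), `config`, and the predictor map.
#' @export
impute_pmm <- function(matrix, config = imputation_config()) {
  validate_abundance_matrix(matrix)
  stopifnot(inherits(config, "imputation_config"))
  obs_count <- colSums(!is.na(matrix))
  too_few <- obs_count < max(2L, config$donor_pool_size)
  if (any(too_few))
    stop("metabolite(s) with too few observed values to impute: ",
         paste(head(colnames(matrix)[too_few], 5L), collapse = ", "))

  targets <- colnames(matrix)[colSums(is.na(matrix)) > 0L]
  predictors <- lapply(setNames(targets, targets), function(id) {
    p <- select_predictors(id, matrix, config$n_predictors,
                           min_overlap = config$min_predictor_overlap)
    if (!length(p))
      warning("no admissible predictors for ", id,
              "; falling back to random observed-value draws")
    p
  })

  datasets <- list()
  for (s in seq_len(config$n_seeds)) {
    imp_seeds <- derive_seeds(config$seed_list[s], "pmm", config$n_imputations)
    for (i in seq_len(config$n_imputations)) {
      set.seed(imp_seeds[i])
      datasets[[sprintf("seed%d_imp%d", s, i)]] <-
        pmm_single(matrix, predictors, config)
    }
  }
  structure(list(datasets = datasets, config = config,
                 predictors = predictors),
            class = "imputed_collection")
}

# one completed dataset under the current RNG state
pmm_single <- function(matrix, predictors, config) {
  completed <- matrix
  na_idx <- lapply(setNames(names(predictors), names(predictors)),
                   function(id) which(is.na(matrix[, id])))
  # initialization: random draws from observed values
  for (id in names(predictors)) {
    obs <- matrix[!is.na(matrix[, id]), id]
    completed[na_idx[[id]], id] <- sample(obs, length(na_idx[[id]]),
                                          replace = TRUE)
  }
  if (!length(predictors)) return(completed)
  for (sweep in seq_len(config$n_chain_iterations)) {
    for (id in names(predictors)) {
      mis <- na_idx[[id]]
      preds <- predictors[[id]]
      obs <- setdiff(seq_len(nrow(matrix)), mis)
      y_obs <- matrix[obs, id]
      if (!length(preds)) {
        completed[mis, id] <- sample(y_obs, length(mis), replace = TRUE)
        next
      }
      X <- cbind(`(Intercept)` = 1, completed[, preds, drop = FALSE])
      completed[mis, id] <- pmm_draw(X[obs, , drop = FALSE], y_obs,
                                     X[mis, , drop = FALSE], config)
    }
  }
  completed
}

# PMM for one target: perturbed least squares + nearest-donor matching
pmm_draw <- function(X_obs, y_obs, X_mis, config) {
  qr_obs <- qr(X_obs)
  if (qr_obs$rank < ncol(X_obs)) {
    keep <- qr_obs$pivot[seq_len(qr_obs$rank)]
    warning("dropping ", ncol(X_obs) - qr_obs$rank,
            " collinear predictor column(s)")
    X_obs <- X_obs[, keep, drop = FALSE]
    X_mis <- X_mis[, keep, drop = FALSE]
    qr_obs <- qr(X_obs)
  }
  beta <- qr.coef(qr_obs, y_obs)
  if (config$coef_noise && length(y_obs) > ncol(X_obs)) {
    res <- y_obs - drop(X_obs %*% beta)
    sigma2 <- sum(res^2) / (length(y_obs) - ncol(X_obs))
    cov_chol <- tryCatch(
      chol(sigma2 * chol2inv(chol(crossprod(X_obs)))),
      error = function(e) NULL)
    if (!is.null(cov_chol))
      beta <- beta + drop(crossprod(cov_chol, rnorm(length(beta))))
  }
  pred_obs <- drop(X_obs %*% beta)
  pred_mis <- drop(X_mis %*% beta)
  k <- min(config$donor_pool_size, length(y_obs))
  vapply(pred_mis, function(pm) {
    pool <- order(abs(pred_obs - pm))[seq_len(k)]
    y_obs[pool[sample.int(k, 1L)]]
  }, numeric(1))
}

#' @export
print.imputed_collection <- function(x, ...) {
  cat(sprintf("imputed collection: %d completed datasets (%d seeds x %d imputations)\n",
              length(x$datasets), x$config$n_seeds, x$config$n_imputations))
  invisible(x)
}

#' Write an imputed collection to a directory of TSV matrices
#'
#' @param collection An `imputed_collection`.
#' @param dir Output directory; one `seed{S}_imp{I}.tsv` per member plus a
#'   JSON manifest with the configuration.
#' @return The directory, invisibly.
#' @export
write_imputed_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "imputed_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(collection$datasets))
    write_abundance_tsv(collection$datasets[[nm]],
                        file.path(dir, paste0(nm, ".tsv")))
  manifest <- c(unclass(collection$config),
                list(members = names(collection$datasets)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
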