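#' Plan of the consensus selection grid
#'
#' The study geometry: 5 imputation seeds x 5 imputations = 25 completed
#' datasets; each analyzed with 5 selector seeds (125 full-data runs); each
#' of those combinations additionally cycled through a stratified 10-fold
#' external cross-validation (25 x 5 x 10 = 1,250 CV runs).  Derived counts
#' are always computed, never stored.
#'
#' @param n_imputation_seeds,n_imputations_per_seed,n_selection_seeds,n_cv_folds
#'   Grid dimensions, all `>= 1`.
#' @return A `grid_plan` list.
#' @export
grid_plan <- function(n_imputation_seeds = 5L, n_imputations_per_seed = 5L,
                      n_selection_seeds = 5L, n_cv_folds = 10L) {
  plan <- list(n_imputation_seeds = as.integer(n_imputation_seeds),
               n_imputations_per_seed = as.integer(n_imputations_per_seed),
               n_selection_seeds = as.integer(n_selection_seeds),
               n_cv_folds = as.integer(n_cv_folds))
  if (any(unlist(plan) < 1L)) stop("all grid_plan counts must be >= 1")
  structure(plan, class = "grid_plan")
}

#' @export
print.grid_plan <- function(x, ...) {
  nd <- x$n_imputation_seeds * x$n_imputations_per_seed
  cat(sprintf("grid plan: %d imputed datasets, %d full runs, %d CV runs\n",
              nd, nd * x$n_selection_seeds,
              nd * x$n_selection_seeds * x$n_cv_folds))
  invisible(x)
}

run_one_selector <- function(x, y, selector, config, spls_config, seed) {
  if (selector == "boruta") {
    cfg <- config
    cfg$seed <- seed
    res <- boruta_run(x, y, cfg)
    list(confirmed = confirmed_features(res),
         signs = NULL, n_confirmed = sum(res$status == "confirmed"))
  } else {
    cfg <- spls_config
    cfg$seed <- seed
    res <- spls_da_select(x, y, cfg)
    sel <- res$selected
    list(confirmed = sel, signs = sign(res$loadings[sel]),
         n_confirmed = length(sel))
  }
}

#' Run the full-data selector grid and form the selection set
#'
#' Executes one selector run per (completed dataset, selection seed): each
#' completed dataset is residualized for weight and collection day, and the
#' selector (Boruta-style shadow test, or sPLS-DA when
#' `selector = "splsda"`) is applied with `n_selection_seeds` different
#' seeds.  The *selection set* contains the metabolites confirmed in every
#' run; for sPLS-DA, confirmation additionally requires an identical loading
#' sign across all runs.
#'
#' @param collection An `imputed_collection` with exactly
#'   `n_imputation_seeds x n_imputations_per_seed` members.
#' @param metadata Sample metadata.
#' @param plan A [grid_plan()].
#' @param config A [boruta_config()]; its `seed` is the grid master seed from
#'   which every run seed is derived.
#' @param selector `"boruta"` or `"splsda"`.
#' @param spls_config An [spls_config()] when `selector = "splsda"`.
#' @return A `selection_result` with per-run confirmed sets, an audit table
#'   (one row per run), and `selection_set`; `core_set` is filled in by
#'   [run_cv_grid()].
#' @export
run_full_grid <- function(collection, metadata, plan = grid_plan(),
                          config = boruta_config(),
                          selector = c("boruta", "splsda"),
                          spls_config = NULL) {
  selector <- match.arg(selector)
  stopifnot(inherits(collection, "imputed_collection"),
            inherits(plan, "grid_plan"))
  n_datasets <- plan$n_imputation_seeds * plan$n_imputations_per_seed
  if (length(collection$datasets) != n_datasets)
    stop("collection has ", length(collection$datasets),
         " datasets but the plan requires ", n_datasets)
  if (selector == "splsda" && is.null(spls_config))
    stop("spls_config is required when selector = 'splsda'")
  metadata <- validate_metadata(metadata,
                                rownames(collection$datasets[[1L]]))
  y <- metadata$group

  runs <- list()
  audit <- list()
  for (ds in names(collection$datasets)) {
    resid <- residualize_matrix(collection$datasets[[ds]], metadata)
    seeds <- derive_seeds(config$seed, paste0("full:", ds),
                          plan$n_selection_seeds)
    for (s in seq_len(plan$n_selection_seeds)) {
      key <- sprintf("%s_sel%d", ds, s)
      run <- tryCatch(
        run_one_selector(resid, y, selector, config, spls_config, seeds[s]),
        error = function(e) stop("selector run ", key, " failed: ",
                                 conditionMessage(e), call. = FALSE))
      runs[[key]] <- run
      audit[[key]] <- data.frame(stage = "full", dataset = ds,
                                 selection_seed = s, fold = NA_integer_,
                                 n_confirmed = run$n_confirmed,
                                 stringsAsFactors = FALSE)
    }
  }
  audit <- do.call(rbind, c(audit, list(make.row.names = FALSE)))
  selection_set <- consensus_set(runs, selector)
  structure(list(selector = selector, plan = plan,
                 full_runs = runs, cv_runs = NULL, audit = audit,
                 selection_set = selection_set, core_set = NULL,
                 confirmation_rate = NULL),
            class = "selection_result")
}

# intersection consensus; for sPLS-DA additionally require a stable sign
consensus_set <- function(runs, selector) {
  sets <- lapply(runs, `[[`, "confirmed")
  common <- Reduce(intersect, sets)
  if (selector == "splsda" && length(common)) {
    signs <- vapply(runs, function(r) r$signs[common], numeric(length(common)))
    signs <- matrix(signs, nrow = length(common))
    stable <- apply(signs, 1L, function(s) all(s == s[1L]))
    common <- common[stable]
  }
  sort(common)
}

#' Stratified cross-validation folds
#'
#' Assigns every sample to exactly one of `k` folds, stratifying by group so
#' each fold mirrors the class imbalance.
#'
#' @param groups Two-level factor of class labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold assignment in `1..k`, one per sample.
#' @export
make_folds <- function(groups, k, seed = 1L) {
  groups <- factor(groups)
  if (any(table(groups) < k))
    stop("cannot stratify: a class has fewer samples than folds")
  set.seed(seed)
  folds <- integer(length(groups))
  for (g in levels(groups)) {
    idx <- sample(which(groups == g))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Run the external cross-validated selector grid and form the core set
#'
#' For each completed dataset, samples are partitioned once into
#' `n_cv_folds` group-stratified folds; for every fold, the retained
#' nine-tenths are residualized afresh and analyzed with
#' `n_selection_seeds` selector seeds.  The *core set* is the subset of the
#' selection set confirmed in every CV run; `confirmation_rate` reports, for
#' each selection-set member, the fraction of CV runs in which it was
#' confirmed.
#'
#' @param full_result The [run_full_grid()] output.
#' @inheritParams run_full_grid
#' @return The completed `selection_result` (audit rows for CV runs appended,
#'   `core_set` and `confirmation_rate` filled in).
#' @export
run_cv_grid <- function(full_result, collection, metadata,
                        plan = grid_plan(), config = boruta_config(),
                        spls_config = NULL) {
  stopifnot(inherits(full_result, "selection_result"),
            inherits(collection, "imputed_collection"))
  selector <- full_result$selector
  metadata <- validate_metadata(metadata,
                                rownames(collection$datasets[[1L]]))
  runs <- list()
  audit <- list()
  for (ds in names(collection$datasets)) {
    folds <- make_folds(metadata$group, plan$n_cv_folds,
                        seed = derive_seeds(config$seed, paste0("folds:", ds)))
    for (f in seq_len(plan$n_cv_folds)) {
      keep <- folds != f
      sub_meta <- metadata[keep, , drop = FALSE]
      if (nlevels(droplevels(sub_meta$group)) < 2L)
        stop("retained samples of fold ", f, " contain a single class")
      resid <- suppressWarnings(
        residualize_matrix(collection$datasets[[ds]][keep, , drop = FALSE],
                           sub_meta))
      seeds <- derive_seeds(config$seed, sprintf("cv:%s:fold%d", ds, f),
                            plan$n_selection_seeds)
      for (s in seq_len(plan$n_selection_seeds)) {
        key <- sprintf("%s_fold%d_sel%d", ds, f, s)
        run <- tryCatch(
          run_one_selector(resid, sub_meta$group, selector, config,
                           spls_config, seeds[s]),
          error = function(e) stop("selector run ", key, " failed: ",
                                   conditionMessage(e), call. = FALSE))
        runs[[key]] <- run
        audit[[key]] <- data.frame(stage = "cv", dataset = ds,
                                   selection_seed = s, fold = f,
                                   n_confirmed = run$n_confirmed,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  audit <- do.call(rbind, c(audit, list(make.row.names = FALSE)))
  result <- full_result
  result$cv_runs <- runs
  result$audit <- rbind(full_result$audit, audit)
  cv_consensus <- consensus_set(runs, selector)
  result$core_set <- intersect(full_result$selection_set, cv_consensus)
  sel <- full_result$selection_set
  result$confirmation_rate <- vapply(setNames(sel, sel), function(id)
    mean(vapply(runs, function(r) id %in% r$confirmed, logical(1))),
    numeric(1))
  result
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection result (%s): %d full runs", x$selector,
              length(x$full_runs)))
  if (!is.null(x$cv_runs)) cat(sprintf(", %d CV runs", length(x$cv_runs)))
  cat(sprintf("\n  selection set: %d metabolites", length(x$selection_set)))
  if (!is.null(x$core_set))
    cat(sprintf(" | core set: %d metabolites", length(x$core_set)))
  cat("\n")
  invisible(x)
}

#' Write a selection result's audit log as JSONL
#'
#' One JSON object per selector run (stage, dataset, selection seed, fold,
#' confirmed count).
#'
#' @param result A `selection_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_audit_jsonl <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  lines <- vapply(seq_len(nrow(result$audit)), function(i)
    jsonlite::toJSON(as.list(result$audit[i, ]), auto_unbox = TRUE,
                     na = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
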