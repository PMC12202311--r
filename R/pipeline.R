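#' Pipeline configuration
#'
#' Bundles the stage configurations and input paths of the end-to-end
#' analysis.  All randomness derives from the single `seed` through named
#' sub-streams (imputation seeds, selector seeds, fold assignment, scoring
#' forests), so a rerun with the same configuration reproduces identical
#' outputs.
#'
#' @param matrix_path,metadata_path,annotation_path Input TSVs (abundances,
#'   sample metadata, metabolite annotation).
#' @param gmt_path Optional GMT pathway library; `NULL` skips the
#'   over-representation stage.
#' @param outdir Output directory for artifacts.
#' @param plan A [grid_plan()].
#' @param boruta A [boruta_config()] (its `seed` is overridden from `seed`).
#' @param imputation An [imputation_config()] (its `seed_list` is overridden
#'   from `seed`).
#' @param spls Optional [spls_config()] when `selector = "splsda"`.
#' @param selector `"boruta"` or `"splsda"`.
#' @param network_threshold Absolute-correlation edge threshold.
#' @param scoring_trees Trees per scoring forest.
#' @param seed Global master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path, metadata_path, annotation_path,
                            gmt_path = NULL, outdir,
                            plan = grid_plan(),
                            boruta = boruta_config(),
                            imputation = imputation_config(
                              n_seeds = plan$n_imputation_seeds,
                              n_imputations = plan$n_imputations_per_seed),
                            spls = NULL,
                            selector = c("boruta", "splsda"),
                            network_threshold = 0.5,
                            scoring_trees = 500L,
                            seed = 1L) {
  selector <- match.arg(selector)
  structure(list(matrix_path = matrix_path, metadata_path = metadata_path,
                 annotation_path = annotation_path, gmt_path = gmt_path,
                 outdir = outdir, plan = plan, boruta = boruta,
                 imputation = imputation, spls = spls, selector = selector,
                 network_threshold = network_threshold,
                 scoring_trees = as.integer(scoring_trees),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Semantic hash of a pipeline configuration
#'
#' Hashes every field except `outdir` (an output location is not
#' semantically meaningful for reproducibility).
#'
#' @param config A `pipeline_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  fields <- unclass(config)
  fields$outdir <- NULL
  rlang::hash(fields)
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("matrix_path", "metadata_path", "annotation_path")) {
    if (!file.exists(config[[f]]))
      stop("input file does not exist (", f, "): ", config[[f]])
  }
  if (!is.null(config$gmt_path) && !file.exists(config$gmt_path))
    stop("input file does not exist (gmt_path): ", config$gmt_path)
  if (config$selector == "splsda" && is.null(config$spls))
    stop("selector 'splsda' requires an spls_config")
  invisible(config)
}

#' Run the full pipeline: QC, imputation, selection, scoring, network, ORA
#'
#' Stage order: 5xIQR outlier masking and NA filtering, chained PMM
#' imputation (seed grid), full-data and cross-validated consensus
#' selection, per-metabolite scoring, the maximum-correlation network over
#' the selection set, and, when a GMT library is supplied, hypergeometric
#' over-representation of the selection set's HMDB ids.  All artifacts are
#' written under `config$outdir` together with a JSON manifest recording the
#' configuration hash and seed.
#'
#' @param config A [pipeline_config()]; inputs are validated before any
#'   computation.
#' @return Invisible result bundle: `qc`, `collection`, `selection`
#'   (a `selection_result`), `scorecard`, `network`, `node_stats`, `ora`
#'   (or NULL), `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  matrix <- read_abundance_tsv(config$matrix_path)
  metadata <- read_metadata_tsv(config$metadata_path)
  metadata <- validate_metadata(metadata, rownames(matrix))
  annotation <- read_annotation_tsv(config$annotation_path)

  # --- QC ------------------------------------------------------------------
  masked <- mask_outliers(matrix)
  filtered <- filter_matrix(masked$matrix, annotation)
  qc <- list(outliers = masked$report, filters = filtered$report)
  write_abundance_tsv(filtered$matrix, file.path(config$outdir, "filtered.tsv"))
  jsonlite::write_json(
    list(n_outliers_masked = masked$report$n_outliers_masked,
         removed_xenobiotics = filtered$report$removed_xenobiotics,
         removed_metabolites = as.list(filtered$report$removed_metabolites),
         removed_samples = as.list(filtered$report$removed_samples)),
    file.path(config$outdir, "qc_report.json"), auto_unbox = TRUE, digits = NA)

  # --- imputation ----------------------------------------------------------
  imp_cfg <- config$imputation
  imp_cfg$seed_list <- derive_seeds(config$seed, "imputation",
                                    imp_cfg$n_seeds)
  collection <- impute_pmm(filtered$matrix, imp_cfg)
  write_imputed_collection(collection, file.path(config$outdir, "imputed"))

  # --- consensus selection -------------------------------------------------
  bor_cfg <- config$boruta
  bor_cfg$seed <- derive_seeds(config$seed, "selection")
  selection <- run_full_grid(collection, metadata, config$plan, bor_cfg,
                             selector = config$selector,
                             spls_config = config$spls)
  selection <- run_cv_grid(selection, collection, metadata, config$plan,
                           bor_cfg, spls_config = config$spls)
  write_audit_jsonl(selection, file.path(config$outdir, "audit.jsonl"))
  jsonlite::write_json(
    list(selection_set = selection$selection_set,
         core_set = selection$core_set,
         confirmation_rate = as.list(selection$confirmation_rate)),
    file.path(config$outdir, "selection.json"), auto_unbox = TRUE, digits = NA)

  scorecard <- NULL
  network <- NULL
  node_stats <- NULL
  ora <- NULL
  if (length(selection$selection_set) >= 1L) {
    scorecard <- score_metabolites(
      collection, metadata, selection$selection_set,
      core_ids = selection$core_set, annotation = annotation,
      n_trees = config$scoring_trees,
      seed = derive_seeds(config$seed, "scoring"))
    write_scorecard_tsv(scorecard, file.path(config$outdir, "scorecard.tsv"))
  }
  if (length(selection$selection_set) >= 2L) {
    triplet <- correlation_triplet(collection$datasets[[1L]], metadata,
                                   selection$selection_set)
    network <- build_network(triplet, config$network_threshold)
    node_stats <- node_statistics(network)
    data.table::fwrite(node_stats,
                       file.path(config$outdir, "node_stats.tsv"),
                       sep = "\t", na = "NA")
    export_network(network, file.path(config$outdir, "network"),
                   node_attributes = scorecard)
    if (!is.null(config$gmt_path)) {
      library <- read_gmt(config$gmt_path)
      universe_map <- map_hmdb(colnames(filtered$matrix), annotation)
      input_map <- universe_map[intersect(selection$selection_set,
                                          names(universe_map))]
      lib_ids <- unique(unlist(library))
      universe <- names(universe_map)[vapply(universe_map, function(h)
        any(h %in% lib_ids), logical(1))]
      input <- intersect(names(input_map), universe)
      if (length(universe) && length(input)) {
        # project library sets onto metabolite ids via any-HMDB membership
        metab_library <- lapply(library, function(members)
          names(universe_map)[vapply(universe_map, function(h)
            any(h %in% members), logical(1))])
        ora <- over_representation(input, metab_library, universe)
        data.table::fwrite(ora, file.path(config$outdir, "ora.tsv"),
                           sep = "\t", na = "NA")
      }
    }
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   selector = config$selector,
                   n_imputed_datasets = length(collection$datasets),
                   n_full_runs = length(selection$full_runs),
                   n_cv_runs = length(selection$cv_runs),
                   selection_set_size = length(selection$selection_set),
                   core_set_size = length(selection$core_set))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(qc = qc, collection = collection, selection = selection,
                 scorecard = scorecard, network = network,
                 node_stats = node_stats, ora = ora, manifest = manifest))
}
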