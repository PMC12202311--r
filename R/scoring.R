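#' Out-of-bag performance of a balanced random forest
#'
#' Fits a single random forest with inverse-class-frequency class weights on
#' the given feature set and scores each sample by the out-of-bag vote of the
#' trees that did not see it.  Samples never out-of-bag (possible with very
#' few trees) are excluded from the score with a warning.
#'
#' @param x Numeric samples x features matrix (no NA).
#' @param y Two-level factor of labels.
#' @param n_trees Trees in the forest.
#' @param seed RNG seed.
#' @return A `classifier_summary` list: `oob_score`, `oob_error`
#'   (`= 1 - oob_score`), `n_features`, `n_trees`, `seed`.
#' @export
oob_evaluate <- function(x, y, n_trees = 500L, seed = 1L) {
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  if (anyNA(x)) stop("feature matrix must not contain NA")
  y <- factor(y)
  class_weights <- as.numeric(length(y) / (2 * table(y)))
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        class.weights = class_weights,
                        num.threads = 1L, seed = seed)
  pred <- fit$predictions
  covered <- !is.na(pred)
  if (!all(covered))
    warning(sum(!covered), " sample(s) never out-of-bag; excluded from score")
  oob_score <- mean(pred[covered] == y[covered])
  structure(list(oob_score = oob_score, oob_error = 1 - oob_score,
                 n_features = ncol(x), n_trees = n_trees, seed = seed),
            class = "classifier_summary")
}

#' Normalized mean-decrease-Gini importance
#'
#' Impurity-decrease importance from a balanced random forest, normalized so
#' the importances of the scored feature set sum to 1 (the reported ranking
#' scale).  Zero-variance features receive importance 0.
#'
#' @inheritParams oob_evaluate
#' @return Named numeric vector of normalized importances summing to 1.
#' @export
gini_importance <- function(x, y, n_trees = 500L, seed = 1L) {
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  if (anyNA(x)) stop("feature matrix must not contain NA")
  y <- factor(y)
  class_weights <- as.numeric(length(y) / (2 * table(y)))
  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        importance = "impurity",
                        class.weights = class_weights,
                        num.threads = 1L, seed = seed)
  imp <- pmax(fit$variable.importance, 0)
  if (sum(imp) == 0) return(setNames(rep(0, ncol(x)), colnames(x)))
  imp / sum(imp)
}

#' Rank-based two-group AUC, orientation-folded
#'
#' Computes `P(value in group A > value in group B)` by the rank (Mann-
#' Whitney) statistic with ties counted one half, then folds orientation:
#' the reported AUC is `max(a, 1 - a)`, so it measures discriminative
#' strength regardless of which group has higher abundance.
#'
#' @param values Numeric vector, one value per sample.
#' @param y Two-level factor; the first level is group A.
#' @param fold Fold orientation (default `TRUE`); `FALSE` returns raw
#'   `P(A > B)`.
#' @return AUC in `[0.5, 1]` (folded) or `[0, 1]` (raw).
#' @export
metabolite_auc <- function(values, y, fold = TRUE) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, length(values) == length(y))
  a <- values[y == levels(y)[1L]]
  b <- values[y == levels(y)[2L]]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  auc <- u / (length(a) * length(b))
  if (fold) max(auc, 1 - auc) else auc
}

#' Two-sided Mann-Whitney test with Bonferroni significance flag
#'
#' Wraps [wilcox.test()]: exact for small tie-free samples, otherwise the
#' tie-corrected normal approximation with continuity correction.  The
#' significance flag applies a Bonferroni correction for `n_tests`
#' simultaneous metabolite tests at family level 0.05.
#'
#' @param values Numeric vector of abundances/residuals.
#' @param y Two-level factor.
#' @param n_tests Number of simultaneous tests (Bonferroni divisor).
#' @param level Family-wise level (default 0.05).
#' @return List with `U` (statistic for group A), `p`, `significant`.
#' @export
mann_whitney_test <- function(values, y, n_tests = 1L, level = 0.05) {
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, length(values) == length(y))
  a <- values[y == levels(y)[1L]]
  b <- values[y == levels(y)[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need at least 2 observations")
  ht <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < level / n_tests)
}

#' Relative group difference in percent
#'
#' `delta_pct = (mean_a - mean_b) / mean_a * 100`: the signed relative
#' difference with group A (castrated males) as the reference; positive
#' values mean higher abundance in group A.  Means are taken on imputed raw
#' abundances, not residuals (residual means are ~0 and would make the ratio
#' degenerate).
#'
#' @param mean_a,mean_b Group mean abundances; `mean_a` must be nonzero.
#' @return Signed percent difference.
#' @export
delta_percent <- function(mean_a, mean_b) {
  if (any(mean_a == 0)) stop("delta_percent is undefined for mean_a = 0")
  (mean_a - mean_b) / mean_a * 100
}

#' PCA summary of a (sub)set of metabolites
#'
#' Z-scores each feature, then computes principal components; used to
#' contrast sample structure before and after metabolite selection.
#'
#' @param x Numeric samples x features matrix (no NA).
#' @param feature_subset Optional character vector of columns to use.
#' @return List with `explained` (variance fractions, summing to 1) and
#'   `scores` (sample scores).
#' @export
pca_summary <- function(x, feature_subset = NULL) {
  stopifnot(is.matrix(x))
  if (!is.null(feature_subset)) x <- x[, feature_subset, drop = FALSE]
  if (ncol(x) < 2L) stop("PCA needs at least 2 features")
  if (anyNA(x)) stop("feature matrix must not contain NA")
  keep <- apply(x, 2L, var) > 0
  fit <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  list(explained = explained, scores = fit$x)
}

#' Score a metabolite set on every imputed dataset and aggregate
#'
#' For each completed dataset: residualizes, computes per-metabolite folded
#' AUC and Mann-Whitney p on the residuals, normalized mean-decrease-Gini
#' from one balanced forest on the scored set, Delta% from the imputed raw
#' abundances, and the forest's out-of-bag error.  Per-metabolite scores are
#' then averaged across datasets (mean and SD), the reporting convention of
#' the scorecard.
#'
#' @param collection An `imputed_collection`.
#' @param metadata Sample metadata.
#' @param ids Metabolite set to score (e.g. the selection set).
#' @param core_ids Optional subset flagged as core in the output.
#' @param annotation Optional annotation merged into the scorecard.
#' @param n_trees Trees per scoring forest.
#' @param seed Master seed for the per-dataset forests.
#' @return A `metabolite_scorecard`: data frame with one row per metabolite
#'   (mdg, auc, delta_pct, mw_p and their SDs, direction, significance at
#'   Bonferroni 0.05 over `length(ids)` tests) plus an `oob` attribute with
#'   the per-dataset out-of-bag summaries.
#' @export
score_metabolites <- function(collection, metadata, ids, core_ids = NULL,
                              annotation = NULL, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(collection, "imputed_collection"), length(ids) >= 1L)
  metadata <- validate_metadata(metadata,
                                rownames(collection$datasets[[1L]]))
  y <- metadata$group
  a_rows <- y == levels(y)[1L]
  seeds <- derive_seeds(seed, "scoring", length(collection$datasets))
  per_ds <- vector("list", length(collection$datasets))
  oob <- vector("list", length(collection$datasets))
  for (k in seq_along(collection$datasets)) {
    m <- collection$datasets[[k]]
    missing_ids <- setdiff(ids, colnames(m))
    if (length(missing_ids))
      stop("scored id(s) absent from matrix: ",
           paste(head(missing_ids, 5L), collapse = ", "))
    resid <- residualize_matrix(m, metadata)[, ids, drop = FALSE]
    mdg <- gini_importance(resid, y, n_trees = n_trees, seed = seeds[k])
    oob[[k]] <- oob_evaluate(resid, y, n_trees = n_trees, seed = seeds[k])
    auc <- apply(resid, 2L, metabolite_auc, y = y)
    mw_p <- apply(resid, 2L, function(v) mann_whitney_test(v, y)$p)
    mean_a <- colMeans(m[a_rows, ids, drop = FALSE])
    mean_b <- colMeans(m[!a_rows, ids, drop = FALSE])
    per_ds[[k]] <- data.frame(metabolite_id = ids, mdg = mdg[ids],
                              auc = auc[ids], mw_p = mw_p[ids],
                              delta_pct = delta_percent(mean_a, mean_b)[ids],
                              stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, per_ds)
  agg <- function(col, fn) tapply(long[[col]], long$metabolite_id, fn)[ids]
  card <- data.frame(
    metabolite_id = ids,
    mdg = agg("mdg", mean), mdg_sd = agg("mdg", sd),
    auc = agg("auc", mean), auc_sd = agg("auc", sd),
    delta_pct = agg("delta_pct", mean), delta_pct_sd = agg("delta_pct", sd),
    mw_p = agg("mw_p", mean),
    stringsAsFactors = FALSE)
  card$direction <- ifelse(card$delta_pct >= 0, levels(y)[1L], levels(y)[2L])
  card$mw_significant <- card$mw_p < 0.05 / length(ids)
  card$core <- card$metabolite_id %in% (core_ids %||% character(0))
  card <- card[order(-card$mdg), , drop = FALSE]
  card$rank <- seq_len(nrow(card))
  if (!is.null(annotation))
    card <- merge(card, annotation, by = "metabolite_id", all.x = TRUE,
                  sort = FALSE)
  rownames(card) <- NULL
  attr(card, "oob") <- do.call(rbind, lapply(oob, function(o)
    data.frame(oob_score = o$oob_score, oob_error = o$oob_error)))
  class(card) <- c("metabolite_scorecard", "data.frame")
  card
}

#' Write a scorecard as TSV
#'
#' @param card A `metabolite_scorecard`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scorecard_tsv <- function(card, path) {
  data.table::fwrite(as.data.frame(card), path, sep = "\t", na = "NA")
  invisible(path)
}
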