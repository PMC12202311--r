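#' Mask per-metabolite outliers by the 5 x IQR rule
#'
#' For each metabolite, values deviating from the metabolite's median by
#' strictly more than `multiplier` times its interquartile range (both
#' computed over the non-NA values, quartiles by linear interpolation between
#' order statistics, i.e. [quantile()] type 7) are replaced by `NA`.
#' Metabolites with fewer than 4 observed values are skipped with a warning
#' because their quartiles are unstable.  Constant metabolites (IQR 0) are
#' never masked: the inequality is strict.
#'
#' @param matrix Abundance matrix (samples x metabolites, NA allowed).
#' @param multiplier IQR multiplier (default 5).
#' @return A list with `matrix` (masked copy) and `report` (a `qc_report`
#'   with the count of masked cells).
#' @export
mask_outliers <- function(matrix, multiplier = 5) {
  validate_abundance_matrix(matrix)
  stopifnot(is.numeric(multiplier), multiplier > 0)
  masked <- matrix
  n_masked <- 0L
  skipped <- character(0)
  for (j in seq_len(ncol(matrix))) {
    v <- matrix[, j]
    obs <- !is.na(v)
    if (sum(obs) < 4L) {
      skipped <- c(skipped, colnames(matrix)[j])
      next
    }
    med <- median(v[obs])
    iqr <- diff(quantile(v[obs], c(0.25, 0.75), names = FALSE))
    flag <- obs & abs(v - med) > multiplier * iqr
    if (any(flag)) {
      masked[flag, j] <- NA_real_
      n_masked <- n_masked + sum(flag)
    }
  }
  if (length(skipped))
    warning("outlier masking skipped ", length(skipped),
            " metabolite(s) with < 4 observed values: ",
            paste(head(skipped, 5L), collapse = ", "))
  report <- structure(list(n_outliers_masked = n_masked,
                           skipped_metabolites = skipped,
                           multiplier = multiplier),
                      class = "qc_report")
  list(matrix = masked, report = report)
}

#' Filter metabolites and samples by annotation class and missingness
#'
#' Applies the cleaning cascade in a fixed order: (1) drop metabolites whose
#' `origin_class` is xenobiotic; (2) drop metabolites with an NA fraction
#' strictly greater than `max_metabolite_na`; (3) drop samples with an NA
#' fraction strictly greater than `max_sample_na`, computed over the
#' metabolites that survived steps 1-2.  All thresholds are strict ("more
#' than").
#'
#' @param matrix Abundance matrix.
#' @param annotation Metabolite annotation covering every column; must have
#'   `metabolite_id` and `origin_class` columns.
#' @param max_metabolite_na Metabolite NA-fraction threshold (default 0.25).
#' @param max_sample_na Sample NA-fraction threshold (default 0.30).
#' @return A list with `matrix` (filtered) and `report` (a `qc_report` listing
#'   removed ids with their NA fractions).
#' @export
filter_matrix <- function(matrix, annotation,
                          max_metabolite_na = 0.25, max_sample_na = 0.30) {
  validate_abundance_matrix(matrix)
  uncovered <- setdiff(colnames(matrix), annotation$metabolite_id)
  if (length(uncovered))
    stop("annotation does not cover metabolite(s): ",
         paste(head(uncovered, 5L), collapse = ", "))

  origin <- annotation$origin_class[match(colnames(matrix),
                                          annotation$metabolite_id)]
  xeno <- colnames(matrix)[grepl("^xenobiotic", tolower(origin))]
  m <- matrix[, setdiff(colnames(matrix), xeno), drop = FALSE]

  met_na <- colMeans(is.na(m))
  drop_met <- names(met_na)[met_na > max_metabolite_na]
  m <- m[, setdiff(colnames(m), drop_met), drop = FALSE]

  if (ncol(m) == 0L)
    stop("no metabolites survive filtering")
  smp_na <- rowMeans(is.na(m))
  drop_smp <- names(smp_na)[smp_na > max_sample_na]
  m <- m[setdiff(rownames(m), drop_smp), , drop = FALSE]
  if (nrow(m) == 0L)
    stop("no samples survive filtering")

  report <- structure(list(
    removed_xenobiotics = xeno,
    removed_metabolites = setNames(met_na[drop_met], drop_met),
    removed_samples = setNames(smp_na[drop_smp], drop_smp),
    thresholds = c(metabolite = max_metabolite_na, sample = max_sample_na)),
    class = "qc_report")
  list(matrix = m, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  if (!is.null(x$n_outliers_masked))
    cat("  outlier cells masked:", x$n_outliers_masked, "\n")
  if (!is.null(x$removed_xenobiotics))
    cat("  xenobiotics removed:", length(x$removed_xenobiotics),
        "| metabolites removed:", length(x$removed_metabolites),
        "| samples removed:", length(x$removed_samples), "\n")
  invisible(x)
}
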