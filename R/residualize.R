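#' Remove weight and collection-day confounding by per-metabolite regression
#'
#' Fits, for every metabolite independently, the ordinary least-squares model
#' `y_i = b0 + b_w w_i + sum_j b_Cj d_ij + xi_i`, where `w_i` is body weight
#' and `d_i1 .. d_i(J-1)` are reference-coded dummies for the J collection-day
#' levels (reference = lexicographically smallest day label), and returns the
#' residuals `observed - fitted`.  With `include_group = TRUE` a group
#' indicator is added to the design; this variant backs the population-level
#' correlations of the metabolite network, where the sex effect itself must
#' be removed.
#'
#' A constant covariate column (e.g. weight identical across samples, or a
#' single day level) is dropped from the design rather than producing a
#' rank-deficient fit; any remaining collinearity is an error.
#'
#' @param matrix Complete abundance matrix (post-imputation; no NA).
#' @param metadata Sample metadata covering all rows of `matrix`.
#' @param include_group Add a group fixed effect to the design.
#' @return Numeric matrix of residuals with the same dimnames as `matrix`;
#'   per-metabolite means are 0 and residuals are orthogonal to every design
#'   column up to numerical tolerance.
#' @export
residualize_matrix <- function(matrix, metadata, include_group = FALSE) {
  validate_abundance_matrix(matrix, allow_na = FALSE)
  metadata <- validate_metadata(metadata, rownames(matrix))
  day <- droplevels(metadata$day)
  singletons <- names(which(table(day) == 1L))
  if (length(singletons))
    warning("day level(s) with a single sample (residual forced to 0 there): ",
            paste(singletons, collapse = ", "))

  design <- stats::model.matrix(~ weight_kg + day, data =
                                  data.frame(weight_kg = metadata$weight_kg,
                                             day = day))
  if (include_group)
    design <- cbind(design,
                    group = as.numeric(metadata$group ==
                                         levels(metadata$group)[1L]))
  # drop constant non-intercept columns (e.g. weight with zero variance)
  keep <- c(TRUE, apply(design[, -1L, drop = FALSE], 2L,
                        function(col) var(col) > 0))
  design <- design[, keep, drop = FALSE]
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("rank-deficient confounder design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  residuals <- qr.resid(qr_d, matrix)
  dimnames(residuals) <- dimnames(matrix)
  residuals
}

#' Residualize every member of an imputed collection
#'
#' @param collection An `imputed_collection`.
#' @inheritParams residualize_matrix
#' @return A named list of residual matrices, one per completed dataset.
#' @export
residualize_collection <- function(collection, metadata,
                                   include_group = FALSE) {
  stopifnot(inherits(collection, "imputed_collection"))
  lapply(collection$datasets, residualize_matrix, metadata = metadata,
         include_group = include_group)
}
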