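#' @importFrom stats coef complete.cases cor lm.fit median p.adjust pbinom
#'   phyper pnorm prcomp qnorm quantile rbinom rlnorm rnorm runif sd var
#'   wilcox.test setNames
#' @importFrom utils head modifyList
NULL

#' Derive reproducible sub-seeds from a single master seed
#'
#' All randomness in the pipeline flows from one master seed through named
#' sub-streams, so that individual stages (simulation, imputation, fold
#' assignment, selector runs) are independently reproducible.  The scheme is
#' deterministic: the stream label is folded into a 31-bit offset via a
#' polynomial character hash, the offset is added to the master seed modulo
#' 2^31 - 1, and the resulting seed drives one [sample.int()] draw of `n`
#' sub-seeds.  The caller's RNG state is left untouched.
#'
#' @param seed Master integer seed.
#' @param label Character stream label (e.g. `"imputation"`).
#' @param n Number of sub-seeds to draw.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, label, n = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label), n >= 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  sub <- (abs(as.numeric(seed)) + h) %% m
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub))
  sample.int(m - 1L, n, replace = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an abundance matrix
#'
#' An abundance matrix is a numeric `samples x metabolites` matrix with unique
#' row names (sample ids), unique column names (metabolite ids), and
#' non-negative values; `NA` marks missing abundances.
#'
#' @param matrix Candidate matrix.
#' @param allow_na Whether `NA` cells are permitted.
#' @return The matrix, invisibly, after validation.
#' @export
validate_abundance_matrix <- function(matrix, allow_na = TRUE) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("abundance matrix must be a numeric matrix (samples x metabolites)")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop("abundance matrix needs unique sample ids as row names")
  if (is.null(colnames(matrix)) || anyDuplicated(colnames(matrix)))
    stop("abundance matrix needs unique metabolite ids as column names")
  if (!allow_na && anyNA(matrix))
    stop("abundance matrix contains NA values where none are allowed")
  if (any(matrix < 0, na.rm = TRUE))
    stop("abundance matrix contains negative values")
  invisible(matrix)
}

#' Validate a sample metadata table
#'
#' Metadata must carry one row per sample with columns `sample_id`, `group`
#' (two-level factor; the first level is treated as group A, e.g. castrated
#' males), `weight_kg` and `day`.
#'
#' @param metadata Candidate data frame.
#' @param sample_ids Sample ids that must all be covered.
#' @return The metadata, ordered to match `sample_ids`, with `group` and `day`
#'   as factors.
#' @export
validate_metadata <- function(metadata, sample_ids = NULL) {
  required <- c("sample_id", "group", "weight_kg", "day")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!is.factor(metadata$group)) metadata$group <- factor(metadata$group)
  if (nlevels(metadata$group) != 2L)
    stop("metadata 'group' must have exactly 2 levels, found ",
         nlevels(metadata$group))
  metadata$day <- factor(metadata$day)
  if (!is.null(sample_ids)) {
    missing_samples <- setdiff(sample_ids, metadata$sample_id)
    if (length(missing_samples))
      stop("metadata does not cover sample(s): ",
           paste(head(missing_samples, 5L), collapse = ", "))
    metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
    rownames(metadata) <- NULL
  }
  metadata
}
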