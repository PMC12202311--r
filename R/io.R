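#' Read / write abundance matrices as TSV
#'
#' The on-disk dialect is tab-separated, samples in rows, first column
#' `sample_id`, remaining columns one per metabolite; missing token `NA`,
#' decimal point `.`.
#'
#' @param path TSV path.
#' @return For the reader, a numeric samples x metabolites matrix with sample
#'   ids as row names.
#' @export
read_abundance_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          data.table = FALSE)
  if (names(dt)[1L] != "sample_id")
    stop("abundance TSV must have 'sample_id' as its first column")
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "double"
  validate_abundance_matrix(m)
  m
}

#' @param matrix Numeric samples x metabolites matrix.
#' @rdname read_abundance_tsv
#' @export
write_abundance_tsv <- function(matrix, path) {
  validate_abundance_matrix(matrix)
  dt <- data.table::data.table(sample_id = rownames(matrix), matrix)
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read sample metadata / metabolite annotation TSVs
#'
#' @param path TSV path.
#' @return A data frame; metadata gets `group` and `day` coerced to factors.
#' @export
read_metadata_tsv <- function(path) {
  md <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          data.table = FALSE)
  validate_metadata(md)
}

#' @rdname read_metadata_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- data.table::fread(path, sep = "\t", na.strings = "NA",
                           data.table = FALSE)
  required <- c("metabolite_id", "origin_class")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols))
    stop("annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ann
}
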