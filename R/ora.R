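#' Read a pathway library from a GMT file
#'
#' Tab-separated: set id, description, then member metabolite ids (HMDB).
#' Parsed with [fgsea::gmtPathways()]; empty sets are dropped and duplicate
#' members within a set collapsed.
#'
#' @param path GMT file path.
#' @return A `pathway_library`: named list of unique member-id vectors, with
#'   a `description` attribute.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  desc <- vapply(strsplit(readLines(path), "\t"), function(f)
    if (length(f) >= 2L) f[2L] else "", character(1))
  names(desc) <- names(sets)
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) > 0L]
  structure(sets, description = desc[names(sets)], class = "pathway_library")
}

#' Map metabolites to HMDB identifiers
#'
#' Annotation cells may carry several comma/semicolon-separated HMDB ids; a
#' metabolite maps to a pathway set if any of its ids is a member, counted
#' once.  Metabolites without an HMDB id are dropped with a message.
#'
#' @param ids Metabolite ids to map.
#' @param annotation Annotation table with `metabolite_id` and `hmdb_id`.
#' @return Named list of HMDB id vectors, one element per mappable
#'   metabolite.
#' @export
map_hmdb <- function(ids, annotation) {
  hmdb <- annotation$hmdb_id[match(ids, annotation$metabolite_id)]
  parsed <- lapply(hmdb, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    trimws(strsplit(cell, "[,;]")[[1L]])
  })
  names(parsed) <- ids
  dropped <- sum(lengths(parsed) == 0L)
  if (dropped > 0L)
    message(dropped, " metabolite(s) without an HMDB id dropped from mapping")
  parsed[lengths(parsed) > 0L]
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric upper-tail enrichment of an input metabolite set
#' against each pathway set, with the universe restricted to metabolites
#' that map into the library.  P values are Benjamini-Hochberg adjusted
#' across the tested sets; a set is *kept* if its adjusted p (FDR) is below
#' `fdr_level` and it contains at least `min_overlap` input metabolites.
#' Sets with no overlap with the universe are skipped.
#'
#' @param input_ids Input metabolite identifiers (HMDB or any id space
#'   matching the library), a subset of `universe_ids`.
#' @param library A `pathway_library` (or plain named list of id vectors).
#' @param universe_ids Background identifiers (e.g. all profiled post-QC
#'   metabolites mapped to the library).
#' @param fdr_level FDR threshold for the kept flag (default 0.05).
#' @param min_overlap Minimum input metabolites in a kept set (default 2).
#' @return Data frame (class `ora_result`), one row per tested set:
#'   `set_id`, `overlap`, `set_size` (within the universe), `input_size`,
#'   `universe_size`, `p`, `q`, `kept`, ordered by `p`.
#' @export
over_representation <- function(input_ids, library, universe_ids,
                                fdr_level = 0.05, min_overlap = 2L) {
  if (!length(universe_ids)) stop("universe is empty")
  if (!length(library)) stop("pathway library is empty")
  universe_ids <- unique(universe_ids)
  input_ids <- unique(input_ids)
  stray <- setdiff(input_ids, universe_ids)
  if (length(stray))
    stop("input id(s) outside the universe: ",
         paste(head(stray, 5L), collapse = ", "))
  n_univ <- length(universe_ids)
  n_input <- length(input_ids)
  rows <- lapply(names(library), function(set_id) {
    members <- intersect(library[[set_id]], universe_ids)
    if (!length(members)) return(NULL)
    k <- length(intersect(members, input_ids))
    p <- phyper(k - 1L, length(members), n_univ - length(members), n_input,
                lower.tail = FALSE)
    data.frame(set_id = set_id, overlap = k, set_size = length(members),
               input_size = n_input, universe_size = n_univ, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no library set overlaps the universe")
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$kept <- out$q < fdr_level & out$overlap >= min_overlap
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}
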