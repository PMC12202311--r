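#' Three correlation tables for the metabolite network
#'
#' Pearson correlations among the given metabolites computed on confounder-
#' free residuals in three ways: at the population level (weight + day +
#' group fixed effect, so the sex difference itself does not inflate r), and
#' within each group separately (weight + day model on that group's
#' samples).
#'
#' @param matrix Complete abundance matrix (one imputed dataset).
#' @param metadata Sample metadata.
#' @param ids Metabolites to correlate (e.g. the selection set).
#' @return List of three correlation matrices named `population`, `group_a`,
#'   `group_b` (in the order of the group factor levels).
#' @export
correlation_triplet <- function(matrix, metadata, ids) {
  validate_abundance_matrix(matrix, allow_na = FALSE)
  metadata <- validate_metadata(metadata, rownames(matrix))
  missing_ids <- setdiff(ids, colnames(matrix))
  if (length(missing_ids))
    stop("id(s) absent from matrix: ",
         paste(head(missing_ids, 5L), collapse = ", "))
  if (length(ids) < 2L) stop("need at least 2 metabolites to correlate")
  small <- names(which(table(metadata$group) < 10L))
  if (length(small))
    warning("group(s) with < 10 samples give unstable correlations: ",
            paste(small, collapse = ", "))

  pop_resid <- residualize_matrix(matrix, metadata, include_group = TRUE)
  out <- list(population = cor(pop_resid[, ids, drop = FALSE]))
  for (g in seq_along(levels(metadata$group))) {
    rows <- metadata$group == levels(metadata$group)[g]
    resid <- suppressWarnings(
      residualize_matrix(matrix[rows, , drop = FALSE],
                         metadata[rows, , drop = FALSE]))
    out[[paste0("group_", letters[g])]] <- cor(resid[, ids, drop = FALSE])
  }
  out
}

#' Build the maximum-correlation network
#'
#' For every metabolite pair, the coefficient with the largest |r| across
#' the three correlation tables is retained; an edge is added if its
#' |r| >= `threshold` (inclusive).  The retained signed r and its source
#' table are recorded on the edge.
#'
#' @param triplet Output of [correlation_triplet()] (three aligned matrices).
#' @param threshold Absolute-correlation threshold (default 0.5, a medium
#'   correlation).
#' @return A `correlation_network`: `nodes` (ids), `edges` (data frame with
#'   `from`, `to`, `r`, `source`), and `component` membership per node.
#' @export
build_network <- function(triplet, threshold = 0.5) {
  stopifnot(is.list(triplet), length(triplet) >= 1L)
  ids <- colnames(triplet[[1L]])
  for (m in triplet)
    if (!identical(colnames(m), ids))
      stop("correlation tables are not aligned on the same id set")
  edges <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq((i + 1L), length(ids))) {
        rs <- vapply(triplet, function(m) m[i, j], numeric(1))
        best <- which.max(abs(rs))
        if (is.finite(rs[best]) && abs(rs[best]) >= threshold)
          edges[[length(edges) + 1L]] <-
            data.frame(from = ids[i], to = ids[j], r = unname(rs[best]),
                       source = names(triplet)[best],
                       stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), r = numeric(0),
               source = character(0), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  structure(list(nodes = ids, edges = edges, component = comp,
                 threshold = threshold),
            class = "correlation_network")
}

#' Per-node network statistics
#'
#' Degree, betweenness centrality normalized by `(n - 1)(n - 2) / 2` within
#' each connected component of size `n`, and the average shortest-path
#' length (unweighted hop count) to the other nodes of the node's component.
#' All three are `NA` for singleton nodes, the convention used for isolated
#' metabolites in reporting tables.
#'
#' @param network A [build_network()] result.
#' @return Data frame with `metabolite_id`, `degree`, `betweenness`,
#'   `avg_shortest_path`, `component`.
#' @export
node_statistics <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes))
  deg <- igraph::degree(g)
  btw <- setNames(rep(NA_real_, length(network$nodes)), network$nodes)
  asp <- btw
  comp <- igraph::components(g)
  for (c_id in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == c_id]
    n <- length(members)
    if (n < 2L) next
    sub <- igraph::induced_subgraph(g, members)
    b <- igraph::betweenness(sub, directed = FALSE, normalized = FALSE)
    denom <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
    btw[members] <- b[members] / denom
    d <- igraph::distances(sub)
    asp[members] <- rowSums(d[members, members, drop = FALSE]) / (n - 1)
  }
  out <- data.frame(metabolite_id = network$nodes,
                    degree = as.integer(deg[network$nodes]),
                    betweenness = btw[network$nodes],
                    avg_shortest_path = asp[network$nodes],
                    component = as.integer(comp$membership[network$nodes]),
                    stringsAsFactors = FALSE)
  out$degree[out$degree == 0L] <- NA_integer_ # singleton convention: "-"
  rownames(out) <- NULL
  out
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation network: %d nodes, %d edges (|r| >= %.2f), %d components\n",
              length(x$nodes), nrow(x$edges), x$threshold,
              length(unique(x$component))))
  invisible(x)
}

#' Export a network for Cytoscape
#'
#' Writes a SIF edge list (`from  correlates_with  to`) and a GraphML file
#' with edge attributes `r` and `source` and any node attributes supplied.
#'
#' @param network A `correlation_network`.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.sif` and `<prefix>.graphml`.
#' @param node_attributes Optional data frame keyed by `metabolite_id` with
#'   columns to attach to nodes (e.g. direction, core flag, AUC, MDG,
#'   super-pathway).
#' @return Invisible character vector of the two written paths.
#' @export
export_network <- function(network, path_prefix, node_attributes = NULL) {
  stopifnot(inherits(network, "correlation_network"))
  sif <- file.path(paste0(path_prefix, ".sif"))
  if (nrow(network$edges)) {
    writeLines(sprintf("%s\tcorrelates_with\t%s",
                       network$edges$from, network$edges$to), sif)
  } else writeLines(character(0), sif)
  vertices <- data.frame(name = network$nodes, stringsAsFactors = FALSE)
  if (!is.null(node_attributes)) {
    idx <- match(vertices$name, node_attributes$metabolite_id)
    extra <- node_attributes[idx, setdiff(names(node_attributes),
                                          "metabolite_id"), drop = FALSE]
    vertices <- cbind(vertices, extra)
  }
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = vertices)
  graphml <- file.path(paste0(path_prefix, ".graphml"))
  igraph::write_graph(g, graphml, format = "graphml")
  invisible(c(sif = sif, graphml = graphml))
}
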