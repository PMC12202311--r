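# Independent brute-force oracles used to validate the implementation.

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# C(n1 + n2, n1) group labelings of the pooled values.
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_stat(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2L, u_stat)
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Exact hypergeometric upper-tail p by enumerating every possible draw of
# `n_input` elements from a universe of size `n_univ` containing `set_size`
# marked elements; feasible for n_univ <= 25.
hyper_enum_p <- function(overlap, set_size, n_univ, n_input) {
  marked <- seq_len(set_size)
  draws <- utils::combn(n_univ, n_input)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= overlap)
}

# Brute-force node statistics from all-pairs shortest paths: Floyd-Warshall
# distances, recursive enumeration of every shortest path, pair-fraction
# betweenness normalized by (n-1)(n-2)/2 within each component.
bf_node_stats <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      adj[edges$from[i], edges$to[i]] <- TRUE
      adj[edges$to[i], edges$from[i]] <- TRUE
    }
  }
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]

  all_shortest_paths <- function(s, t) {
    # enumerate every path of length d[s, t] from s to t
    paths <- list()
    recurse <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (v in seq_len(n))
        if (adj[last, v] && d[last, t] == d[v, t] + 1)
          recurse(c(path, v))
    }
    recurse(s)
    paths
  }

  btw_count <- setNames(numeric(n), nodes)
  for (s in seq_len(n - 1L)) for (t in seq((s + 1L), n)) {
    if (!is.finite(d[s, t]) || d[s, t] == 0) next
    paths <- all_shortest_paths(s, t)
    through <- vapply(seq_len(n), function(v)
      mean(vapply(paths, function(p) v %in% p[-c(1L, length(p))],
                  logical(1))), numeric(1))
    btw_count <- btw_count + through
  }

  comp <- setNames(rep(NA_integer_, n), nodes)
  c_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    c_id <- c_id + 1L
    comp[is.finite(d[i, ])] <- c_id
  }
  out <- data.frame(metabolite_id = nodes, degree = NA_integer_,
                    betweenness = NA_real_, avg_shortest_path = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    members <- which(comp == comp[i])
    nc <- length(members)
    if (nc < 2L) next
    out$degree[i] <- sum(adj[i, ])
    denom <- if (nc > 2L) (nc - 1) * (nc - 2) / 2 else 1
    out$betweenness[i] <- btw_count[i] / denom
    out$avg_shortest_path[i] <- sum(d[i, members]) / (nc - 1)
  }
  out
}

# random undirected graph with up to max_nodes nodes as an edge data frame
random_graph <- function(n_nodes, p_edge = 0.3) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p_edge
  list(nodes = nodes,
       edges = data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                          stringsAsFactors = FALSE))
}
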