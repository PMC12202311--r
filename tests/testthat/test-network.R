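triplet_for <- function(pop, ga, gb, ids = c("A", "B")) {
  mk <- function(r) {
    m <- matrix(c(1, r, r, 1), 2, 2, dimnames = list(ids, ids))
    m
  }
  list(population = mk(pop), group_a = mk(ga), group_b = mk(gb))
}

test_that("the strongest-|r| rule picks the right source and sign", {
  net <- build_network(triplet_for(0.3, -0.6, 0.2), threshold = 0.5)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$r, -0.6)
  expect_identical(net$edges$source, "group_a")
})

test_that("the |r| >= 0.5 threshold is inclusive", {
  expect_identical(nrow(build_network(triplet_for(0.49, 0.2, 0.1))$edges), 0L)
  expect_identical(nrow(build_network(triplet_for(0.50, 0.2, 0.1))$edges), 1L)
})

test_that("components and singletons are identified", {
  ids <- c("A", "B", "C", "D")
  mk <- function() matrix(0, 4, 4, dimnames = list(ids, ids)) + diag(4)
  pop <- mk()
  pop["A", "B"] <- pop["B", "A"] <- 0.8
  pop["B", "C"] <- pop["C", "B"] <- 0.7
  net <- build_network(list(population = pop), threshold = 0.5)
  expect_identical(nrow(net$edges), 2L)
  expect_identical(length(unique(net$component)), 2L)
  stats <- node_statistics(net)
  d_stat <- stats[stats$metabolite_id == "D", ]
  expect_true(is.na(d_stat$degree) && is.na(d_stat$betweenness) &&
                is.na(d_stat$avg_shortest_path))
})

test_that("path and complete-graph statistics match hand computation", {
  ids <- c("A", "B", "C")
  pop <- diag(3); dimnames(pop) <- list(ids, ids)
  pop["A", "B"] <- pop["B", "A"] <- 0.9
  pop["B", "C"] <- pop["C", "B"] <- 0.9
  stats <- node_statistics(build_network(list(population = pop), 0.5))
  expect_identical(stats$degree, c(1L, 2L, 1L))
  expect_equal(stats$betweenness, c(0, 1, 0))
  expect_equal(stats$avg_shortest_path, c(1.5, 1, 1.5))

  ids4 <- c("A", "B", "C", "D")
  k4 <- matrix(0.9, 4, 4, dimnames = list(ids4, ids4)); diag(k4) <- 1
  s4 <- node_statistics(build_network(list(population = k4), 0.5))
  expect_identical(s4$degree, rep(3L, 4L))
  expect_equal(s4$betweenness, rep(0, 4L))
  expect_equal(s4$avg_shortest_path, rep(1, 4L))
})

test_that("node statistics equal the brute-force oracle on random graphs", {
  set.seed(5)
  for (i in 1:10) {
    g <- random_graph(sample(4:12, 1L), p_edge = runif(1, 0.15, 0.5))
    net <- structure(list(nodes = g$nodes, edges = g$edges,
                          component = NULL, threshold = 0),
                     class = "correlation_network")
    got <- node_statistics(net)
    oracle <- bf_node_stats(g$nodes, g$edges)
    expect_equal(got$degree, oracle$degree)
    expect_equal(got$betweenness, oracle$betweenness, tolerance = 1e-12)
    expect_equal(got$avg_shortest_path, oracle$avg_shortest_path,
                 tolerance = 1e-12)
  }
})

test_that("raising the threshold never adds edges", {
  fix <- tiny_complete(seed = 55)
  trip <- correlation_triplet(fix$matrix, fix$metadata,
                              colnames(fix$matrix)[1:10])
  e_lo <- build_network(trip, 0.4)$edges
  e_hi <- build_network(trip, 0.6)$edges
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(e_hi) %in% key(e_lo)))
})

test_that("correlation triplet residualizes per group and drops diagonals", {
  fix <- tiny_complete(seed = 60)
  m <- cbind(fix$matrix, M_dup = fix$matrix[, 1L])
  trip <- correlation_triplet(m, fix$metadata, c(colnames(fix$matrix)[1L],
                                                 "M_dup", "M0003"))
  for (tab in trip) {
    expect_equal(tab[1L, "M_dup"], 1, tolerance = 1e-12)
    expect_equal(unname(diag(tab)), rep(1, 3L))
  }
  net <- build_network(trip, 0.5)
  expect_false(any(net$edges$from == net$edges$to))

  # hand Pearson on the population residuals reproduces the table
  resid <- residualize_matrix(m, fix$metadata, include_group = TRUE)
  a <- resid[, colnames(fix$matrix)[1L]]; b <- resid[, "M0003"]
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(trip$population[colnames(fix$matrix)[1L], "M0003"], hand,
               tolerance = 1e-12)
})

test_that("planted within-block pairs are recovered as edges", {
  ds <- generate_dataset(generator_config(
    n_group_a = 150, n_group_b = 150, n_metabolites = 12, n_informative = 0,
    block_sizes = c(4L, 4L), within_block_correlation = 0.75,
    n_days = 4, missing_rate = 0, outlier_rate = 0, seed = 66))
  trip <- correlation_triplet(ds$matrix, ds$metadata, colnames(ds$matrix))
  net <- build_network(trip, 0.5)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted <- key(ds$truth$planted_edges$metabolite_1,
                 ds$truth$planted_edges$metabolite_2)
  got <- key(net$edges$from, net$edges$to)
  expect_gte(mean(planted %in% got), 0.9)
})

test_that("network export writes SIF and Cytoscape-loadable GraphML", {
  fix <- tiny_complete(seed = 70)
  trip <- correlation_triplet(fix$matrix, fix$metadata,
                              colnames(fix$matrix)[1:5])
  net <- build_network(trip, 0.5)
  prefix <- file.path(withr::local_tempdir(), "net")
  attrs <- data.frame(metabolite_id = net$nodes,
                      direction = "castrated_male")
  paths <- export_network(net, prefix, node_attributes = attrs)
  expect_true(all(file.exists(paths)))
  g <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(g), length(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
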