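ig <- function(el, n = max(el)) {
  igraph::graph_from_edgelist(el, directed = FALSE) |>
    (\(g) { igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g))); g })()
}

test_that("characteristic path length matches the BFS oracle", {
  expect_equal(characteristic_path_length(igraph::make_full_graph(4)), 1)
  path3 <- ig(cbind(1:2, 2:3))
  expect_equal(characteristic_path_length(path3), 1)   # median of {1,1,2}
  ring6 <- igraph::make_ring(6)
  expect_equal(characteristic_path_length(ring6), 2)
  # random connected graphs vs the hand-rolled BFS
  withr::with_seed(5, {
    for (r in 1:5) {
      g <- igraph::sample_gnp(12, 0.35)
      if (igraph::components(g)$no > 1) next
      adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
      d <- oracle_bfs_distances(adj)
      expect_equal(characteristic_path_length(g),
                   median(d[upper.tri(d)]))
      expect_equal(characteristic_path_length(g, agg = "mean"),
                   mean(d[upper.tri(d)]))
    }
  })
  expect_error(characteristic_path_length(ig(cbind(c(1, 3), c(2, 4)))),
               "disconnected")
})

test_that("clustering coefficient matches exhaustive triangle counting", {
  expect_equal(clustering_coefficient(igraph::make_full_graph(3)), 1)
  expect_equal(clustering_coefficient(igraph::make_star(4, mode = "undirected")),
               0)
  # kite graph: K4 minus one edge plus a pendant
  kite <- ig(rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4), c(4, 5)))
  adj <- igraph::as_adjacency_matrix(kite, sparse = FALSE)
  expect_equal(clustering_coefficient(kite), mean(oracle_clustering(adj)))
  withr::with_seed(6, {
    for (r in 1:5) {
      g <- igraph::sample_gnp(15, 0.3)
      adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
      expect_equal(clustering_coefficient(g), mean(oracle_clustering(adj)),
                   tolerance = 1e-12)
    }
  })
})

test_that("participation coefficient matches the direct summation oracle", {
  # single module: 0 for every node
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- letters[1:5]
  part <- setNames(rep(1, 5), letters[1:5])
  expect_equal(participation_coefficient(g, part), 0)
  # a node with 4 edges split 2/2 across two modules scores 1 - 2*(1/2)^2
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", "a1", "a2", "b1", "b2")
  p <- setNames(c(1, 1, 1, 2, 2), c("hub", "a1", "a2", "b1", "b2"))
  adj <- igraph::as_adjacency_matrix(star, sparse = FALSE)
  node_vals <- oracle_participation(adj, p[igraph::V(star)$name])
  expect_equal(node_vals[1], 0.5)
  expect_equal(participation_coefficient(star, p), mean(node_vals),
               tolerance = 1e-12)
  # random graph + random 3-module partition vs the oracle
  withr::with_seed(7, {
    g <- igraph::sample_gnp(20, 0.25)
    igraph::V(g)$name <- sprintf("n%02d", 1:20)
    mem <- sample(1:3, 20, replace = TRUE)
    part <- setNames(mem, igraph::V(g)$name)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    expect_equal(participation_coefficient(g, part),
                 mean(oracle_participation(adj, mem)), tolerance = 1e-12)
  })
  # uncovered nodes are rejected
  expect_error(participation_coefficient(star, p[1:3]), "cover")
})

test_that("community detection recovers planted cliques and is deterministic", {
  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(5),
                                        igraph::make_full_graph(5))
  two_cliques <- igraph::add_edges(two_cliques, c(1, 6))
  igraph::V(two_cliques)$name <- sprintf("n%02d", 1:10)
  cm <- detect_communities(two_cliques)
  mem <- igraph::membership(cm)
  expect_identical(length(unique(mem)), 2L)
  expect_identical(length(unique(mem[1:5])), 1L)
  expect_identical(length(unique(mem[6:10])), 1L)
  # complete graph: one module
  full <- igraph::make_full_graph(6)
  igraph::V(full)$name <- letters[1:6]
  expect_identical(length(unique(igraph::membership(detect_communities(full)))),
                   1L)
  expect_identical(igraph::membership(detect_communities(two_cliques, seed = 1)),
                   igraph::membership(detect_communities(two_cliques, seed = 2)))
})

test_that("small-world index behaves across canonical graph families", {
  # complete graph: rewiring cannot change K_n
  expect_equal(small_world_index(igraph::make_full_graph(8), seed = 1), 1)
  # Erdos-Renyi graphs are their own null: index near 1 on average
  withr::with_seed(10, {
    vals <- replicate(20, {
      repeat {
        g <- igraph::sample_gnp(50, 0.2)
        if (igraph::components(g)$no == 1) break
      }
      small_world_index(g, n_random_refs = 5,
                        seed = sample.int(1e6, 1))
    })
  })
  expect_gt(mean(vals), 0.8); expect_lt(mean(vals), 1.2)
  # Watts-Strogatz ring: canonical small-world regime
  withr::with_seed(12, {
    ws <- replicate(10, {
      repeat {
        g <- igraph::sample_smallworld(1, 100, 3, 0.1)
        g <- igraph::simplify(g)
        if (igraph::components(g)$no == 1) break
      }
      small_world_index(g, n_random_refs = 5, seed = sample.int(1e6, 1))
    })
  })
  expect_gt(mean(ws), 1.5)
  expect_error(small_world_index(igraph::make_full_graph(3)), ">= 4 nodes")
})

test_that("small-world index is reproducible under a seed", {
  withr::with_seed(3, g <- igraph::sample_gnp(30, 0.2))
  expect_identical(small_world_index(g, seed = 77),
                   small_world_index(g, seed = 77))
})
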