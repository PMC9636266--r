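# Internal: accept a thresholded_graph or a bare igraph.
as_metric_graph <- function(g) {
  if (inherits(g, "thresholded_graph")) g$graph
  else if (igraph::is_igraph(g)) g
  else abort("expected a thresholded_graph or an igraph object")
}

#' Characteristic path length (median hop count)
#'
#' The median over all unordered node pairs of the unweighted shortest-path
#' hop count. The median (rather than mean) convention makes the measure
#' robust to the long-tail pairs that appear in sparse pruned graphs;
#' `agg = "mean"` gives the classical mean path length.
#'
#' @param g a `thresholded_graph` or igraph graph; must be connected
#'   (pruning must precede metric computation).
#' @param agg `"median"` (default) or `"mean"`.
#' @return path length in hops.
#' @export
characteristic_path_length <- function(g, agg = c("median", "mean")) {
  agg <- match.arg(agg)
  g <- as_metric_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) abort("characteristic path length needs >= 2 nodes")
  d <- igraph::distances(g, weights = NA)  # unweighted BFS hop counts
  dd <- d[upper.tri(d)]
  if (any(is.infinite(dd))) {
    abort("graph is disconnected; prune to the biggest component first")
  }
  if (agg == "median") median(dd) else mean(dd)
}

#' Mean binary clustering coefficient
#'
#' Per node, the proportion of existing edges among its neighbours to the
#' number possible; nodes of degree < 2 contribute 0. Returns the mean over
#' nodes. Computed on the binarized (thresholded) graph; `weighted = TRUE`
#' uses the Barrat weighted generalization instead.
#'
#' @param g a `thresholded_graph` or igraph graph.
#' @param weighted use edge weights (Barrat local coefficient).
#' @return mean clustering in `[0, 1]`.
#' @export
clustering_coefficient <- function(g, weighted = FALSE) {
  g <- as_metric_graph(g)
  if (igraph::vcount(g) < 1) abort("empty graph")
  cc <- if (weighted) {
    igraph::transitivity(g, type = "barrat", isolates = "zero")
  } else {
    igraph::transitivity(g, type = "local", isolates = "zero")
  }
  cc[!is.finite(cc)] <- 0
  mean(cc)
}

#' Mean participation coefficient
#'
#' For node i with degree `k_i` and `k_im` edges into module m:
#' `P_i = 1 - sum_m (k_im / k_i)^2`. A node whose edges spread uniformly
#' over modules approaches 1; a node confined to one module scores 0.
#' Returns the mean over nodes (degree-0 nodes contribute 0; these cannot
#' occur after isolated-node pruning).
#'
#' @param g a `thresholded_graph` or igraph graph.
#' @param partition named integer/character vector mapping every node label
#'   to a module, or a `communities` object from [detect_communities()].
#'   Default: modules from [detect_communities()].
#' @return mean participation coefficient in `[0, 1]`.
#' @export
participation_coefficient <- function(g, partition = NULL) {
  g <- as_metric_graph(g)
  labels <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (is.null(partition)) partition <- detect_communities(g)
  if (inherits(partition, "communities")) {
    partition <- setNames(igraph::membership(partition), labels)
  }
  if (!all(labels %in% names(partition))) {
    abort("partition does not cover nodes: ",
          paste(setdiff(labels, names(partition)), collapse = ", "))
  }
  mem <- as.integer(factor(partition[labels]))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  deg <- rowSums(adj)
  p <- vapply(seq_along(labels), function(i) {
    if (deg[i] == 0) return(0)
    kim <- tapply(adj[i, ], mem, sum)
    1 - sum((kim / deg[i])^2)
  }, numeric(1))
  mean(p)
}

#' Modularity-maximizing community partition
#'
#' Greedy agglomerative modularity optimization (fast-greedy). The
#' algorithm is deterministic; the `seed` argument is accepted for interface
#' symmetry with the stochastic metrics and to future-proof stochastic
#' alternatives.
#'
#' @param g a `thresholded_graph` or igraph graph (connected).
#' @param seed unused by the deterministic greedy algorithm.
#' @param weighted use edge weights in the modularity objective.
#' @return an igraph `communities` object.
#' @export
detect_communities <- function(g, seed = NULL, weighted = FALSE) {
  g <- as_metric_graph(g)
  gs <- igraph::simplify(g)
  w <- if (weighted) igraph::E(gs)$weight else NULL
  fg <- igraph::cluster_fast_greedy(gs, weights = w)
  # ties in peak modularity (e.g. a complete graph, where every merge keeps
  # Q = 0) are broken toward the coarsest partition
  mods <- fg$modularity
  best <- max(which(mods >= max(mods) - 1e-12))
  k <- igraph::vcount(gs) - (best - 1L)
  if (k < length(fg)) {
    mem <- igraph::cut_at(fg, no = k)
    fg$membership <- mem
  }
  fg
}

#' Small-world index (sigma form)
#'
#' `SWI = (C / <C_rand>) / (L / <L_rand>)` where C is the mean binary
#' clustering coefficient, L the median-hop characteristic path length, and
#' the reference values are averages over `n_random_refs` degree-preserving
#' rewirings of the graph (double-edge swaps; rewirings that disconnect the
#' graph are resampled). Random graphs score ~1; small-world graphs score
#' substantially above 1.
#'
#' @param g a `thresholded_graph` or igraph graph; connected, >= 4 nodes.
#' @param n_random_refs number of random reference graphs (default 20).
#' @param seed integer seed for the rewiring RNG.
#' @param max_tries connected-rewiring attempts per reference before
#'   giving up with an error.
#' @return small-world index (ratio >= 0).
#' @export
small_world_index <- function(g, n_random_refs = 20, seed = NULL,
                              max_tries = 50) {
  g <- as_metric_graph(g)
  n <- igraph::vcount(g)
  if (n < 4) abort("small-world index needs >= 4 nodes")
  if (igraph::components(g)$no > 1) abort("graph must be connected")
  C <- clustering_coefficient(g)
  L <- characteristic_path_length(g)
  run <- function() {
    niter <- max(10 * igraph::ecount(g), 100)
    Cr <- numeric(n_random_refs)
    Lr <- numeric(n_random_refs)
    for (r in seq_len(n_random_refs)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
        if (igraph::components(gr)$no == 1) { ok <- TRUE; break }
      }
      if (!ok) {
        abort("failed to produce a connected degree-preserving rewiring in ",
              max_tries, " attempts")
      }
      Cr[r] <- clustering_coefficient(gr)
      Lr[r] <- characteristic_path_length(gr)
    }
    list(C = mean(Cr), L = mean(Lr))
  }
  ref <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (ref$C == 0 || L == 0) {
    # clustering-free references (e.g. trees, stars): index undefined -> 0
    # only when the graph itself has no clustering either
    if (C == 0) return(if (L == ref$L) 1 else (ref$L / L))
    abort("reference clustering is zero; sigma index undefined")
  }
  (C / ref$C) / (L / ref$L)
}
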