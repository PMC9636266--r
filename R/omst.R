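# Internal: deterministic Kruskal spanning tree on a residual weight matrix.
# Edge key = (distance, i, j) ascending with distance = 1/weight (or
# 1 - weight), so the tree maximizes total synchronization weight; with
# all-equal weights the lexicographically smallest edge list wins.
kruskal_mst <- function(w, labels, distance = c("inverse", "one_minus")) {
  distance <- match.arg(distance)
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (!nrow(idx)) abort("residual graph has no positive-weight edges")
  wt <- w[idx]
  d <- if (distance == "inverse") 1 / wt else 1 - wt
  ord <- order(d, idx[, 1], idx[, 2])
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  edges <- matrix(0L, 0, 2)
  weights <- numeric(0)
  for (k in ord) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[max(ri, rj)] <- min(ri, rj)
      edges <- rbind(edges, c(i, j))
      weights <- c(weights, wt[k])
      if (nrow(edges) == n - 1) break
    }
  }
  if (nrow(edges) < n - 1) {
    abort("residual graph is disconnected; no spanning tree exists")
  }
  ord2 <- order(edges[, 1], edges[, 2])
  tibble(i = labels[edges[ord2, 1]], j = labels[edges[ord2, 2]],
         weight = weights[ord2],
         i_idx = edges[ord2, 1], j_idx = edges[ord2, 2])
}

#' Maximum-synchronization spanning tree
#'
#' Spanning tree minimizing total distance (distance = `1/weight` by
#' default, i.e. maximizing total synchronization weight), with
#' deterministic lexicographic tie-breaking. Zero-weight entries are treated
#' as absent edges.
#'
#' @param m a `connectivity_matrix` or symmetric nonnegative matrix
#'   (possibly a residual with extracted edges zeroed).
#' @param distance `"inverse"` (`1/w`, default) or `"one_minus"` (`1 - w`).
#' @return tibble of the `N - 1` tree edges: `i`, `j`, `weight` (labels),
#'   plus integer indices `i_idx`, `j_idx`.
#' @export
maximum_spanning_tree <- function(m, distance = c("inverse", "one_minus")) {
  if (inherits(m, "connectivity_matrix")) {
    w <- m$weights; labels <- m$labels
  } else {
    w <- as.matrix(m)
    labels <- rownames(w) %||% sprintf("n%02d", seq_len(nrow(w)))
  }
  kruskal_mst(w, labels, match.arg(distance))
}

# Internal: global efficiency of a weighted adjacency matrix: mean over
# node pairs of 1/d_ij with d_ij the shortest path on distances 1/w.
# Unreachable pairs contribute 0.
global_efficiency_w <- function(w, distance = "inverse") {
  n <- nrow(w)
  dmat <- w
  pos <- dmat > 0
  dmat[pos] <- if (distance == "inverse") 1 / dmat[pos] else 1 - dmat[pos]
  dmat[!pos] <- 0
  g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Orthogonal minimum spanning tree (OMST) network extraction
#'
#' Repeatedly extracts the maximum-synchronization spanning tree from the
#' residual graph, zeroing the extracted edges each round so successive
#' trees are pairwise edge-disjoint ("orthogonal"), and accumulates them
#' into a union network. After round m the trace records the wiring cost
#' `cost(m)` (summed union weight over total graph weight), the global
#' efficiency `GE(m)` of the union (weighted, normalized by the full
#' graph's efficiency so `GE` lies in `[0, 1]`), and the global cost
#' efficiency `J(m) = GE(m) - cost(m)`. The selected network is the union
#' of the first `argmax J` trees -- the equilibrium between efficiency
#' gained and wiring cost paid. Extraction stops when the residual
#' disconnects or when `J` has not improved for `patience` rounds.
#'
#' @param m a `connectivity_matrix` or symmetric nonnegative matrix
#'   (connected on its positive edges).
#' @param distance distance transform for tree extraction and efficiency,
#'   `"inverse"` or `"one_minus"`.
#' @param patience rounds to continue past the current argmax of J.
#' @param max_msts optional cap on extraction rounds (default: until the
#'   residual disconnects).
#'
#' @return object of class `omst_result`: `msts` (list of edge tibbles),
#'   `union_graph` (igraph, weighted, of the selected union), `gce_trace`
#'   (tibble m, cost, ge, J), `selected_m`, `density` (selected union edges
#'   over `N(N-1)/2`), `labels`.
#' @export
extract_orthogonal_msts <- function(m, distance = c("inverse", "one_minus"),
                                    patience = 3, max_msts = Inf) {
  distance <- match.arg(distance)
  if (inherits(m, "connectivity_matrix")) {
    w <- m$weights; labels <- m$labels
  } else {
    w <- as.matrix(m)
    labels <- rownames(w) %||% sprintf("n%02d", seq_len(nrow(w)))
  }
  if (any(w < 0)) abort("OMST extraction requires nonnegative weights")
  n <- nrow(w)
  total_weight <- sum(upper_weights(w))
  if (total_weight <= 0) abort("all-zero matrix")
  ge_full <- global_efficiency_w(w, distance)
  residual <- w
  union <- matrix(0, n, n, dimnames = dimnames(w))
  msts <- list()
  trace <- list()
  best_J <- -Inf
  best_m <- 0L
  repeat {
    tree <- tryCatch(kruskal_mst(residual, labels, distance),
                     error = function(e) NULL)
    if (is.null(tree)) break
    for (r in seq_len(nrow(tree))) {
      i <- tree$i_idx[r]; j <- tree$j_idx[r]
      union[i, j] <- union[j, i] <- w[i, j]
      residual[i, j] <- residual[j, i] <- 0
    }
    msts[[length(msts) + 1L]] <- tree
    m_now <- length(msts)
    cost <- sum(upper_weights(union)) / total_weight
    ge <- global_efficiency_w(union, distance) / ge_full
    J <- ge - cost
    trace[[m_now]] <- tibble(m = m_now, cost = cost, ge = ge, J = J)
    if (J > best_J) { best_J <- J; best_m <- m_now }
    if (m_now >= max_msts) break
    if (m_now - best_m >= patience) break
  }
  if (!length(msts)) abort("input graph is disconnected; cannot extract an MST")
  trace <- bind_rows(trace)
  selected_m <- trace$m[which.max(trace$J)]
  sel <- matrix(0, n, n, dimnames = dimnames(w))
  for (k in seq_len(selected_m)) {
    tr <- msts[[k]]
    for (r in seq_len(nrow(tr))) {
      i <- tr$i_idx[r]; j <- tr$j_idx[r]
      sel[i, j] <- sel[j, i] <- w[i, j]
    }
  }
  union_graph <- igraph::graph_from_adjacency_matrix(
    sel, mode = "undirected", weighted = TRUE, diag = FALSE)
  igraph::V(union_graph)$name <- labels
  structure(list(
    subject_id = if (inherits(m, "connectivity_matrix")) m$subject_id else NA,
    group = if (inherits(m, "connectivity_matrix")) m$group else NA,
    measure = if (inherits(m, "connectivity_matrix")) m$measure else NA,
    msts = msts, union_graph = union_graph, gce_trace = trace,
    selected_m = selected_m,
    density = igraph::ecount(union_graph) / (n * (n - 1) / 2),
    labels = labels
  ), class = "omst_result")
}

#' @export
print.omst_result <- function(x, ...) {
  cat(sprintf(
    "<omst_result> %s/%s: %d trees extracted, %d selected (J=%.4f), density %.3f\n",
    x$subject_id, x$measure, length(x$msts), x$selected_m,
    max(x$gce_trace$J), x$density))
  invisible(x)
}

#' Proportional-threshold graph of matched density
#'
#' Picks the grid quantile whose pre-pruning density is nearest to
#' `target_density` (for all-distinct weights, `q` is essentially
#' `1 - target_density`) and returns that thresholded graph. Used to
#' compare the data-driven OMST network with a conventionally thresholded
#' graph of the same density.
#'
#' @param m a `connectivity_matrix` or symmetric nonnegative matrix.
#' @param target_density desired pre-pruning density in `(0, 1)`.
#' @param q_grid candidate quantile levels (default [default_q_grid()]).
#' @return a `thresholded_graph` (see [quantile_threshold()]); the chosen
#'   level is its `q` field.
#' @export
match_density_threshold <- function(m, target_density,
                                    q_grid = default_q_grid()) {
  if (target_density <= 0 || target_density >= 1) {
    abort("target_density must lie in (0, 1)")
  }
  w <- if (inherits(m, "connectivity_matrix")) m$weights else as.matrix(m)
  uw <- upper_weights(w)
  E <- length(uw)
  dens <- vapply(q_grid, function(q) {
    thr <- unname(quantile(uw, q, type = 7))
    sum(uw >= thr) / E
  }, numeric(1))
  q_best <- q_grid[which.min(abs(dens - target_density))]
  quantile_threshold(m, q_best)
}
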