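#' Proportional quantile thresholding of a connectivity matrix
#'
#' The threshold is the `q`-quantile of the off-diagonal upper-triangle
#' weight distribution (the diagonal is structurally zero and excluded).
#' Edges with weight strictly below the threshold are eliminated (ties at
#' the threshold are kept). Nodes left without edges are removed and
#' recorded as isolated; if the surviving graph is disconnected only the
#' biggest component is retained (ties broken by the component containing
#' the lexicographically smallest node label).
#'
#' @param m a `connectivity_matrix` (nonnegative weights) or a plain
#'   symmetric matrix.
#' @param q quantile level in `(0, 1)`.
#' @param interpolation if `TRUE` (default) the quantile interpolates
#'   linearly between order statistics (`stats::quantile` type 7); if
#'   `FALSE` the nearest-order-statistic rule (type 3) is used.
#'
#' @return object of class `thresholded_graph`: `subject_id`, `group`,
#'   `measure`, `q`, `threshold`, `graph` (the retained [igraph] graph, edge
#'   attribute `weight`), `kept_edges` (tibble i, j, weight over retained
#'   edges), `retained_nodes`, `isolated_nodes`, `dropped_component_nodes`,
#'   `n_components_before_pruning`, `density` (retained edges over
#'   `N(N-1)/2` of the *original* N), `density_pre` (edges surviving the
#'   threshold before any node removal, same denominator), `n_nodes_original`.
#' @export
quantile_threshold <- function(m, q, interpolation = TRUE) {
  if (inherits(m, "connectivity_matrix")) {
    w <- m$weights; labels <- m$labels
    subject_id <- m$subject_id; group <- m$group; measure <- m$measure
  } else {
    w <- as.matrix(m)
    labels <- rownames(w) %||% sprintf("n%02d", seq_len(nrow(w)))
    subject_id <- NA_character_; group <- NA_character_
    measure <- NA_character_
  }
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  if (any(w < 0)) abort("thresholding requires nonnegative weights; rectify first")
  uw <- upper_weights(w)
  if (all(uw == 0)) abort("all-zero matrix: no weight distribution to threshold")
  thr <- unname(quantile(uw, q, type = if (interpolation) 7 else 3))
  n <- nrow(w)
  adj <- w
  adj[adj < thr] <- 0
  # weight-0 edges never exist; surviving = weight >= thr (> 0)
  g_full <- igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected", weighted = TRUE, diag = FALSE)
  igraph::V(g_full)$name <- labels
  pre_edges <- igraph::ecount(g_full)
  comp <- igraph::components(g_full)
  degs <- igraph::degree(g_full)
  isolated <- labels[degs == 0]
  g <- igraph::delete_vertices(g_full, which(degs == 0))
  dropped <- character()
  if (igraph::vcount(g) > 0) {
    comp2 <- igraph::components(g)
    if (comp2$no > 1) {
      sizes <- comp2$csize
      biggest <- which(sizes == max(sizes))
      if (length(biggest) > 1) {
        # tie: the component holding the lexicographically smallest label
        first_label <- vapply(biggest, function(ci) {
          min(igraph::V(g)$name[comp2$membership == ci])
        }, character(1))
        biggest <- biggest[order(first_label)[1]]
      }
      drop_idx <- which(comp2$membership != biggest)
      dropped <- igraph::V(g)$name[drop_idx]
      g <- igraph::delete_vertices(g, drop_idx)
    }
  }
  el <- igraph::as_data_frame(g, what = "edges")
  kept <- tibble(i = el$from, j = el$to, weight = el$weight)
  possible <- n * (n - 1) / 2
  structure(list(
    subject_id = subject_id, group = group, measure = measure,
    q = q, threshold = thr, graph = g, kept_edges = kept,
    retained_nodes = igraph::V(g)$name,
    isolated_nodes = isolated,
    dropped_component_nodes = dropped,
    n_components_before_pruning = comp$no,
    density = nrow(kept) / possible,
    density_pre = pre_edges / possible,
    n_nodes_original = n, node_labels = labels
  ), class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf(
    "<thresholded_graph> %s/%s q=%.2f: %d/%d nodes, %d edges (density %.3f), %d isolated\n",
    x$subject_id, x$measure, x$q, length(x$retained_nodes),
    x$n_nodes_original, nrow(x$kept_edges), x$density,
    length(x$isolated_nodes)))
  invisible(x)
}

#' Default proportional-threshold grid
#'
#' Quantile levels 0.01, 0.02, ..., 0.99.
#' @return numeric vector of length 99.
#' @export
default_q_grid <- function() seq(0.01, 0.99, by = 0.01)

#' Threshold sweep over a cohort of connectivity matrices
#'
#' Applies [quantile_threshold()] at every level of `q_grid` to every
#' matrix and (optionally) fills in the four global graph measures on each
#' pruned graph. Per-graph metric failures (e.g. a retained graph too small
#' for the small-world index) are recorded as `NA` and summarised in a
#' single warning rather than aborting the sweep.
#'
#' @param matrices list of `connectivity_matrix` objects.
#' @param q_grid quantile levels; default [default_q_grid()].
#' @param metrics character subset of
#'   `c("cpl", "clustering", "participation", "swi")`; `NULL` skips metric
#'   computation (bookkeeping columns only).
#' @param n_random_refs random references per small-world index.
#' @param master_seed integer; per-(subject, q) SWI seeds are derived from
#'   it, making the sweep reproducible.
#' @param keep_graphs if `TRUE`, the pruned graphs are attached as attribute
#'   `"graphs"` (a list indexed `[subject]][[as.character(q)]]`) for reuse by
#'   the edge-probability module.
#'
#' @return tibble with one row per (subject, measure, q): columns `subject`,
#'   `group`, `measure`, `q`, `threshold`, `density`, `density_pre`,
#'   `n_isolated`, `n_dropped`, `n_retained`, `n_components_before`, and one
#'   column per requested metric.
#' @export
run_sweep <- function(matrices, q_grid = default_q_grid(),
                      metrics = c("cpl", "clustering", "participation", "swi"),
                      n_random_refs = 20, master_seed = 42,
                      keep_graphs = FALSE) {
  if (!length(matrices)) abort("no connectivity matrices supplied")
  if (inherits(matrices, "connectivity_matrix")) matrices <- list(matrices)
  seeds <- derive_seeds(master_seed, length(matrices) * length(q_grid))
  rows <- list()
  graphs <- list()
  failures <- character()
  idx <- 0L
  for (m in matrices) {
    subj_graphs <- list()
    for (q in q_grid) {
      idx <- idx + 1L
      tg <- tryCatch(quantile_threshold(m, q), error = function(e) e)
      if (inherits(tg, "error")) {
        failures <- c(failures, sprintf("%s q=%.2f: %s", m$subject_id, q,
                                        conditionMessage(tg)))
        next
      }
      row <- tibble(
        subject = tg$subject_id, group = tg$group, measure = tg$measure,
        q = q, threshold = tg$threshold, density = tg$density,
        density_pre = tg$density_pre,
        n_isolated = length(tg$isolated_nodes),
        n_dropped = length(tg$dropped_component_nodes),
        n_retained = length(tg$retained_nodes),
        n_components_before = tg$n_components_before_pruning
      )
      if (!is.null(metrics)) {
        vals <- compute_graph_metrics(tg, metrics = metrics,
                                      n_random_refs = n_random_refs,
                                      seed = seeds[idx])
        for (nm in names(vals$values)) row[[nm]] <- vals$values[[nm]]
        failures <- c(failures, vals$failures)
      }
      rows[[length(rows) + 1L]] <- row
      if (keep_graphs) subj_graphs[[format(q)]] <- tg
    }
    if (keep_graphs) graphs[[m$subject_id]] <- subj_graphs
  }
  if (length(failures)) {
    warning(length(failures), " graph/metric evaluations skipped (NA); first: ",
            failures[1], call. = FALSE)
  }
  out <- bind_rows(rows)
  if (keep_graphs) attr(out, "graphs") <- graphs
  out
}

# Internal: compute the requested global metrics on one pruned graph,
# returning NA (with a note) where a metric's preconditions fail.
compute_graph_metrics <- function(tg, metrics, n_random_refs = 20,
                                  seed = NULL) {
  values <- list()
  failures <- character()
  note <- function(metric, e) {
    sprintf("%s q=%.2f %s: %s", tg$subject_id, tg$q, metric,
            conditionMessage(e))
  }
  for (metric in metrics) {
    values[[metric]] <- tryCatch(
      switch(metric,
        cpl = characteristic_path_length(tg),
        clustering = clustering_coefficient(tg),
        participation = participation_coefficient(tg),
        swi = small_world_index(tg, n_random_refs = n_random_refs,
                                seed = seed),
        abort("unknown metric: ", metric)
      ),
      error = function(e) {
        failures <<- c(failures, note(metric, e))
        NA_real_
      })
  }
  list(values = values, failures = failures)
}

#' Write a sweep table as long-format CSV
#'
#' @param sweep tibble from [run_sweep()].
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_sweep <- function(sweep, path) {
  write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}
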