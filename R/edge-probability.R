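#' Edge-probability graph across a cohort at one threshold
#'
#' For every node pair, the fraction of subjects whose pruned network at
#' this threshold contains the edge. Probabilities are evaluated on the
#' analyzed (post isolated-node / biggest-component pruning) graphs, so the
#' incident edges of a removed node count as absent. OMST union networks can
#' be supplied in place of thresholded graphs (pass `q = "omst"`).
#'
#' @param graphs list of `thresholded_graph` or `omst_result` objects sharing
#'   one original node-label set (one subject each).
#' @param measure,q labels stored on the result; inferred from the first
#'   graph when `NULL`.
#' @return object of class `edge_probability_graph`: `measure`, `q`, `prob`
#'   (symmetric N x N, entries k/n_subjects), `scaled_prob` (`NULL` until
#'   [scale_across_thresholds()]), `n_subjects`, `labels`.
#' @export
edge_probabilities <- function(graphs, measure = NULL, q = NULL) {
  if (!length(graphs)) abort("empty subject list")
  labels_of <- function(g) {
    if (inherits(g, "thresholded_graph")) g$node_labels else g$labels
  }
  labels <- labels_of(graphs[[1]])
  n <- length(labels)
  count <- matrix(0, n, n, dimnames = list(labels, labels))
  for (g in graphs) {
    if (!identical(labels_of(g), labels)) {
      abort("all graphs must share the original node label set")
    }
    gg <- if (inherits(g, "thresholded_graph")) g$graph else g$union_graph
    el <- igraph::as_data_frame(gg, what = "edges")
    for (r in seq_len(nrow(el))) {
      count[el$from[r], el$to[r]] <- count[el$from[r], el$to[r]] + 1
      count[el$to[r], el$from[r]] <- count[el$to[r], el$from[r]] + 1
    }
  }
  g1 <- graphs[[1]]
  structure(list(
    measure = measure %||% g1$measure,
    q = q %||% (if (inherits(g1, "omst_result")) "omst" else g1$q),
    prob = count / length(graphs), scaled_prob = NULL,
    n_subjects = length(graphs), labels = labels
  ), class = "edge_probability_graph")
}

#' Min-max scale edge probabilities across thresholds
#'
#' Rescales the probability matrices of one measure jointly to `[0, 1]`
#' using the global minimum and maximum over *all* supplied thresholds
#' (order-preserving within and across thresholds). If every probability is
#' identical the scaled values are all 0 by convention.
#'
#' @param eps list of `edge_probability_graph` objects for one measure.
#' @return the same list with `scaled_prob` filled.
#' @export
scale_across_thresholds <- function(eps) {
  if (!length(eps)) abort("need at least one threshold level")
  all_p <- unlist(lapply(eps, function(e) upper_weights(e$prob)))
  lo <- min(all_p); hi <- max(all_p)
  lapply(eps, function(e) {
    e$scaled_prob <- if (hi == lo) {
      matrix(0, nrow(e$prob), ncol(e$prob), dimnames = dimnames(e$prob))
    } else {
      (e$prob - lo) / (hi - lo)
    }
    e
  })
}

#' Per-edge monotonicity of probability across thresholds
#'
#' The rationale for pruning predicts a stable core: each edge's existence
#' probability should fall monotonically as the threshold rises. This
#' report flags, per edge, whether that holds -- non-monotone edges are the
#' instability signature of proportional thresholding.
#'
#' @param eps list of `edge_probability_graph` objects ordered by `q`.
#' @return tibble `i`, `j`, `monotone_nonincreasing`, `max_prob`, `min_prob`.
#' @export
edge_probability_monotonicity <- function(eps) {
  if (length(eps) < 2) abort("need >= 2 threshold levels")
  labels <- eps[[1]]$labels
  ut <- which(upper.tri(eps[[1]]$prob), arr.ind = TRUE)
  pmat <- vapply(eps, function(e) e$prob[upper.tri(e$prob)],
                 numeric(nrow(ut)))
  mono <- apply(pmat, 1, function(p) all(diff(p) <= 1e-12))
  tibble(i = labels[ut[, 1]], j = labels[ut[, 2]],
         monotone_nonincreasing = mono,
         max_prob = apply(pmat, 1, max), min_prob = apply(pmat, 1, min))
}

#' Long-format edge-probability table
#'
#' @param eps list of `edge_probability_graph` (scaled or not).
#' @return tibble `measure`, `q`, `i`, `j`, `prob`, `scaled_prob`.
#' @export
edge_probability_table <- function(eps) {
  bind_rows(lapply(eps, function(e) {
    ut <- which(upper.tri(e$prob), arr.ind = TRUE)
    tibble(
      measure = e$measure, q = as.character(e$q),
      i = e$labels[ut[, 1]], j = e$labels[ut[, 2]],
      prob = e$prob[ut],
      scaled_prob = if (is.null(e$scaled_prob)) NA_real_ else e$scaled_prob[ut]
    )
  }))
}

#' @export
print.edge_probability_graph <- function(x, ...) {
  cat(sprintf(
    "<edge_probability_graph> %s q=%s: %d nodes, %d subjects, SD(prob)=%.3f\n",
    x$measure, format(x$q), length(x$labels), x$n_subjects,
    sd(upper_weights(x$prob))))
  invisible(x)
}
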