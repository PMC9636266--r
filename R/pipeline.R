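#' Write / read a connectivity matrix as delimited text
#'
#' Square comma-separated matrix with a header row of node labels; the
#' conventional file name is `<subject>_<measure>.csv`.
#'
#' @param m a `connectivity_matrix`.
#' @param path output file path.
#' @return `write_connectivity_matrix` returns `path` invisibly;
#'   `read_connectivity_matrix` returns a `connectivity_matrix`.
#' @export
write_connectivity_matrix <- function(m, path) {
  stopifnot(inherits(m, "connectivity_matrix"))
  df <- as.data.frame(m$weights)
  names(df) <- m$labels
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_matrix
#' @param subject_id,measure metadata; defaults parsed from a
#'   `<subject>_<measure>.csv` file name.
#' @param tol symmetry tolerance (matrices asymmetric beyond it are rejected).
#' @export
read_connectivity_matrix <- function(path, subject_id = NULL, measure = NULL,
                                     tol = 1e-9) {
  df <- read.csv(path, check.names = FALSE)
  w <- as.matrix(df)
  if (nrow(w) != ncol(w)) {
    abort(basename(path), ": matrix is not square (", nrow(w), " x ",
          ncol(w), ")")
  }
  if (!is.numeric(w)) abort(basename(path), ": non-numeric entries")
  if (any(!is.finite(w))) {
    bad <- which(!is.finite(w), arr.ind = TRUE)[1, ]
    abort(basename(path), ": non-finite value at row ", bad[1], ", column ",
          bad[2])
  }
  if (max(abs(w - t(w))) > tol) {
    abort(basename(path), ": asymmetric beyond tolerance ", tol)
  }
  base <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(base, "_")[[1]]
  if (is.null(subject_id)) {
    subject_id <- if (length(parts) >= 2)
      paste(head(parts, -1), collapse = "_") else base
  }
  if (is.null(measure)) {
    measure <- if (length(parts) >= 2) tail(parts, 1) else NA_character_
  }
  connectivity_matrix(w, labels = colnames(df), subject_id = subject_id,
                      measure = measure, tol = tol)
}

#' Read a directory of connectivity matrices
#'
#' Loads every `*.csv` in `path` via [read_connectivity_matrix()]. With
#' `strict = TRUE` (default) any invalid file aborts the read; with
#' `strict = FALSE` invalid files are skipped with one warning each.
#'
#' @param path directory of square delimited matrices with label headers.
#' @param strict abort on the first invalid file?
#' @param tol symmetry tolerance.
#' @return list of `connectivity_matrix` objects.
#' @export
read_connectivity_dir <- function(path, strict = TRUE, tol = 1e-9) {
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  if (!length(files)) abort("no .csv matrices found in ", path)
  out <- list()
  for (f in files) {
    m <- tryCatch(read_connectivity_matrix(f, tol = tol),
                  error = function(e) e)
    if (inherits(m, "error")) {
      if (strict) stop(m)
      warning("skipping ", basename(f), ": ", conditionMessage(m),
              call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end analysis needs. Either
#' a synthetic cohort (`cohort` + `oscillator`) or a directory of
#' precomputed connectivity matrices (`input_dir`) serves as input.
#'
#' @param output_dir directory for all artifacts (created if needed).
#' @param cohort,oscillator a [cohort_spec()] and [oscillator_spec()] for
#'   synthetic input, or `NULL` when `input_dir` is given.
#' @param input_dir directory of `<subject>_<measure>.csv` matrices.
#' @param measures synchronization measures to estimate.
#' @param band frequency band (Hz).
#' @param epoch_length epoch length in samples (`NULL`: per-recording
#'   default).
#' @param q_grid threshold levels.
#' @param rectify rectification mode for signed measures.
#' @param metrics graph metrics to compute along the sweep.
#' @param n_random_refs random references per small-world index.
#' @param n_permutations Monte-Carlo permutations for the statistical layer.
#' @param edge_prob_q threshold levels at which edge-probability matrices
#'   are written (default: deciles of the grid).
#' @param seed master seed for the full run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            cohort = NULL, oscillator = NULL,
                            input_dir = NULL,
                            measures = c("wpli", "imcoh", "coherence",
                                         "ciplv", "ppc"),
                            band = c(8, 13), epoch_length = NULL,
                            q_grid = default_q_grid(),
                            rectify = "default",
                            metrics = c("cpl", "clustering",
                                        "participation", "swi"),
                            n_random_refs = 20, n_permutations = 2000,
                            edge_prob_q = NULL, seed = 42) {
  synth <- !is.null(cohort)
  if (synth) {
    stopifnot(inherits(cohort, "cohort_spec"),
              inherits(oscillator, "oscillator_spec"))
  } else if (is.null(input_dir)) {
    abort("either a synthetic cohort spec or input_dir must be given")
  }
  measures <- match.arg(measures, names(measure_registry), several.ok = TRUE)
  if (any(q_grid <= 0 | q_grid >= 1)) abort("q_grid levels must lie in (0,1)")
  structure(list(
    output_dir = output_dir, cohort = cohort, oscillator = oscillator,
    input_dir = input_dir, measures = measures, band = band,
    epoch_length = epoch_length, q_grid = q_grid, rectify = rectify,
    metrics = metrics, n_random_refs = n_random_refs,
    n_permutations = n_permutations,
    edge_prob_q = edge_prob_q %||% (if (length(q_grid) >= 10)
      q_grid[seq(10, length(q_grid), by = 10)] else q_grid),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

# Internal: run one stage, aborting with the stage name (and subject if the
# underlying error already names one).
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full threshold-sensitivity pipeline
#'
#' Connectivity estimation (or loading), proportional threshold sweep with
#' graph metrics, edge-probability graphs, OMST extraction with
#' matched-density comparison, and the statistical layer; everything is
#' written under `cfg$output_dir` together with the resolved configuration,
#' the package version and the master seed (`manifest.yaml`). Identical
#' config and seed reproduce byte-identical CSV outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the in-memory results: `matrices`, `sweep`,
#'   `edge_probability`, `omst`, `omst_comparison`, `regression`,
#'   `group_profiles`, `descriptives`, `output_dir`.
#' @export
run_full_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[connsweep] ", ...)
  t0 <- Sys.time()

  # --- stage: input ---------------------------------------------------------
  matrices <- run_stage("connectivity", {
    if (!is.null(cfg$cohort)) {
      say("generating synthetic cohort")
      cohort <- cfg$cohort
      cohort$seed <- cohort$seed %||% cfg$seed
      recs <- generate_cohort(cohort, cfg$oscillator)
      mats <- list()
      for (r in recs) {
        cs <- compute_cross_spectra(r, band = cfg$band,
                                    epoch_length = cfg$epoch_length)
        for (ms in cfg$measures) {
          mats[[length(mats) + 1L]] <-
            band_connectivity(cs, ms, rectify = cfg$rectify)
        }
      }
      mats
    } else {
      say("reading connectivity matrices from ", cfg$input_dir)
      read_connectivity_dir(cfg$input_dir)
    }
  })
  conn_dir <- file.path(cfg$output_dir, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  for (m in matrices) {
    write_connectivity_matrix(
      m, file.path(conn_dir, paste0(m$subject_id, "_", m$measure, ".csv")))
  }

  # --- stage: descriptives --------------------------------------------------
  descriptives <- run_stage("descriptives",
    bind_rows(lapply(matrices, connectivity_descriptives)))
  write.csv(descriptives, file.path(cfg$output_dir, "descriptives.csv"),
            row.names = FALSE)

  # --- stage: threshold sweep ----------------------------------------------
  say("threshold sweep over ", length(cfg$q_grid), " levels x ",
      length(matrices), " matrices")
  sweep <- run_stage("sweep",
    run_sweep(matrices, q_grid = cfg$q_grid, metrics = cfg$metrics,
              n_random_refs = cfg$n_random_refs, master_seed = cfg$seed,
              keep_graphs = TRUE))
  write_sweep(sweep, file.path(cfg$output_dir, "sweep.csv"))
  graphs <- attr(sweep, "graphs")

  # --- stage: edge probability ---------------------------------------------
  say("edge-probability graphs")
  edge_prob <- run_stage("edgeprob", {
    by_measure <- split(matrices, vapply(matrices, `[[`, "", "measure"))
    out <- list()
    for (ms in names(by_measure)) {
      subj <- vapply(by_measure[[ms]], `[[`, "", "subject_id")
      eps <- lapply(cfg$q_grid, function(q) {
        edge_probabilities(lapply(subj, function(s) graphs[[s]][[format(q)]]),
                           measure = ms, q = q)
      })
      out[[ms]] <- scale_across_thresholds(eps)
    }
    out
  })
  ep_rows <- bind_rows(lapply(edge_prob, function(eps) {
    keep <- vapply(eps, function(e) e$q %in% cfg$edge_prob_q, logical(1))
    edge_probability_table(eps[keep])
  }))
  write.csv(ep_rows, file.path(cfg$output_dir, "edge_probability.csv"),
            row.names = FALSE)

  # --- stage: OMST ----------------------------------------------------------
  say("OMST extraction and matched-density comparison")
  omst_out <- run_stage("omst", {
    res <- list()
    for (m in matrices) {
      key <- paste0(m$subject_id, "_", m$measure)
      res[[key]] <- tryCatch(extract_orthogonal_msts(m), error = function(e) {
        abort("subject ", m$subject_id, " (", m$measure, "): ",
              conditionMessage(e))
      })
    }
    res
  })
  omst_rows <- list()
  thr_rows <- list()
  seeds <- derive_seeds(cfg$seed + 1L, 2L * length(omst_out))
  kk <- 0L
  for (key in names(omst_out)) {
    o <- omst_out[[key]]
    m <- matrices[[which(vapply(matrices, function(x)
      paste0(x$subject_id, "_", x$measure), "") == key)]]
    tg <- match_density_threshold(m, o$density, q_grid = cfg$q_grid)
    kk <- kk + 1L
    ov <- compute_graph_metrics(
      structure(list(graph = o$union_graph, subject_id = o$subject_id,
                     q = NA_real_), class = "thresholded_graph"),
      metrics = cfg$metrics, n_random_refs = cfg$n_random_refs,
      seed = seeds[2 * kk - 1])$values
    tv <- compute_graph_metrics(tg, metrics = cfg$metrics,
                                n_random_refs = cfg$n_random_refs,
                                seed = seeds[2 * kk])$values
    omst_rows[[key]] <- tibble(subject = o$subject_id, measure = o$measure,
                               density = o$density, selected_m = o$selected_m,
                               !!!ov)
    thr_rows[[key]] <- tibble(subject = tg$subject_id, measure = tg$measure,
                              density = tg$density, q = tg$q, !!!tv)
    trace_path <- file.path(cfg$output_dir, "omst")
    dir.create(trace_path, showWarnings = FALSE)
    jsonlite::write_json(o$gce_trace,
                         file.path(trace_path, paste0(key, "_trace.json")),
                         digits = NA)
    write.csv(bind_rows(o$msts[seq_len(o$selected_m)]),
              file.path(trace_path, paste0(key, "_edges.csv")),
              row.names = FALSE)
  }
  omst_metrics <- bind_rows(omst_rows)
  thr_metrics <- bind_rows(thr_rows)
  write.csv(omst_metrics, file.path(cfg$output_dir, "omst_metrics.csv"),
            row.names = FALSE)
  write.csv(thr_metrics, file.path(cfg$output_dir, "matched_metrics.csv"),
            row.names = FALSE)
  omst_cmp <- run_stage("omst_comparison",
    compare_omst_vs_matched(omst_metrics, thr_metrics, metrics = cfg$metrics,
                            n_permutations = cfg$n_permutations,
                            seed = cfg$seed + 2L))
  write.csv(omst_cmp, file.path(cfg$output_dir, "omst_comparison.csv"),
            row.names = FALSE)

  # --- stage: statistics ----------------------------------------------------
  say("statistical layer")
  regression <- run_stage("regression",
    density_regression_table(sweep, metrics = cfg$metrics))
  write.csv(regression, file.path(cfg$output_dir, "density_regression.csv"),
            row.names = FALSE)
  group_profiles <- NULL
  if (length(unique(sweep$group[!is.na(sweep$group)])) == 2) {
    group_profiles <- run_stage("group_comparison", {
      gp <- list()
      for (ms in unique(sweep$measure)) {
        for (mt in intersect(cfg$metrics, names(sweep))) {
          prof <- group_effect_profile(sweep, mt, measure = ms,
                                       n_permutations = cfg$n_permutations,
                                       seed = cfg$seed + 3L)
          prof$measure <- ms; prof$metric <- mt
          gp[[paste(ms, mt)]] <- prof
        }
      }
      bind_rows(gp)
    })
    write.csv(group_profiles,
              file.path(cfg$output_dir, "group_profiles.csv"),
              row.names = FALSE)
  }

  # --- provenance -----------------------------------------------------------
  manifest <- list(
    package = "connsweep",
    version = as.character(packageVersion("connsweep")),
    seed = cfg$seed,
    measures = cfg$measures, band = cfg$band,
    q_grid = range(cfg$q_grid), n_q = length(cfg$q_grid),
    rectify = cfg$rectify, metrics = cfg$metrics,
    n_random_refs = cfg$n_random_refs,
    n_permutations = cfg$n_permutations,
    input = if (is.null(cfg$input_dir)) "synthetic" else cfg$input_dir,
    n_matrices = length(matrices)
  )
  yaml::write_yaml(manifest, file.path(cfg$output_dir, "manifest.yaml"))
  writeLines(sprintf("completed in %.1f s",
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))),
             file.path(cfg$output_dir, "run.log"))
  say("done")
  invisible(list(matrices = matrices, sweep = sweep,
                 edge_probability = edge_prob, omst = omst_out,
                 omst_metrics = omst_metrics, matched_metrics = thr_metrics,
                 omst_comparison = omst_cmp, regression = regression,
                 group_profiles = group_profiles,
                 descriptives = descriptives, output_dir = cfg$output_dir))
}
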