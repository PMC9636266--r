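#' Descriptive statistics of a connectivity weight distribution
#'
#' Median, mean, median absolute deviation (unscaled, i.e. the raw median of
#' absolute deviations from the median) and SD of the off-diagonal
#' upper-triangle weights -- the per-subject distribution summaries whose
#' cohort spread indicates how much individual synchronization strength
#' varies (and hence how differently a common proportional threshold bites).
#'
#' @param m a `connectivity_matrix` or symmetric matrix.
#' @return tibble row: `subject`, `measure`, `median`, `mean`, `mad`, `sd`.
#' @export
connectivity_descriptives <- function(m) {
  if (inherits(m, "connectivity_matrix")) {
    w <- upper_weights(m$weights)
    subject <- m$subject_id; measure <- m$measure
  } else {
    w <- upper_weights(as.matrix(m))
    subject <- NA_character_; measure <- NA_character_
  }
  if (!length(w)) abort("no off-diagonal weights")
  tibble(subject = subject, measure = measure,
         median = median(w), mean = mean(w),
         mad = mad(w, constant = 1), sd = sd(w))
}

#' Ordinary least squares of a graph metric on density
#'
#' Pools all (density, metric) observations across subjects and thresholds
#' and fits `metric ~ density`. The slope's sign and the adjusted R-squared
#' summarize how strongly and in which direction the thresholding level
#' drives the metric.
#'
#' @param records sweep tibble (from [run_sweep()]) or any data frame with a
#'   `density` column and the metric column.
#' @param metric name of the metric column (e.g. `"cpl"`).
#' @param measure optional filter on the `measure` column.
#' @return object of class `regression_fit`: `intercept`, `slope`,
#'   `adj_r_squared`, `p_values` (named, intercept and density), `n`,
#'   `metric`, `measure`.
#' @export
fit_density_regression <- function(records, metric, measure = NULL) {
  df <- as.data.frame(records)
  if (!is.null(measure)) df <- df[df$measure == measure, , drop = FALSE]
  if (!metric %in% names(df)) abort("no column named '", metric, "'")
  df <- df[is.finite(df$density) & is.finite(df[[metric]]), , drop = FALSE]
  if (nrow(df) < 3) abort("need >= 3 (density, value) pairs")
  if (var(df$density) == 0) abort("zero variance in density")
  fit <- lm(df[[metric]] ~ df$density)
  sm <- summary(fit)
  structure(list(
    intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
    adj_r_squared = sm$adj.r.squared,
    p_values = setNames(sm$coefficients[, 4],
                        c("intercept", "density")),
    n = nrow(df), metric = metric, measure = measure
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit> %s ~ density%s: intercept %.3f, slope %.3f, adj R^2 %.3f (n=%d)\n",
    x$metric, if (is.null(x$measure)) "" else paste0(" [", x$measure, "]"),
    x$intercept, x$slope, x$adj_r_squared, x$n))
  invisible(x)
}

#' Table of density regressions mirroring a measure-by-metric layout
#'
#' One [fit_density_regression()] per (measure, metric) present in the
#' sweep, in a long table with columns named after the conventional report
#' layout.
#'
#' @param sweep tibble from [run_sweep()].
#' @param metrics metric columns to fit.
#' @return tibble: `measure`, `metric`, `Intercept`,
#'   `Density value (Coef)`, `Adj.R.squared`, `p_intercept`, `p_density`, `n`.
#' @export
density_regression_table <- function(sweep,
                                     metrics = c("cpl", "clustering",
                                                 "participation", "swi")) {
  rows <- list()
  for (ms in unique(sweep$measure)) {
    for (mt in intersect(metrics, names(sweep))) {
      fit <- tryCatch(fit_density_regression(sweep, mt, measure = ms),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- tibble(
        measure = ms, metric = mt,
        Intercept = fit$intercept,
        `Density value (Coef)` = fit$slope,
        Adj.R.squared = fit$adj_r_squared,
        p_intercept = fit$p_values[["intercept"]],
        p_density = fit$p_values[["density"]],
        n = fit$n)
    }
  }
  bind_rows(rows)
}

#' Cross-threshold Spearman correlation structure
#'
#' Subject-wise Spearman rank correlation between the metric vectors at
#' every pair of thresholds. A strongly positive block structure indicates
#' that the metric orders subjects consistently across thresholds; loss of
#' correlation at high thresholds is the instability signature.
#'
#' @param records sweep tibble from [run_sweep()].
#' @param metric metric column name.
#' @param measure optional filter on the `measure` column.
#' @param min_subjects minimum complete subject pairs per threshold pair.
#' @return list with `rho` and `p` (symmetric q x q matrices, unit/zero
#'   diagonal, `NA` where undefined) and `q` (the levels).
#' @export
cross_threshold_correlations <- function(records, metric, measure = NULL,
                                         min_subjects = 4) {
  df <- as.data.frame(records)
  if (!is.null(measure)) df <- df[df$measure == measure, , drop = FALSE]
  wide <- pivot_wider(df[, c("subject", "q", metric)],
                      names_from = "q",
                      values_from = dplyr::all_of(metric))
  qs <- sort(as.numeric(setdiff(names(wide), "subject")))
  k <- length(qs)
  rho <- matrix(NA_real_, k, k, dimnames = list(format(qs), format(qs)))
  pval <- rho
  mat <- as.matrix(wide[, format(qs)])
  for (a in seq_len(k)) {
    rho[a, a] <- 1; pval[a, a] <- 0
    for (b in seq_len(k)) {
      if (b <= a) next
      x <- mat[, a]; y <- mat[, b]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_subjects) next
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) next  # rho undefined -> NA
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      rho[a, b] <- rho[b, a] <- unname(ct$estimate)
      pval[a, b] <- pval[b, a] <- ct$p.value
    }
  }
  list(rho = rho, p = pval, q = qs)
}

# Internal: Welch t statistic; 0 when both variances are 0 and means equal,
# signed Inf when variances are 0 and means differ.
welch_t <- function(a, b) {
  va <- var(a); vb <- var(b)
  se2 <- va / length(a) + vb / length(b)
  dm <- mean(a) - mean(b)
  if (se2 == 0) return(if (dm == 0) 0 else sign(dm) * Inf)
  dm / sqrt(se2)
}

# Internal: pooled-SD Cohen's d.
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  dm <- mean(a) - mean(b)
  if (sp2 == 0) return(if (dm == 0) 0 else sign(dm) * Inf)
  dm / sqrt(sp2)
}

#' Permutation t-test with Cohen's d
#'
#' Two-sample: the observed Welch t is compared with its distribution under
#' random relabelling. When the number of distinct splits is at most 20000
#' every split is enumerated (exact p); otherwise `n_permutations`
#' Monte-Carlo draws are used with the add-one correction
#' `p = (1 + #{|t*| >= |t|}) / (n_permutations + 1)`. Paired: sign-flip
#' permutation of the within-pair differences of a paired t statistic
#' (exact when `2^n <= 20000`). Cohen's d always uses the pooled SD of the
#' two samples.
#'
#' @param a,b numeric samples (equal length when `paired = TRUE`).
#' @param n_permutations Monte-Carlo permutations (default 10000).
#' @param seed integer seed for the Monte-Carlo draw.
#' @param paired sign-flip paired test instead of two-sample relabelling.
#' @param exact_max enumeration cutoff on the number of distinct splits.
#' @return object of class `comparison_result`: `t_stat`, `p_value`,
#'   `cohens_d`, `n_permutations` (actual; `NA` when exact), `exact`, `seed`.
#' @export
permutation_ttest <- function(a, b, n_permutations = 10000, seed = NULL,
                              paired = FALSE, exact_max = 20000) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) abort("each sample needs >= 2 values")
  eps <- 1e-12
  if (paired) {
    if (length(a) != length(b)) abort("paired samples must have equal length")
    d <- a - b
    n <- length(d)
    tstat <- function(dd) {
      sdd <- sd(dd)
      if (sdd == 0) return(if (mean(dd) == 0) 0 else sign(mean(dd)) * Inf)
      mean(dd) / (sdd / sqrt(n))
    }
    t_obs <- tstat(d)
    if (2^n <= exact_max) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      ts <- apply(signs, 1, function(s) tstat(d * s))
      p <- mean(abs(ts) >= abs(t_obs) - eps)
      exact <- TRUE; nperm <- NA_integer_
    } else {
      run <- function() {
        ts <- replicate(n_permutations,
                        tstat(d * sample(c(-1, 1), n, replace = TRUE)))
        (1 + sum(abs(ts) >= abs(t_obs) - eps)) / (n_permutations + 1)
      }
      p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
      exact <- FALSE; nperm <- as.integer(n_permutations)
    }
  } else {
    t_obs <- welch_t(a, b)
    z <- c(a, b); na <- length(a); ntot <- length(z)
    n_splits <- choose(ntot, na)
    if (n_splits <= exact_max) {
      splits <- combn(ntot, na)
      ts <- apply(splits, 2, function(ix) welch_t(z[ix], z[-ix]))
      p <- mean(abs(ts) >= abs(t_obs) - eps)
      exact <- TRUE; nperm <- NA_integer_
    } else {
      run <- function() {
        ts <- replicate(n_permutations, {
          ix <- sample.int(ntot, na)
          welch_t(z[ix], z[-ix])
        })
        (1 + sum(abs(ts) >= abs(t_obs) - eps)) / (n_permutations + 1)
      }
      p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
      exact <- FALSE; nperm <- as.integer(n_permutations)
    }
  }
  structure(list(t_stat = t_obs, p_value = p, cohens_d = cohens_d(a, b),
                 n_permutations = nperm, exact = exact, seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> t=%.3f, p=%.4g (%s), Cohen's d=%.3f\n",
              x$t_stat, x$p_value,
              if (x$exact) "exact" else paste0(x$n_permutations, " perms"),
              x$cohens_d))
  invisible(x)
}

#' Group comparison profile across thresholds
#'
#' Runs a two-sample permutation t-test with Cohen's d at every threshold
#' level of a sweep and flags the contiguous runs of significant levels and
#' any sign change of d between significant runs -- the configuration in
#' which the threshold choice flips a study's conclusion.
#'
#' @param sweep tibble from [run_sweep()] with a `group` column (two groups).
#' @param metric metric column name.
#' @param measure optional filter on the `measure` column.
#' @param alpha two-sided significance level (default 0.05).
#' @param n_permutations,seed passed to [permutation_ttest()] (per-q seeds
#'   are derived from `seed`).
#' @return tibble `q`, `t_stat`, `p_value`, `cohens_d`, `significant`;
#'   attributes `"significant_runs"` (tibble of q intervals) and
#'   `"d_sign_change"` (logical: significant runs with opposite d signs).
#' @export
group_effect_profile <- function(sweep, metric, measure = NULL, alpha = 0.05,
                                 n_permutations = 2000, seed = 1) {
  df <- as.data.frame(sweep)
  if (!is.null(measure)) df <- df[df$measure == measure, , drop = FALSE]
  groups <- sort(unique(df$group))
  if (length(groups) != 2) abort("sweep must contain exactly two groups")
  qs <- sort(unique(df$q))
  seeds <- derive_seeds(seed, length(qs))
  rows <- list()
  for (k in seq_along(qs)) {
    sub <- df[df$q == qs[k], , drop = FALSE]
    a <- sub[[metric]][sub$group == groups[1]]
    b <- sub[[metric]][sub$group == groups[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) {
      warning("q = ", qs[k], " skipped: fewer than 2 finite values per group",
              call. = FALSE)
      next
    }
    res <- permutation_ttest(a, b, n_permutations = n_permutations,
                             seed = seeds[k])
    rows[[length(rows) + 1L]] <- tibble(
      q = qs[k], t_stat = res$t_stat, p_value = res$p_value,
      cohens_d = res$cohens_d, significant = res$p_value < alpha)
  }
  out <- bind_rows(rows)
  r <- rle(out$significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sig_runs <- tibble(q_start = out$q[starts[r$values]],
                     q_end = out$q[ends[r$values]],
                     length = r$lengths[r$values])
  run_signs <- mapply(function(s, e) {
    sign(mean(out$cohens_d[out$q >= s & out$q <= e]))
  }, sig_runs$q_start, sig_runs$q_end)
  attr(out, "significant_runs") <- sig_runs
  attr(out, "d_sign_change") <- length(unique(run_signs[run_signs != 0])) > 1
  out
}

#' Paired comparison of OMST and matched-density thresholded metrics
#'
#' Per (measure, metric): paired sign-flip permutation t-test and pooled-SD
#' Cohen's d between each subject's OMST-network metric and the same
#' subject's metric from the proportional-threshold graph of matched
#' density.
#'
#' @param omst_metrics,thresh_metrics data frames with columns `subject`,
#'   `measure`, and one column per metric; same subjects in both.
#' @param metrics metric columns to compare.
#' @param n_permutations,seed passed to [permutation_ttest()].
#' @return tibble: `measure`, `metric`, `t_stat`, `p_value`, `cohens_d`, `n`.
#' @export
compare_omst_vs_matched <- function(omst_metrics, thresh_metrics,
                                    metrics = c("cpl", "clustering",
                                                "participation", "swi"),
                                    n_permutations = 10000, seed = 1) {
  om <- as.data.frame(omst_metrics)
  th <- as.data.frame(thresh_metrics)
  miss_a <- setdiff(th$subject, om$subject)
  miss_b <- setdiff(om$subject, th$subject)
  if (length(miss_a) || length(miss_b)) {
    abort("unmatched subjects; missing from OMST set: ",
          paste(miss_a, collapse = ", "), "; missing from thresholded set: ",
          paste(miss_b, collapse = ", "))
  }
  rows <- list()
  seeds <- derive_seeds(seed, length(unique(om$measure)) * length(metrics))
  k <- 0L
  for (ms in unique(om$measure)) {
    for (mt in intersect(metrics, intersect(names(om), names(th)))) {
      k <- k + 1L
      oa <- om[om$measure == ms, c("subject", mt)]
      tb <- th[th$measure == ms, c("subject", mt)]
      merged <- merge(oa, tb, by = "subject", suffixes = c("_omst", "_thr"))
      a <- merged[[paste0(mt, "_omst")]]
      b <- merged[[paste0(mt, "_thr")]]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 2) next
      res <- permutation_ttest(a[ok], b[ok], paired = TRUE,
                               n_permutations = n_permutations,
                               seed = seeds[k])
      rows[[length(rows) + 1L]] <- tibble(
        measure = ms, metric = mt, t_stat = res$t_stat,
        p_value = res$p_value, cohens_d = res$cohens_d, n = sum(ok))
    }
  }
  bind_rows(rows)
}
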