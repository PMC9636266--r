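# Independent reference implementations used to cross-check the package.
# These deliberately avoid the code paths (and igraph routines) used by the
# implementation: BFS by hand, exhaustive enumeration, direct summation.

# --- graph oracles ----------------------------------------------------------

# All-pairs shortest-path hop counts by breadth-first search on an adjacency
# matrix (0/1 or weighted; any nonzero entry is an edge).
oracle_bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    visited <- rep(FALSE, n); visited[s] <- TRUE
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] != 0 & !visited)
        visited[nb] <- TRUE
        d[s, nb] <- depth
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  d
}

# Per-node binary clustering by exhaustive triple counting.
oracle_clustering <- function(adj) {
  adj <- (adj != 0) * 1
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      links <- links + adj[nb[a], nb[b]]
    }
    links / (k * (k - 1) / 2)
  }, numeric(1))
}

# Participation coefficient by direct summation.
oracle_participation <- function(adj, membership) {
  adj <- (adj != 0) * 1
  n <- nrow(adj)
  p <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(adj[i, ])
    if (k == 0) next
    acc <- 0
    for (m in unique(membership)) {
      kim <- sum(adj[i, membership == m])
      acc <- acc + (kim / k)^2
    }
    p[i] <- 1 - acc
  }
  p
}

# All spanning trees of a small graph by enumerating edge subsets of size
# n-1 and checking acyclicity/connectivity via BFS.
oracle_spanning_trees <- function(w) {
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  trees <- list()
  for (sel in utils::combn(nrow(idx), n - 1, simplify = FALSE)) {
    adj <- matrix(0, n, n)
    for (r in sel) {
      adj[idx[r, 1], idx[r, 2]] <- adj[idx[r, 2], idx[r, 1]] <- w[idx[r, 1], idx[r, 2]]
    }
    if (all(is.finite(oracle_bfs_distances(adj)))) {
      trees[[length(trees) + 1L]] <- list(edges = idx[sel, , drop = FALSE],
                                          weight = sum(adj[upper.tri(adj)]))
    }
  }
  trees
}

# --- statistics oracles -----------------------------------------------------

# Spearman rho via midranks then the Pearson product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# OLS via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Exact two-sample permutation p for the Welch t, by enumerating every
# assignment of the pooled values to group A (recursive, independent of
# utils::combn used in the implementation).
oracle_perm_p <- function(a, b) {
  z <- c(a, b); na <- length(a); n <- length(z)
  tw <- function(xa, xb) {
    se2 <- var(xa) / length(xa) + var(xb) / length(xb)
    if (se2 == 0) return(if (mean(xa) == mean(xb)) 0 else Inf)
    (mean(xa) - mean(xb)) / sqrt(se2)
  }
  t_obs <- abs(tw(a, b))
  count <- 0L; total <- 0L
  rec <- function(start, chosen) {
    if (length(chosen) == na) {
      total <<- total + 1L
      if (abs(tw(z[chosen], z[-chosen])) >= t_obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    if (start > n) return(invisible())
    for (k in start:n) rec(k + 1, c(chosen, k))
    invisible()
  }
  rec(1, integer())
  count / total
}

# Plain rectangular-window periodogram band power, independent of the
# Hann-windowed path (used with an explicitly rectangular comparison).
oracle_periodogram_band <- function(x, sfreq, band) {
  L <- length(x)
  f <- (0:(L - 1)) * sfreq / L
  X <- fft(x - mean(x))
  keep <- f >= band[1] & f <= band[2] & f <= sfreq / 2
  mean(Mod(X[keep])^2)
}

# Instantaneous phase via the analytic signal (FFT positive-frequency
# doubling), for checking planted phase lags.
oracle_instantaneous_phase <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Arg(fft(X * h, inverse = TRUE) / n)
}

# Circular correlation (Fisher-Lee) of two phase vectors.
oracle_circular_correlation <- function(a, b) {
  num <- sum(sin(a - mean_angle(a)) * sin(b - mean_angle(b)))
  den <- sqrt(sum(sin(a - mean_angle(a))^2) * sum(sin(b - mean_angle(b))^2))
  num / den
}
mean_angle <- function(a) Arg(mean(exp(1i * a)))

# --- synthetic helpers ------------------------------------------------------

# Build a cross_spectra object directly from a matrix of per-epoch phases
# (epochs x channels), unit amplitudes, one frequency bin. Lets tests hit
# the measure formulas with exactly known phase differences.
fake_cross_spectra <- function(phases, amplitudes = NULL) {
  ne <- nrow(phases); nc <- ncol(phases)
  if (is.null(amplitudes)) amplitudes <- matrix(1, ne, nc)
  coef <- array(complex(real = 0), c(ne, 1, nc))
  coef[, 1, ] <- amplitudes * exp(1i * phases)
  structure(list(coef = coef, freqs = 10, n_epochs = ne,
                 labels = sprintf("ch%02d", seq_len(nc)),
                 band = c(8, 13), sfreq = 256,
                 subject_id = "fake", group = NA_character_),
            class = "cross_spectra")
}

# Symmetric matrix with all-distinct weights, as a connectivity_matrix.
random_distinct_matrix <- function(n, seed = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2)
    w <- w + t(w)
  })
  connectivity_matrix(w, subject_id = "synthetic", measure = "wpli")
}

# Small cohort of wPLI matrices from the canonical chain layout, cached per
# session (used by several sweep-level tests).
cohort_cache <- new.env(parent = emptyenv())
cached_chain_cohort <- function(n_channels = 16, n_per_group = 5,
                                duration = 40, delta = 0, seed = 7,
                                strength = 0.8) {
  key <- paste(n_channels, n_per_group, duration, delta, seed, strength,
               sep = "_")
  if (!is.null(cohort_cache[[key]])) return(cohort_cache[[key]])
  base <- oscillator_spec(n_channels, 256, duration, c(8, 13),
                          chain_topology(n_channels, strength = strength),
                          noise_sd = 0.5)
  eff <- if (delta != 0) list(parameter = "coupling_strength", delta = delta)
  co <- cohort_spec(n_per_group, group_effect = eff,
                    subject_variability_sd = 0.05, seed = seed)
  recs <- generate_cohort(co, base)
  mats <- lapply(recs, band_connectivity, measure = "wpli")
  cohort_cache[[key]] <- mats
  mats
}
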