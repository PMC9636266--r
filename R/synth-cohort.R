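#' Specify a synthetic multichannel oscillator recording
#'
#' Describes a band-limited multichannel oscillation with optional fixed
#' phase-lag coupling between designated channel pairs, emulating an
#' eyes-closed resting-state recording in a narrow frequency band. Each
#' channel carries a phase trajectory whose instantaneous frequency wanders
#' inside `carrier_band`; for a coupled pair `(i, j, lag, strength)` the
#' follower channel `j` tracks the driver phase of channel `i` shifted by
#' `lag`, with tracking fidelity increasing in `strength` (at `strength = 1`
#' the lag is exact at every sample, at `strength = 0` the relative phase
#' diffuses freely).
#'
#' @param n_channels number of channels (>= 2).
#' @param sfreq sampling rate in Hz. Default 256 Hz.
#' @param duration recording length in seconds.
#' @param carrier_band numeric length-2, `(low, high)` in Hz, within
#'   `(0, sfreq/2)`. `low == high` gives a fixed carrier frequency, which is
#'   useful for analytic checks at an exact FFT bin. Default alpha, 8-13 Hz.
#' @param coupled_pairs list of length-4 numeric vectors
#'   `c(i, j, lag, strength)`: driver channel, follower channel, phase lag in
#'   radians (in `(-pi, pi]`), coupling strength in `[0, 1]`. A channel may
#'   follow at most one driver; a pair may appear at most once.
#' @param noise_sd standard deviation of additive white measurement noise, in
#'   units of the unit-amplitude oscillation.
#' @param freq_jitter_sd standard deviation (Hz) of the slow instantaneous
#'   frequency perturbation around the band centre; clipped to the band.
#'   Ignored when `low == high`.
#' @param phase_noise_sd stationary standard deviation (radians) of the
#'   follower's independent phase jitter (an Ornstein-Uhlenbeck process with
#'   100 ms correlation time), scaled by `1 - strength`. The default 3 rad
#'   makes an uncoupled (`strength = 0`) pair's relative phase effectively
#'   uniform while a strongly coupled pair stays tightly locked.
#' @param seed integer seed; the recording is a pure function of the spec.
#'
#' @return an object of class `oscillator_spec`.
#' @export
oscillator_spec <- function(n_channels,
                            sfreq = 256,
                            duration = 60,
                            carrier_band = c(8, 13),
                            coupled_pairs = list(),
                            noise_sd = 0.2,
                            freq_jitter_sd = 1,
                            phase_noise_sd = 3,
                            seed = NULL) {
  if (n_channels < 2) abort("n_channels must be >= 2")
  if (sfreq <= 0 || duration <= 0) abort("sfreq and duration must be positive")
  if (length(carrier_band) != 2 || carrier_band[1] > carrier_band[2] ||
      carrier_band[1] <= 0 || carrier_band[2] >= sfreq / 2) {
    abort("carrier_band must be (low, high) with 0 < low <= high < sfreq/2")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  seen <- character()
  followers <- integer()
  for (p in coupled_pairs) {
    if (length(p) != 4) abort("each coupled pair must be c(i, j, lag, strength)")
    i <- p[1]; j <- p[2]; lag <- p[3]; s <- p[4]
    if (i < 1 || i > n_channels || j < 1 || j > n_channels || i == j) {
      abort("coupled pair channels must be distinct and in 1..n_channels")
    }
    if (lag <= -pi || lag > pi) {
      abort("phase lag must lie in (-pi, pi], got ", signif(lag, 4))
    }
    if (s < 0 || s > 1) abort("coupling strength must lie in [0, 1]")
    key <- paste(sort(c(i, j)), collapse = "-")
    if (key %in% seen) abort("pair (", i, ",", j, ") appears more than once")
    if (j %in% followers) abort("channel ", j, " follows more than one driver")
    seen <- c(seen, key)
    followers <- c(followers, j)
  }
  structure(list(
    n_channels = as.integer(n_channels), sfreq = sfreq, duration = duration,
    carrier_band = carrier_band, coupled_pairs = coupled_pairs,
    noise_sd = noise_sd, freq_jitter_sd = freq_jitter_sd,
    phase_noise_sd = phase_noise_sd, seed = seed
  ), class = "oscillator_spec")
}

#' Canonical coupling layout: a phase-gradient sensor chain
#'
#' Couples consecutive channels along a chain with a fixed phase advance per
#' step, emulating a travelling oscillation sweeping across a sensor array
#' (alpha travelling waves show phase gradients of this kind). Because the
#' follower jitter accumulates along the chain and the lag wraps, the
#' resulting synchronization falls off with sensor distance in the
#' non-monotone way phase-lag measures show on real arrays: nearest
#' neighbours (~lag pi/2) are strong, second neighbours (~lag pi) and fourth
#' neighbours (~lag 2pi) are suppressed. The strong-edge skeleton is
#' triangle-poor and lattice-like, so heavily thresholded graphs become
#' path-like rather than clique-like.
#'
#' @param n_channels chain length.
#' @param lag phase advance per step in radians (default 1.5, ~pi/2).
#' @param strength coupling strength per step in `[0, 1]`.
#' @return list of coupled pairs for [oscillator_spec()].
#' @export
chain_topology <- function(n_channels, lag = 1.5, strength = 0.8) {
  lapply(seq_len(n_channels - 1), function(k) c(k, k + 1, lag, strength))
}

#' Specify a synthetic two-group cohort
#'
#' @param n_subjects_per_group subjects per group (>= 2).
#' @param group_effect `list(parameter, delta, extra_pairs)`. Supported
#'   `parameter`: `"coupling_strength"` -- group B subjects get their mean
#'   coupling strength shifted by `delta` (clipped to `[0, 1]`).
#'   `extra_pairs`, if given, is a list of `c(i, j, lag, strength)` pairs
#'   added to group B subjects only (a planted structural difference).
#'   `NULL` means a null cohort with no group difference.
#' @param subject_variability_sd spread (SD) of per-subject coupling-strength
#'   deviations around the group mean (>= 0).
#' @param seed integer master seed for the cohort.
#'
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects_per_group,
                        group_effect = NULL,
                        subject_variability_sd = 0.05,
                        seed = NULL) {
  if (n_subjects_per_group < 2) abort("n_subjects_per_group must be >= 2")
  if (subject_variability_sd < 0) abort("subject_variability_sd must be >= 0")
  if (!is.null(group_effect)) {
    if (!is.list(group_effect)) abort("group_effect must be a list or NULL")
    param <- group_effect$parameter %||% "coupling_strength"
    if (!param %in% "coupling_strength") {
      abort("unsupported group_effect parameter: ", param)
    }
    group_effect$parameter <- param
    group_effect$delta <- group_effect$delta %||% 0
  }
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    group_effect = group_effect,
    subject_variability_sd = subject_variability_sd,
    seed = seed
  ), class = "cohort_spec")
}

# Internal: one in-band phase trajectory (radians, unwrapped).
# Instantaneous frequency = band centre + AR(1) perturbation clipped to the
# band (100 ms correlation time); phase = integrated frequency + U(0, 2pi).
band_phase <- function(n, sfreq, band, freq_jitter_sd) {
  f0 <- mean(band)
  if (band[1] == band[2] || freq_jitter_sd == 0) {
    f_inst <- rep(f0, n)
  } else {
    rho <- exp(-1 / (0.1 * sfreq))
    eps <- rnorm(n, 0, freq_jitter_sd * sqrt(1 - rho^2))
    x <- numeric(n)
    x[1] <- rnorm(1, 0, freq_jitter_sd)
    for (t in 2:n) x[t] <- rho * x[t - 1] + eps[t]
    f_inst <- pmin(pmax(f0 + x, band[1]), band[2])
  }
  runif(1, 0, 2 * pi) + 2 * pi * cumsum(f_inst) / sfreq
}

#' Generate one synthetic recording
#'
#' Draws a multichannel recording from an [oscillator_spec()]. Channels are
#' unit-amplitude sinusoids of their phase trajectories plus white noise.
#' Identical spec (including seed) gives bit-identical output.
#'
#' @param spec an [oscillator_spec()].
#' @param subject_id,group labels attached to the recording.
#' @param epoch_length default epoch length in samples carried by the
#'   recording (used downstream by [compute_cross_spectra()]); default 2 s.
#'
#' @return a `recording` object: list with `subject_id`, `group`, `data`
#'   (channels x samples matrix), `sfreq`, `epoch_length`, and the phase
#'   matrix in attribute `"phase"` (used by validation tests).
#' @export
generate_recording <- function(spec, subject_id = "S01", group = "A",
                               epoch_length = NULL) {
  stopifnot(inherits(spec, "oscillator_spec"))
  gen <- function() {
    n <- round(spec$duration * spec$sfreq)
    nc <- spec$n_channels
    phase <- matrix(0, nc, n)
    for (k in seq_len(nc)) {
      phase[k, ] <- band_phase(n, spec$sfreq, spec$carrier_band,
                               spec$freq_jitter_sd)
    }
    for (p in spec$coupled_pairs) {
      i <- p[1]; j <- p[2]; lag <- p[3]; s <- p[4]
      # independent phase jitter: OU process, 100 ms correlation time,
      # stationary SD = phase_noise_sd (fast-mixing, so an uncoupled pair's
      # relative phase decorrelates within an epoch)
      rho <- exp(-1 / (0.1 * spec$sfreq))
      eps <- rnorm(n, 0, spec$phase_noise_sd * sqrt(1 - rho^2))
      eta <- numeric(n)
      eta[1] <- rnorm(1, 0, spec$phase_noise_sd)
      for (t in 2:n) eta[t] <- rho * eta[t - 1] + eps[t]
      phase[j, ] <- phase[i, ] + lag + (1 - s) * eta
    }
    x <- sin(phase)
    if (spec$noise_sd > 0) {
      x <- x + matrix(rnorm(nc * n, 0, spec$noise_sd), nc, n)
    }
    rownames(x) <- sprintf("ch%02d", seq_len(nc))
    structure(list(
      subject_id = subject_id, group = group, data = x, sfreq = spec$sfreq,
      epoch_length = as.integer(epoch_length %||% round(2 * spec$sfreq))
    ), class = "recording", phase = phase)
  }
  if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
}

#' Generate a synthetic two-group cohort of recordings
#'
#' Per-subject coupling strengths are drawn around the group mean (group A:
#' the base spec's strengths; group B: shifted by the planted
#' `group_effect$delta`), clipped to `[0, 1]`. Group B additionally receives
#' `group_effect$extra_pairs` if given. Subject seeds are derived from the
#' cohort seed, so the cohort is reproducible and each recording independent.
#'
#' @param cohort a [cohort_spec()].
#' @param base an [oscillator_spec()] giving the common recording parameters
#'   and the group-A coupling layout.
#'
#' @return list of `recording` objects, groups `"A"` then `"B"`, subject ids
#'   `S001`, `S002`, ...
#' @export
generate_cohort <- function(cohort, base) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(base, "oscillator_spec"))
  npg <- cohort$n_subjects_per_group
  n_total <- 2L * npg
  master <- cohort$seed %||% sample.int(.Machine$integer.max - 1L, 1)
  seeds <- derive_seeds(master, n_total + 1L)
  delta <- if (is.null(cohort$group_effect)) 0 else cohort$group_effect$delta
  extra <- if (is.null(cohort$group_effect)) NULL else
    cohort$group_effect$extra_pairs
  recs <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    grp <- if (s <= npg) "A" else "B"
    pairs <- base$coupled_pairs
    if (grp == "B" && !is.null(extra)) pairs <- c(pairs, extra)
    # per-subject deviation from the group-mean strength, shared by all of a
    # subject's pairs (the subject's global synchronizability)
    dev <- withr::with_seed(seeds[s], rnorm(1, 0, cohort$subject_variability_sd))
    pairs <- lapply(pairs, function(p) {
      p[4] <- min(max(p[4] + (if (grp == "B") delta else 0) + dev, 0), 1)
      p
    })
    sp <- base
    sp$coupled_pairs <- pairs
    sp$seed <- seeds[s + 1L] %% .Machine$integer.max
    # re-validate the perturbed spec
    sp <- oscillator_spec(sp$n_channels, sp$sfreq, sp$duration,
                          sp$carrier_band, pairs, sp$noise_sd,
                          sp$freq_jitter_sd, sp$phase_noise_sd, sp$seed)
    recs[[s]] <- generate_recording(sp, subject_id = sprintf("S%03d", s),
                                    group = grp)
  }
  recs
}

#' Write / read a recording as delimited text
#'
#' One numeric matrix (channels x samples, tab-separated) per subject plus a
#' small `# key: value` header (sampling rate, labels, group).
#'
#' @param rec a `recording`.
#' @param path output file path.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a `recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  hdr <- c(
    paste0("# subject_id: ", rec$subject_id),
    paste0("# group: ", rec$group),
    paste0("# sfreq: ", format(rec$sfreq, digits = 15)),
    paste0("# epoch_length: ", rec$epoch_length),
    paste0("# channels: ", paste(rownames(rec$data), collapse = ","))
  )
  writeLines(hdr, path)
  suppressWarnings(write.table(
    format(rec$data, digits = 15, trim = TRUE, scientific = FALSE),
    path, append = TRUE, sep = "\t", row.names = FALSE, col.names = FALSE,
    quote = FALSE
  ))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) abort("recording header missing key: ", key)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  x <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  dimnames(x) <- list(strsplit(get("channels"), ",")[[1]], NULL)
  structure(list(
    subject_id = get("subject_id"), group = get("group"), data = x,
    sfreq = as.numeric(get("sfreq")),
    epoch_length = as.integer(get("epoch_length"))
  ), class = "recording")
}

#' Write a cohort to a directory with a manifest
#'
#' @param recs list of `recording` objects.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV (columns subject_id, group, file),
#'   invisibly.
#' @export
write_cohort <- function(recs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(recs, function(r) {
    f <- paste0(r$subject_id, ".tsv")
    write_recording(r, file.path(dir, f))
    tibble(subject_id = r$subject_id, group = r$group, file = f)
  })
  manifest <- file.path(dir, "manifest.csv")
  write.csv(bind_rows(rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (group %s): %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$sfreq))
  invisible(x)
}
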