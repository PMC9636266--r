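#' Epoch-wise cross-spectra of a recording
#'
#' Cuts the recording into fixed-length non-overlapping epochs (a trailing
#' partial epoch is discarded), applies a Hann window per epoch and channel,
#' and keeps the FFT coefficients of the bins whose centre frequency lies in
#' `band` (inclusive). All five synchronization measures are functionals of
#' these per-epoch coefficients: the epoch-e cross-spectrum of channels x, y
#' at bin f is `S_xy(f) = X_x(f) * Conj(X_y(f))`.
#'
#' Frequency resolution is `sfreq / epoch_length`; pick an epoch length that
#' places a bin at the carrier frequency when exact-bin behaviour matters.
#'
#' @param rec a `recording` (or a plain channels x samples matrix, in which
#'   case `sfreq` must be supplied).
#' @param band numeric `(low, high)` in Hz; default alpha 8-13 Hz.
#' @param epoch_length epoch length in samples; defaults to the recording's
#'   `epoch_length` (2 s for generated recordings).
#' @param sfreq sampling rate, only needed for matrix input.
#' @param window `"hann"` (default, Welch-style) or `"rect"` (plain
#'   periodogram; mainly for cross-checks against unwindowed FFT references).
#'
#' @return object of class `cross_spectra`: `coef` (complex array
#'   n_epochs x n_bins x n_channels), `freqs`, `n_epochs`, `labels`, `band`,
#'   `sfreq`, plus the recording's subject/group labels.
#' @export
compute_cross_spectra <- function(rec, band = c(8, 13), epoch_length = NULL,
                                  sfreq = NULL, window = c("hann", "rect")) {
  window <- match.arg(window)
  if (inherits(rec, "recording")) {
    x <- rec$data; sfreq <- rec$sfreq
    epoch_length <- epoch_length %||% rec$epoch_length
    subject_id <- rec$subject_id; group <- rec$group
  } else {
    x <- as.matrix(rec)
    if (is.null(sfreq)) abort("sfreq required for matrix input")
    epoch_length <- epoch_length %||% round(2 * sfreq)
    subject_id <- NA_character_; group <- NA_character_
  }
  if (any(!is.finite(x))) abort("recording contains non-finite values")
  if (band[1] <= 0 || band[2] >= sfreq / 2 || band[1] > band[2]) {
    abort("band must satisfy 0 < low <= high < sfreq/2")
  }
  L <- as.integer(epoch_length)
  n <- ncol(x); nc <- nrow(x)
  if (L > n) abort("epoch_length exceeds the number of samples")
  n_epochs <- n %/% L
  if (n_epochs < 2) {
    abort("need at least 2 complete epochs (got ", n_epochs,
          "); epoch-averaged estimators are undefined")
  }
  freqs_all <- (0:(L - 1)) * sfreq / L
  bins <- which(freqs_all >= band[1] & freqs_all <= band[2] &
                  freqs_all <= sfreq / 2)
  if (!length(bins)) abort("no FFT bin falls inside the band; ",
                           "increase epoch_length or widen the band")
  win <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  } else {
    rep(1, L)
  }
  coef <- array(complex(real = 0), dim = c(n_epochs, length(bins), nc))
  for (e in seq_len(n_epochs)) {
    seg <- x[, ((e - 1) * L + 1):(e * L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    ft <- mvfft(t(seg) * win)          # L x nc
    coef[e, , ] <- ft[bins, , drop = FALSE]
  }
  structure(list(
    coef = coef, freqs = freqs_all[bins], n_epochs = n_epochs,
    labels = rownames(x) %||% sprintf("ch%02d", seq_len(nc)),
    band = band, sfreq = sfreq, subject_id = subject_id, group = group
  ), class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf(
    "<cross_spectra> %d channels, %d epochs, %d bins in [%g, %g] Hz\n",
    dim(x$coef)[3], x$n_epochs, length(x$freqs), x$band[1], x$band[2]))
  invisible(x)
}

# Internal: per-bin sums over epochs of S_xy = X Conj(X)', of Im(S_xy),
# of |Im(S_xy)|, and of the unit-normalized phase-difference vectors.
# Returns a list of n_bins x N x N arrays used by the measure functions.
cs_accumulate <- function(cs) {
  d <- dim(cs$coef); ne <- d[1]; nb <- d[2]; nc <- d[3]
  S <- array(complex(real = 0), c(nb, nc, nc))
  sumIm <- array(0, c(nb, nc, nc))
  sumAbsIm <- array(0, c(nb, nc, nc))
  sumAbsS <- array(0, c(nb, nc, nc))
  U <- array(complex(real = 0), c(nb, nc, nc))
  for (e in seq_len(ne)) {
    for (b in seq_len(nb)) {
      xe <- cs$coef[e, b, ]
      Se <- outer(xe, Conj(xe))
      S[b, , ] <- S[b, , ] + Se
      im <- Im(Se)
      sumIm[b, , ] <- sumIm[b, , ] + im
      sumAbsIm[b, , ] <- sumAbsIm[b, , ] + abs(im)
      sumAbsS[b, , ] <- sumAbsS[b, , ] + Mod(Se)
      u <- xe / pmax(Mod(xe), .Machine$double.xmin)
      U[b, , ] <- U[b, , ] + outer(u, Conj(u))
    }
  }
  list(S = S / ne, sumIm = sumIm, sumAbsIm = sumAbsIm, sumAbsS = sumAbsS,
       plv = U / ne, n_epochs = ne, n_bins = nb, n_channels = nc)
}

# Internal: wrap a bins x N x N array with dimnames.
bin_array <- function(a, cs) {
  dimnames(a) <- list(format(cs$freqs), cs$labels, cs$labels)
  a
}

# Internal: check band power and error naming the offending channel.
check_band_power <- function(acc, cs, measure) {
  pw <- sapply(seq_len(acc$n_channels), function(k) sum(Re(acc$S[, k, k])))
  bad <- which(pw <= 0)
  if (length(bad)) {
    abort(measure, ": channel(s) ", paste(cs$labels[bad], collapse = ", "),
          " have zero power in the band")
  }
}

#' Weighted phase lag index per frequency bin
#'
#' `wPLI = |mean_e Im(S_xy)| / mean_e |Im(S_xy)|`, with the convention that a
#' zero denominator (e.g. identical signals, where the cross-spectrum is
#' real in every epoch) gives 0. Values lie in `[0, 1]`; zero-lag coupling is
#' suppressed because `Im(S_xy)` then fluctuates around 0.
#'
#' @param cs a `cross_spectra` object.
#' @return numeric array `n_bins x N x N` (zero diagonal).
#' @export
wpli <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  acc <- cs_accumulate(cs)
  out <- abs(acc$sumIm) / pmax(acc$sumAbsIm, .Machine$double.xmin)
  # zero-denominator convention: a cross-spectrum that is real up to
  # floating-point rounding (identical / perfectly zero-lag signals, where
  # |Im S| is within rounding error of 0 relative to |S|) gives 0
  out[acc$sumAbsIm <= 1e-12 * acc$sumAbsS] <- 0
  for (b in seq_len(acc$n_bins)) diag(out[b, , ]) <- 0
  bin_array(out, cs)
}

#' Imaginary part of coherency per frequency bin
#'
#' `ImCoh = Im( mean_e S_xy / sqrt(mean_e S_xx * mean_e S_yy) )`, in
#' `[-1, 1]`. Zero for identical (or purely zero-lag mixed, noiseless)
#' signals, `sin(lag)` in magnitude for an equal-amplitude constant-lag pair.
#'
#' @inheritParams wpli
#' @return numeric array `n_bins x N x N` (antisymmetric before
#'   rectification, zero diagonal).
#' @export
imcoh <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  acc <- cs_accumulate(cs)
  check_band_power(acc, cs, "imcoh")
  out <- array(0, dim(acc$sumIm))
  for (b in seq_len(acc$n_bins)) {
    p <- Re(diag(acc$S[b, , ]))
    norm <- sqrt(outer(p, p))
    out[b, , ] <- Im(acc$S[b, , ]) / pmax(norm, .Machine$double.xmin)
  }
  bin_array(out, cs)
}

#' Magnitude-squared-free coherence per frequency bin
#'
#' `Coh = |mean_e S_xy| / sqrt(mean_e S_xx * mean_e S_yy)`, in `[0, 1]`.
#' Invariant to per-channel amplitude scaling; does not suppress zero-lag
#' (volume-conduction-like) coupling.
#'
#' @inheritParams wpli
#' @return numeric array `n_bins x N x N` (unit diagonal set to 0 by
#'   convention in [band_connectivity()]; here the raw diagonal is 1).
#' @export
coherence <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  acc <- cs_accumulate(cs)
  check_band_power(acc, cs, "coherence")
  out <- array(0, dim(acc$sumIm))
  for (b in seq_len(acc$n_bins)) {
    p <- Re(diag(acc$S[b, , ]))
    norm <- sqrt(outer(p, p))
    out[b, , ] <- Mod(acc$S[b, , ]) / pmax(norm, .Machine$double.xmin)
  }
  bin_array(out, cs)
}

#' Corrected imaginary phase locking value per frequency bin
#'
#' With `PLV = mean_e exp(i * dphi_e)` (phase differences from
#' unit-normalized cross-spectra): `ciPLV = Im(PLV) / sqrt(1 - Re(PLV)^2)`,
#' defined as 0 when `|Re(PLV)| = 1` (perfect zero/pi-lag locking). Any
#' constant nonzero lag gives magnitude 1; zero-lag coupling is suppressed.
#'
#' @inheritParams wpli
#' @return numeric array `n_bins x N x N`.
#' @export
ciplv <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  acc <- cs_accumulate(cs)
  re <- Re(acc$plv); im <- Im(acc$plv)
  den2 <- pmax(1 - re^2, 0)
  out <- im / pmax(sqrt(den2), .Machine$double.xmin)
  # |Re(PLV)| = 1 up to floating-point rounding => defined as 0
  out[den2 <= 1e-12] <- 0
  for (b in seq_len(acc$n_bins)) diag(out[b, , ]) <- 0
  bin_array(out, cs)
}

#' Pairwise phase consistency per frequency bin
#'
#' Mean cosine of all pairwise differences between per-epoch phase
#' differences: `PPC = (|sum_e exp(i dphi_e)|^2 - n) / (n (n - 1))`, the
#' unbiased analogue of the squared PLV; in `[-1, 1]` with expectation 0
#' under independent phases.
#'
#' @inheritParams wpli
#' @return numeric array `n_bins x N x N`.
#' @export
ppc <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  acc <- cs_accumulate(cs)
  n <- acc$n_epochs
  out <- (Mod(acc$plv * n)^2 - n) / (n * (n - 1))
  for (b in seq_len(acc$n_bins)) diag(out[b, , ]) <- 0
  bin_array(out, cs)
}

# Registry of per-bin measure functions.
measure_registry <- list(wpli = wpli, imcoh = imcoh, coherence = coherence,
                         ciplv = ciplv, ppc = ppc)

# Default rectification per measure: quantile thresholding and spanning
# trees need an unsigned strength ordering.
default_rectify <- c(wpli = "raw", coherence = "raw", imcoh = "abs",
                     ciplv = "abs", ppc = "clip")

#' Band-averaged connectivity matrix for one measure
#'
#' Computes the per-bin measure, averages arithmetically across the bins
#' whose centre frequency lies in the band, rectifies signed measures, and
#' returns a symmetric zero-diagonal weight matrix ready for graph analysis.
#'
#' @param rec a `recording` or a `cross_spectra` object.
#' @param measure one of `"wpli"`, `"imcoh"`, `"coherence"`, `"ciplv"`,
#'   `"ppc"`.
#' @param band,epoch_length passed to [compute_cross_spectra()] when `rec`
#'   is a recording.
#' @param rectify `"default"` (|ImCoh|, |ciPLV|, PPC clipped at 0; wPLI and
#'   coherence untouched), `"abs"`, `"clip"` (negative values to 0) or
#'   `"raw"` (signed values kept; the result is then not a valid input for
#'   thresholding).
#'
#' @return object of class `connectivity_matrix`: `subject_id`, `group`,
#'   `measure`, `band`, `labels`, `weights` (symmetric N x N, zero diagonal).
#' @export
band_connectivity <- function(rec, measure, band = c(8, 13),
                              epoch_length = NULL,
                              rectify = c("default", "abs", "clip", "raw")) {
  rectify <- match.arg(rectify)
  measure <- match.arg(measure, names(measure_registry))
  cs <- if (inherits(rec, "cross_spectra")) rec else
    compute_cross_spectra(rec, band = band, epoch_length = epoch_length)
  per_bin <- measure_registry[[measure]](cs)
  w <- apply(per_bin, c(2, 3), mean)
  mode <- if (rectify == "default") default_rectify[[measure]] else rectify
  w <- switch(mode, abs = abs(w), clip = pmax(w, 0), raw = w)
  if (mode == "raw") {
    # mirror the upper triangle so signed measures stay symmetric
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
  } else {
    w <- (w + t(w)) / 2
  }
  diag(w) <- 0
  connectivity_matrix(w, labels = cs$labels, subject_id = cs$subject_id,
                      group = cs$group, measure = measure, band = cs$band)
}

#' Construct a connectivity matrix object
#'
#' Validates symmetry, finiteness and a zero diagonal.
#'
#' @param weights symmetric N x N numeric matrix, zero diagonal.
#' @param labels node labels (default taken from dimnames or generated).
#' @param subject_id,group,measure,band metadata labels.
#' @param tol symmetry tolerance.
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, labels = NULL,
                                subject_id = NA_character_,
                                group = NA_character_,
                                measure = NA_character_, band = NULL,
                                tol = 1e-9) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) abort("weights must be square")
  if (any(!is.finite(weights))) {
    bad <- which(!is.finite(weights), arr.ind = TRUE)[1, ]
    abort("non-finite weight at (", bad[1], ", ", bad[2], ")")
  }
  if (max(abs(weights - t(weights))) > tol) {
    abort("weights asymmetric beyond tolerance ", tol)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  labels <- labels %||% rownames(weights) %||% sprintf("n%02d", seq_len(n))
  dimnames(weights) <- list(labels, labels)
  structure(list(subject_id = subject_id, group = group, measure = measure,
                 band = band, labels = labels, weights = weights),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s / %s: %d nodes, mean weight %.4f\n",
              x$subject_id, x$measure, length(x$labels),
              mean(upper_weights(x$weights))))
  invisible(x)
}
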