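# Exact-bin recordings for analytic limit checks: fixed 10 Hz carrier with
# 4 s epochs puts the carrier exactly on an FFT bin.
lagged_cs <- function(lag, strength = 1, noise_sd = 0, duration = 40,
                      seed = 1, epoch_length = 1024) {
  sp <- oscillator_spec(2, sfreq = 256, duration = duration,
                        carrier_band = c(10, 10),
                        coupled_pairs = list(c(1, 2, lag, strength)),
                        noise_sd = noise_sd, seed = seed)
  compute_cross_spectra(generate_recording(sp), band = c(8, 13),
                        epoch_length = epoch_length)
}
carrier_bin <- function(cs) which(abs(cs$freqs - 10) < 1e-9)

test_that("cross-spectra bookkeeping: epochs, bins, peak, self-consistency", {
  sp <- oscillator_spec(2, sfreq = 256, duration = 10,
                        carrier_band = c(10, 10), noise_sd = 0, seed = 2)
  rec <- generate_recording(sp)
  expect_error(compute_cross_spectra(rec, epoch_length = 2000),
               "at least 2 complete epochs")
  cs <- compute_cross_spectra(rec, band = c(8, 13), epoch_length = 256)
  expect_identical(cs$n_epochs, 10L)
  expect_equal(cs$freqs, 8:13)
  # pure 10 Hz sine: auto-spectrum maximal at the 10 Hz bin
  power <- colMeans(Mod(cs$coef[, , 1])^2)
  expect_identical(which.max(power), which(cs$freqs == 10))
  # identical channels: S_xy = S_xx at every bin
  x <- rec$data[1, ]
  cs2 <- compute_cross_spectra(rbind(a = x, b = x), band = c(8, 13),
                               epoch_length = 256, sfreq = 256)
  sxy <- colMeans(cs2$coef[, , 1] * Conj(cs2$coef[, , 2]))
  sxx <- colMeans(Mod(cs2$coef[, , 1])^2)
  expect_equal(Re(sxy), sxx, tolerance = 1e-12)
  expect_equal(Im(sxy) / sxx, rep(0, length(sxx)), tolerance = 1e-12)
})

test_that("white-noise band power matches an independent periodogram oracle", {
  set.seed(4)
  x <- rnorm(2048)
  sfreq <- 256; L <- 512
  oracle <- mean(vapply(seq_len(4), function(e) {
    oracle_periodogram_band(x[((e - 1) * L + 1):(e * L)], sfreq, c(8, 13))
  }, numeric(1)))
  cs <- compute_cross_spectra(rbind(x, x), band = c(8, 13), epoch_length = L,
                              sfreq = sfreq, window = "rect")
  pkg <- mean(Mod(cs$coef[, , 1])^2)
  expect_equal(pkg / oracle, 1, tolerance = 1e-10)
  # the default Hann window only rescales flat spectra by its power factor
  csh <- compute_cross_spectra(rbind(x, x), band = c(8, 13), epoch_length = L,
                               sfreq = sfreq)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  expect_equal(mean(Mod(csh$coef[, , 1])^2) / (pkg * mean(win^2)), 1,
               tolerance = 0.5)
})

test_that("constant-lag noiseless pairs hit the analytic limits", {
  cs <- lagged_cs(pi / 2)
  b <- carrier_bin(cs)
  expect_equal(wpli(cs)[b, 1, 2], 1, tolerance = 1e-9)
  expect_equal(coherence(cs)[b, 1, 2], 1, tolerance = 1e-9)
  expect_equal(abs(ciplv(cs)[b, 1, 2]), 1, tolerance = 1e-9)
  expect_equal(ppc(cs)[b, 1, 2], 1, tolerance = 1e-9)
  expect_equal(abs(imcoh(cs)[b, 1, 2]), 1, tolerance = 1e-5)
  # pi/4: |ImCoh| = sin(pi/4) by the closed form
  cs4 <- lagged_cs(pi / 4)
  expect_equal(abs(imcoh(cs4)[carrier_bin(cs4), 1, 2]), sin(pi / 4),
               tolerance = 1e-6)
})

test_that("zero-lag (identical / volume-conduction) signals are suppressed", {
  cs <- lagged_cs(0)
  b <- carrier_bin(cs)
  expect_identical(wpli(cs)[b, 1, 2], 0)          # zero-denominator rule
  expect_identical(ciplv(cs)[b, 1, 2], 0)         # |Re(PLV)| = 1 rule
  expect_lt(abs(imcoh(cs)[b, 1, 2]), 1e-12)
  expect_equal(coherence(cs)[b, 1, 2], 1, tolerance = 1e-9)
  # amplitude scaling leaves coherence at 1
  sp <- oscillator_spec(2, sfreq = 256, duration = 8,
                        carrier_band = c(10, 10), noise_sd = 0, seed = 5)
  x <- generate_recording(sp)$data[1, ]
  cs3 <- compute_cross_spectra(rbind(x, 3 * x), band = c(8, 13),
                               epoch_length = 512, sfreq = 256)
  expect_equal(max(abs(coherence(cs3)[, 1, 2] - 1)), 0, tolerance = 1e-9)
})

test_that("ciPLV equals 1 for any constant nonzero lag and respects the guard", {
  for (theta in c(pi / 6, pi / 3, 2)) {
    ph <- cbind(runif(50, 0, 2 * pi))
    cs <- fake_cross_spectra(cbind(ph, ph - theta))
    expect_equal(ciplv(cs)[1, 1, 2], sin(theta) / sqrt(1 - cos(theta)^2),
                 tolerance = 1e-12)
    expect_equal(ciplv(cs)[1, 1, 2], 1, tolerance = 1e-12)
  }
  # exactly zero lag: guard gives 0
  ph <- cbind(runif(50, 0, 2 * pi))
  expect_identical(ciplv(fake_cross_spectra(cbind(ph, ph)))[1, 1, 2], 0)
})

test_that("PPC matches its pairwise-cosine definition on tiny cases", {
  # n = 2 epochs with phase differences 0 and pi: single pair, cos(pi) = -1
  ph <- rbind(c(0, 0), c(0, pi))
  expect_equal(ppc(fake_cross_spectra(ph))[1, 1, 2], -1, tolerance = 1e-12)
  # direct pairwise-cosine oracle on random phase differences
  withr::with_seed(8, {
    dphi <- runif(14, -pi, pi)
    ph <- cbind(rep(0, 14), -dphi)
    oracle <- mean(combn(14, 2, function(jk) cos(dphi[jk[1]] - dphi[jk[2]])))
    expect_equal(ppc(fake_cross_spectra(ph))[1, 1, 2], oracle,
                 tolerance = 1e-12)
  })
  # uniform random phases: unbiased around 0 (3 SE over 500 replicates)
  withr::with_seed(9, {
    vals <- replicate(500, {
      ph <- cbind(rep(0, 100), runif(100, 0, 2 * pi))
      ppc(fake_cross_spectra(ph))[1, 1, 2]
    })
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(500))
})

test_that("independent noise keeps wPLI and coherence near their bias floors", {
  withr::with_seed(31, {
    wbins <- replicate(20, {
      x <- matrix(rnorm(2 * 200 * 64), 2)
      cs <- compute_cross_spectra(x, band = c(8, 13), epoch_length = 64,
                                  sfreq = 256)
      wpli(cs)[, 1, 2]
    })
    # Monte-Carlo average per in-band bin stays under the small-sample floor
    expect_lt(max(rowMeans(wbins)), 0.15)
    x <- matrix(rnorm(2 * 100 * 128), 2)
    cs <- compute_cross_spectra(x, band = c(8, 13), epoch_length = 128,
                                sfreq = 256)
    expect_lt(mean(coherence(cs)[, 1, 2]), 0.2)
  })
})

test_that("zero-lag mixtures: phase-lag measures vanish, coherence persists", {
  sp <- oscillator_spec(2, sfreq = 256, duration = 250, noise_sd = 0,
                        seed = 13)
  x <- generate_recording(sp)$data[1, ]
  withr::with_seed(14, y <- x + rnorm(length(x), 0, 1))
  cs <- compute_cross_spectra(rbind(x, y), band = c(8, 13),
                              epoch_length = 128, sfreq = 256)  # 500 epochs
  w <- mean(wpli(cs)[, 1, 2]); ic <- mean(abs(imcoh(cs)[, 1, 2]))
  cv <- mean(abs(ciplv(cs)[, 1, 2])); ch <- mean(coherence(cs)[, 1, 2])
  expect_lt(w, 0.1); expect_lt(ic, 0.1); expect_lt(cv, 0.1)
  expect_gt(ch, 0.5)
  expect_gt(ch, 3 * max(w, ic, cv))
})

test_that("band_connectivity returns valid rectified symmetric matrices", {
  sp <- oscillator_spec(4, duration = 20,
                        coupled_pairs = list(c(1, 3, pi / 2, 1)),
                        noise_sd = 0, seed = 19)
  rec <- generate_recording(sp)
  cs <- compute_cross_spectra(rec)
  for (ms in c("wpli", "imcoh", "coherence", "ciplv", "ppc")) {
    m <- band_connectivity(cs, ms)
    expect_identical(m$weights - t(m$weights), matrix(0, 4, 4),
                     ignore_attr = TRUE)
    expect_identical(unname(diag(m$weights)), rep(0, 4))
    expect_true(all(m$weights >= 0))
    # the planted pair is the strongest edge for every measure
    top <- which(m$weights == max(m$weights), arr.ind = TRUE)
    expect_true(all(sort(unique(as.vector(top))) == c(1, 3)))
  }
  # raw mode keeps signs but stays symmetric
  mr <- band_connectivity(cs, "imcoh", rectify = "raw")
  expect_identical(mr$weights, t(mr$weights))
  # zero-power channel errors name the channel
  silent <- rbind(rec$data[1:2, ], 0)
  expect_error(
    band_connectivity(
      compute_cross_spectra(silent, band = c(8, 13), epoch_length = 512,
                            sfreq = 256), "imcoh"),
    "zero power")
})

test_that("all-independent channels give uniformly weak wPLI matrices", {
  withr::with_seed(23, x <- matrix(rnorm(6 * 200 * 64), 6))
  cs <- compute_cross_spectra(x, band = c(8, 13), epoch_length = 64,
                              sfreq = 256)
  m <- band_connectivity(cs, "wpli")
  expect_lt(max(m$weights), 0.2)
})
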