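test_that("welch_psd satisfies Parseval and resolves sinusoid power", {
  set.seed(31)
  fs <- 250
  x <- rnorm(60 * fs)                       # unit variance white noise
  sp <- welch_psd(x, fs, 4, 2)
  integ <- band_power(sp, min(sp$freq[sp$freq > 0]), max(sp$freq))
  expect_within(integ, 1, 0.05)

  a <- 3
  tone <- a * sin(2 * pi * 10 * (1:(30 * fs)) / fs)
  spt <- welch_psd(tone, fs, 2, 1)
  expect_within(band_power(spt, 8, 12), a^2 / 2, 0.02 * a^2 / 2)

  spz <- welch_psd(rep(0, 10 * fs), fs, 2, 1)
  expect_true(all(spz$power == 0))
  expect_error(welch_psd(rnorm(100), fs, 4, 2), "shorter")
  expect_error(welch_psd(x, fs, 2, 2), "overlap")
})

test_that("band_power integrates density over half-open bands", {
  flat <- structure(list(freq = seq(0, 125, by = 0.5),
                         power = rep(1, 251), fs = 250, window_s = 2,
                         overlap_s = 1, n_segments = 1), class = "eeg_spectrum")
  expect_equal(band_power(flat, 30, 50), 20)
  # additivity: seven canonical bands never exceed the 0.5-50 total
  b <- eeg_bands()
  tot <- band_power(flat, 0.5, 50)
  parts <- sum(vapply(seq_len(nrow(b)), function(i) {
    band_power(flat, b$low_hz[i], b$high_hz[i])
  }, numeric(1)))
  expect_lte(parts, tot + 1e-9)
  expect_error(band_power(flat, 50, 50), "empty")
  expect_error(band_power(flat, 100, 200), "outside")
})

test_that("spectral entropy has the right bounds, ordering and scale invariance", {
  mk <- function(p) structure(list(freq = seq(0.5, 50, by = 0.5), power = p,
                                   fs = 100, window_s = 2, overlap_s = 1,
                                   n_segments = 1), class = "eeg_spectrum")
  n <- length(seq(0.5, 50, by = 0.5))
  expect_equal(spectral_entropy(mk(rep(2, n))), 1)
  onebin <- rep(0, n); onebin[40] <- 5
  expect_equal(spectral_entropy(mk(onebin)), 0)

  set.seed(32)
  fs <- 250
  white <- rnorm(40 * fs)
  pink <- eegpheno:::shaped_noise(40 * fs, fs, function(f) pmax(f, 0.5)^-1)
  sw <- welch_psd(white, fs, 4, 2)
  spk <- welch_psd(pink, fs, 4, 2)
  expect_gt(spectral_entropy(sw), spectral_entropy(spk))
  scaled <- sw; scaled$power <- scaled$power * 7.3
  expect_equal(spectral_entropy(sw), spectral_entropy(scaled), tolerance = 1e-12)
  expect_error(spectral_entropy(mk(rep(0, n))), "zero")
})

test_that("fit_aperiodic recovers exponents, unbiased by oscillatory peaks", {
  set.seed(33)
  fs <- 250
  x2 <- eegpheno:::shaped_noise(180 * fs, fs, function(f) 10 * pmax(f, 0.5)^-2)
  f2 <- fit_aperiodic(welch_psd(x2, fs, 4, 2), c(1, 50))
  expect_within(f2$exponent, 2, 0.15)

  peaked <- function(f) 10 * pmax(f, 0.5)^-1 + 40 * exp(-(f - 10)^2 / 2)
  x1 <- eegpheno:::shaped_noise(180 * fs, fs, peaked)
  f1 <- fit_aperiodic(welch_psd(x1, fs, 4, 2), c(1, 50))
  expect_within(f1$exponent, 1, 0.15)
  expect_gte(nrow(f1$peaks), 1)
  expect_within(f1$peaks$center_hz[which.max(f1$peaks$height)], 10, 1)

  flat <- fit_aperiodic(welch_psd(rnorm(120 * fs), fs, 4, 2), c(1, 50))
  expect_within(flat$exponent, 0, 0.1)
})

test_that("exponent recovery RMSE stays below 0.2 across chi in {0.5,1,2,3}", {
  set.seed(34)
  fs <- 250
  err <- vapply(c(0.5, 1, 2, 3), function(chi) {
    x <- eegpheno:::shaped_noise(150 * fs, fs,
                                 function(f) 20 * pmax(f, 0.5)^-chi)
    fit_aperiodic(welch_psd(x, fs, 4, 2), c(1, 50))$exponent - chi
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("Tort MI separates uncoupled, partially and fully gated signals", {
  # degenerate distribution: all amplitude in one of 18 bins -> MI = 1
  expect_equal(eegpheno:::mi_from_bins(c(5, rep(0, 17))), 1)
  expect_equal(eegpheno:::mi_from_bins(rep(1, 18)), 0)

  fs <- 250
  t <- (1:(40 * fs)) / fs
  # uncoupled: independent narrowband noise carries the amplitude
  mis <- vapply(1:20, function(s) {
    set.seed(400 + s)
    x <- 10 * sin(2 * pi * 4 * t) +
      eegpheno:::shaped_noise(length(t), fs, function(f) {
        ifelse(f >= 30 & f <= 50, 1, 0.01)
      })
    tort_mi(x, fs, phase_band = c(2, 6), amp_band = c(30, 50))
  }, numeric(1))
  expect_lt(stats::median(mis), 0.01)

  # MI strictly increases with coupling depth
  mi_at_depth <- function(d) {
    set.seed(41)
    carrier <- eegpheno:::shaped_noise(length(t), fs, function(f) {
      ifelse(f >= 30 & f <= 50, 1, 0.001)
    })
    slow <- sin(2 * pi * 4 * t)
    x <- 10 * slow + (1 + d * slow) * carrier
    tort_mi(x, fs, c(2, 6), c(30, 50))
  }
  m <- vapply(c(0.2, 0.5, 0.9), mi_at_depth, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("stage_psd averages only the requested stage's epochs", {
  ses <- sleep_session()
  sp <- stage_psd(ses$recording$channels$EEG, ses$recording$fs,
                  ses$hypnogram, "NREM")
  expect_s3_class(sp, "eeg_spectrum")
  # NREM delta (2 Hz generator peak) dominates theta
  expect_gt(band_power(sp, 1, 4), 3 * band_power(sp, 4, 8))
  expect_error(stage_psd(ses$recording$channels$EEG, ses$recording$fs,
                         hypnogram(rep("WAKE", length(ses$hypnogram$stages))),
                         "NREM"), "no NREM")
})
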