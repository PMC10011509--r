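test_that("epoch_events baselines, drops edge trials and rejects artifacts", {
  fs <- 200
  rec <- recording(list(EEG = rep(5, 60 * fs)), fs = fs)   # constant offset
  ev <- data.frame(onset_s = seq(1, 55, by = 0.6)[1:90], label = "standard")
  ep <- epoch_events(rec, ev, t_min = -0.1, t_max = 0.3,
                     baseline_window = c(-0.05, 0))
  expect_lt(max(abs(ep$data)), 1e-12)                      # baseline removes DC

  # 100 events, 2 of them too close to the recording edges -> 98 trials
  ev2 <- data.frame(onset_s = c(0.05, seq(1, 55, length.out = 98), 59.95),
                    label = "standard")
  ep2 <- epoch_events(rec, ev2, -0.1, 0.3, baseline_window = NULL)
  expect_equal(nrow(ep2$data), 98)
  expect_equal(ep2$n_dropped_edge, 2)

  # one 500 uV artifact trial against a 400 uV ceiling
  x <- rnorm(60 * fs, sd = 10)
  art_on <- round(30 * fs)
  x[art_on + 20] <- 500
  rec3 <- recording(list(EEG = x), fs = fs)
  ev3 <- data.frame(onset_s = c(10, 20, 30, 40), label = "standard")
  ep3 <- epoch_events(rec3, ev3, -0.1, 0.3, baseline_window = c(-0.05, 0),
                      reject_uv = 400)
  expect_equal(ep3$n_rejected, 1)
  expect_equal(nrow(ep3$data), 3)
})

test_that("ASSR ratio is 1 without stimulation and matches analytic power addition", {
  fs <- 250
  # no added signal -> expectation 1
  ses0 <- generate_assr_session(stim_freqs = 40, n_trains_per_freq = 60,
                                entrainment_gain = 0,
                                background_params = flat_background(1),
                                fs = fs, seed = 71)
  ep0 <- epoch_events(ses0$recording, ses0$events, -0.5, 1,
                      baseline_window = NULL, reject_uv = Inf)
  r0 <- assr_power_ratio(ep0, 40)
  expect_within(r0$ratio, 1, 0.15)

  # flat background of density c: baseline bin density = c; an added
  # sinusoid of amplitude A contributes A^2*nw/(3*fs) at the bin (Hann
  # ENBW), so gain g with A = g*rms, rms^2 = c*fs/2 gives ratio
  # 1 + g^2*fs/12. Choose g for ratio = 4; 300 trials keep the baseline
  # density estimate (one 0.5-s segment per trial) within ~6%.
  g <- sqrt(36 / fs)
  ses <- generate_assr_session(stim_freqs = 40, n_trains_per_freq = 300,
                               entrainment_gain = g,
                               background_params = flat_background(1),
                               fs = fs, seed = 72)
  ep <- epoch_events(ses$recording, ses$events, -0.5, 1,
                     baseline_window = NULL, reject_uv = Inf)
  r <- assr_power_ratio(ep, 40)
  expect_within(r$ratio, 4, 0.5)

  # off-frequency control stays near 1
  roff <- assr_power_ratio(ep, 40, analysis_freq_hz = 20)
  expect_within(roff$ratio, 1, 0.2)

  # scale invariance: multiplying the recording by a constant leaves the ratio
  ses$recording$channels$EEG <- ses$recording$channels$EEG * 3.7
  eps <- epoch_events(ses$recording, ses$events, -0.5, 1,
                      baseline_window = NULL, reject_uv = Inf)
  expect_equal(assr_power_ratio(eps, 40)$ratio, r$ratio, tolerance = 1e-10)

  expect_error(assr_power_ratio(ep, 0.5), "resolvable")
})

test_that("erp_difference is pointwise deviant minus standard", {
  t <- seq(-0.1, 0.3, by = 0.004)
  base <- exp(-(t - 0.05)^2 / 0.001)
  bump <- 2 * exp(-(t - 0.2)^2 / 0.002)
  es <- structure(list(time = t, waveforms = list(standard = base),
                       n_trials = c(standard = 10)), class = "erp")
  ed <- structure(list(time = t, waveforms = list(deviant = base + bump),
                       n_trials = c(deviant = 10)), class = "erp")
  dif <- erp_difference(es, ed)
  expect_equal(dif$waveforms$difference, bump)
  dif0 <- erp_difference(es, es)
  expect_true(all(dif0$waveforms$difference == 0))
  es2 <- es; es2$time <- t + 0.01
  expect_error(erp_difference(es2, ed), "grids differ")
})

test_that("find_erp_peaks recovers template components and honors polarity", {
  fs <- 1000
  t <- seq(-0.05, 0.35, by = 1 / fs)
  comps <- default_erp_components("deviant")
  w <- eegpheno:::erp_template(t, comps)
  pk <- find_erp_peaks(w, time = t)
  expect_true(all(pk$present))
  lat <- stats::setNames(pk$latency_ms, pk$component)
  amp <- stats::setNames(pk$amplitude_uv, pk$component)
  for (i in seq_len(nrow(comps))) {
    nm <- comps$name[i]
    expect_within(lat[[nm]], comps$latency_ms[i], 5)
    expect_within(abs(amp[[nm]]), comps$amp_uv[i], 0.1 * comps$amp_uv[i])
  }
  # inverted polarity: the negative bump at P1's latency is picked up as N1
  # when its window covers that latency; the true P1 is flagged absent
  pk_inv <- find_erp_peaks(-w, time = t,
                           windows = list(P1 = c(10, 50), N1 = c(10, 100),
                                          P3a = c(100, 300)))
  expect_false(pk_inv$present[pk_inv$component == "P1"])
  expect_true(pk_inv$present[pk_inv$component == "N1"])
  expect_within(pk_inv$latency_ms[pk_inv$component == "N1"], 25, 5)
  # flat waveform: everything absent
  pk0 <- find_erp_peaks(rep(0, length(t)), time = t)
  expect_true(all(!pk0$present))
})

test_that("ERP averaging noise shrinks as 1/sqrt(trials)", {
  set.seed(73)
  fs <- 200
  rec <- recording(list(EEG = rnorm(400 * fs, sd = 15)), fs = fs)
  ev <- data.frame(onset_s = seq(2, 398, by = 0.8), label = "standard")
  ep <- epoch_events(rec, ev, -0.1, 0.3, baseline_window = NULL)
  rms <- function(rows) sqrt(mean(colMeans(ep$data[rows, ])^2))
  r25 <- mean(vapply(0:7, function(k) rms(k * 25 + 1:25), numeric(1)))
  r100 <- mean(vapply(0:3, function(k) rms(k * 100 + 1:100), numeric(1)))
  expect_within(r25 / r100, 2, 0.5)
})
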