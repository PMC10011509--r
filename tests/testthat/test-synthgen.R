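test_that("generate_hypnogram hits degenerate, targeted and latency contracts", {
  # degenerate chain: single admissible stage
  h1 <- generate_hypnogram(600, target_nrem_fraction = 1.0, seed = 1)
  expect_true(all(h1$stages == "NREM"))

  # 12 h at target 0.50 lands within +/- 3 pp
  h2 <- generate_hypnogram(12 * 3600, target_nrem_fraction = 0.5, seed = 2)
  expect_within(mean(h2$stages == "NREM"), 0.5, 0.03)

  # construction constraint: no sleep before the requested latency
  h3 <- generate_hypnogram(3600, target_nrem_fraction = 0.5,
                           sleep_onset_latency_s = 600, seed = 3)
  expect_true(all(h3$stages[1:60] == "WAKE"))
  expect_true(h3$stages[61] %in% c("NREM", "REM"))

  expect_error(generate_hypnogram(3600, target_nrem_fraction = 0.9, seed = 4),
               "infeasible")
  expect_error(generate_hypnogram(3605, target_nrem_fraction = 0.5), "multiple")
})

test_that("realized stage fractions converge to target over long sessions (24 h)", {
  for (s in c(10, 20, 30)) {
    h <- generate_hypnogram(24 * 3600, target_nrem_fraction = 0.55, seed = s)
    expect_within(mean(h$stages == "NREM"), 0.55, 0.03)
  }
})

test_that("hypnogram and session generation are seed-reproducible bit-identically", {
  h1 <- generate_hypnogram(1200, target_nrem_fraction = 0.6, seed = 42)
  h2 <- generate_hypnogram(1200, target_nrem_fraction = 0.6, seed = 42)
  expect_identical(h1$stages, h2$stages)
  s1 <- synthesize_session(h1, fs = 200, seed = 7)
  s2 <- synthesize_session(h2, fs = 200, seed = 7)
  expect_identical(s1$recording$channels$EEG, s2$recording$channels$EEG)
  expect_identical(s1$spindles, s2$spindles)
})

test_that("aperiodic-only synthesis has the requested log-log PSD slope", {
  pars <- list(NREM = list(offset = 1.5, exponent = 2, emg_rms = 5,
                           peaks = data.frame(center_hz = numeric(0),
                                              amp_uv = numeric(0),
                                              sd_hz = numeric(0))),
               WAKE = list(offset = 1.5, exponent = 2, emg_rms = 30,
                           peaks = data.frame(center_hz = numeric(0),
                                              amp_uv = numeric(0),
                                              sd_hz = numeric(0))),
               REM = list(offset = 1.5, exponent = 2, emg_rms = 4,
                          peaks = data.frame(center_hz = numeric(0),
                                             amp_uv = numeric(0),
                                             sd_hz = numeric(0))))
  h <- generate_hypnogram(600, target_nrem_fraction = 1, seed = 5)
  ses <- synthesize_session(h, stage_params = pars,
                            spindle_params = spindle_gen_params(rate_per_min = c("11" = 0)),
                            fs = 250, seed = 6)
  sp <- welch_psd(ses$recording$channels$EEG, 250, 4, 2)
  sel <- sp$freq >= 1 & sp$freq <= 50
  slope <- stats::coef(stats::lm(log10(sp$power[sel]) ~ log10(sp$freq[sel])))[2]
  expect_within(unname(slope), -2, 0.1)
})

test_that("ground-truth spindle counts follow the injected Poisson rate", {
  h <- generate_hypnogram(3600, target_nrem_fraction = 1, seed = 8)
  ses <- synthesize_session(h, spindle_params = spindle_gen_params(
    rate_per_min = c("11" = 5)), fs = 200, seed = 9)
  n <- nrow(ses$spindles)
  expect_within(n, 300, 4 * sqrt(300))   # 60 min * 5/min, 4-sigma band
  # sample-accurate onsets all inside NREM epochs
  ep <- floor(ses$spindles$onset_s / 10) + 1
  expect_true(all(h$stages[ep] == "NREM"))
  expect_true(all(ses$spindles$offset_s - ses$spindles$onset_s >= 0.3))
})

test_that("gamma amplitude scaling squares into 30-50 Hz band power (Parseval oracle)", {
  h <- generate_hypnogram(600, target_nrem_fraction = 1, seed = 10)
  spp <- spindle_gen_params(rate_per_min = c("11" = 0))
  base <- synthesize_session(h, spindle_params = spp, fs = 500, seed = 11)
  up <- synthesize_session(h, spindle_params = spp, fs = 500, seed = 11,
                           effects = effect_config(gamma_amp = 1.2))
  gp <- function(x) mean(bandpass(x, 30, 50, fs = 500)^2)  # variance = band power
  ratio <- gp(up$recording$channels$EEG) / gp(base$recording$channels$EEG)
  expect_within(ratio, 1.44, 0.08)
})

test_that("every generated epoch satisfies Parseval within 5%", {
  ses <- sleep_session()
  eeg <- ses$recording$channels$EEG
  fs <- ses$recording$fs
  grid <- epoch_grid(length(eeg), 10, fs = fs)
  set.seed(13)
  for (k in sample(grid$epoch, 12)) {
    x <- epoch_slice(eeg, grid, k)
    sp <- welch_psd(x, fs, window_s = 10, overlap_s = 0, taper = "rect")
    integ <- sum(diff(sp$freq) * (head(sp$power, -1) + tail(sp$power, -1)) / 2)
    expect_within(integ / mean((x - mean(x))^2), 1, 0.05)
  }
})

test_that("ASSR sessions carry the paradigm contract", {
  ses <- generate_assr_session(stim_freqs = c(10, 20, 30, 40, 50),
                               n_trains_per_freq = 4, fs = 200, seed = 14)
  expect_equal(nrow(ses$events), 20)            # trains x frequencies
  expect_equal(sort(unique(ses$events$freq_hz)), c(10, 20, 30, 40, 50))
  expect_equal(as.vector(table(ses$events$freq_hz)), rep(4, 5))
  # randomized order: not blocked by frequency
  expect_gt(length(rle(ses$events$freq_hz)$lengths), 5)
  expect_error(generate_assr_session(train_duration_s = 0.5, fs = 200), ">= 1")
  expect_error(generate_assr_session(iti_s = 0.2, fs = 200), "baseline|overlap")
})

test_that("MMN sessions have 900/100 composition and non-adjacent deviants", {
  ses <- generate_mmn_session(fs = 200, seed = 15)
  expect_equal(sum(ses$events$label == "standard"), 900)
  expect_equal(sum(ses$events$label == "deviant"), 100)
  for (s in 16:19) {
    ev <- generate_mmn_session(n_standard = 90, n_deviant = 10, fs = 200,
                               seed = s)$events
    dv <- which(ev$label == "deviant")
    expect_true(all(diff(dv) >= 2))
  }
  expect_error(generate_mmn_session(isi_s = 0.2, fs = 200), "isi")
})

test_that("noiseless MMN trial equals the component template exactly", {
  comps <- default_erp_components("deviant")
  ses <- generate_mmn_session(n_standard = 20, n_deviant = 2, noise_scale = 0,
                              fs = 500, seed = 20)
  ep <- epoch_events(ses$recording, ses$events, t_min = 0, t_max = 0.3,
                     baseline_window = NULL)
  i <- which(ep$labels == "deviant")[1]
  tpl <- eegpheno:::erp_template(ep$time, comps)
  expect_lt(max(abs(ep$data[i, ] - tpl)), 1e-8)
})

test_that("deviant P3a scaling propagates to the difference waveform template", {
  base <- default_erp_components("deviant")
  scaled <- generate_mmn_session(n_standard = 20, n_deviant = 2, noise_scale = 0,
                                 fs = 500, seed = 21,
                                 effects = effect_config(p3a_amp = 0.3))
  ep <- epoch_events(scaled$recording, scaled$events, t_min = 0, t_max = 0.35,
                     baseline_window = NULL)
  dif <- colMeans(ep$data[ep$labels == "deviant", , drop = FALSE]) -
    colMeans(ep$data[ep$labels == "standard", , drop = FALSE])
  p3a_target <- 0.3 * base$amp_uv[base$name == "P3a"]
  sel <- ep$time >= 0.15 & ep$time <= 0.25
  expect_within(max(dif[sel]), p3a_target, 0.05 * p3a_target + 0.2)
})

test_that("parameter containers enforce their invariants", {
  expect_error(spindle_gen_params(duration_range_s = c(0.1, 1)), "0.3")
  expect_error(spindle_gen_params(rate_per_min = c("11" = -1)), ">= 0")
  expect_error(effect_config(gamma_amp = 0), "> 0")
  bad <- default_stage_params()
  bad$WAKE$emg_rms <- 1
  expect_error(validate_stage_params <- eegpheno:::validate_stage_params(bad), "EMG")
  comps <- default_erp_components("standard")
  comps$latency_ms <- c(100, 50, 200)
  expect_error(eegpheno:::validate_erp_components(comps), "ordered")
})
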