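test_that("EDF write/read round trip preserves samples to one quantization step", {
  set.seed(11)
  rec <- recording(list(EEG = 60 * sin(2 * pi * 4 * (1:12000) / 200) + rnorm(12000),
                        EMG = rnorm(12000, sd = 25)),
                   fs = 200, meta = list(subject = "m01", genotype = "Het", age = "3mo"))
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  r2 <- read_edf(path)

  expect_equal(names(r2$channels), c("EEG", "EMG"))
  expect_equal(r2$fs, 200)
  expect_equal(length(r2$channels$EEG), 12000)  # 60 s x 200 Hz from the header
  for (ch in names(rec$channels)) {
    step <- 2 * max(abs(rec$channels[[ch]])) / 65535
    expect_lt(max(abs(r2$channels[[ch]] - rec$channels[[ch]])), step)
  }
  expect_equal(r2$meta$subject, "m01")
  expect_equal(r2$meta$genotype, "Het")
  expect_equal(r2$meta$age, "3mo")
})

test_that("truncated EDF raises a format error rather than loading silently", {
  rec <- recording(list(EEG = rnorm(2000)), fs = 100)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  full <- readBin(path, "raw", file.info(path)$size)
  writeBin(full[seq_len(length(full) - 600)], path)
  expect_error(read_edf(path), "truncated")
  expect_error(read_edf(tempfile()), "no such file")
})

test_that("python mne reads our EDF with matching scale (independent oracle)", {
  set.seed(12)
  x <- 40 * sin(2 * pi * 6 * (1:4000) / 200)
  rec <- recording(list(EEG = x), fs = 200)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  script <- paste0(
    "import mne, numpy as np; ",
    "raw = mne.io.read_raw_edf(r'", path, "', verbose='ERROR'); ",
    "d = raw.get_data(units='uV'); ",
    "print(round(float(np.sqrt((d[0]**2).mean())), 4), raw.info['sfreq'])")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  vals <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.numeric(vals[1]), sqrt(mean(x^2)), tolerance = 1e-3)
  expect_equal(as.numeric(vals[2]), 200)
})

test_that("bandpass passes in-band tones, rejects drift and DC", {
  fs <- 500
  t <- (1:(20 * fs)) / fs
  tone <- sin(2 * pi * 5 * t)
  y <- bandpass(tone, 1, 100, fs = fs)
  core <- seq(2 * fs, length(y) - 2 * fs)      # exclude filter edges
  env <- Mod(eegpheno:::analytic_signal(y))
  expect_within(stats::median(env[core]), 1, 0.01)   # < 1% attenuation

  drift <- sin(2 * pi * 0.1 * t)
  yd <- bandpass(drift, 1, 100, fs = fs)
  expect_lt(sqrt(mean(yd[core]^2)), 0.05 * sqrt(mean(drift^2)))

  yc <- bandpass(rep(3, 10 * fs), 1, 100, fs = fs)
  expect_lt(max(abs(yc)), 1e-6)

  # idempotence in the passband to within 2% amplitude
  y2 <- bandpass(y, 1, 100, fs = fs)
  expect_within(stats::median(Mod(eegpheno:::analytic_signal(y2))[core]), 1, 0.02)

  expect_error(bandpass(tone, 50, 300, fs = fs), "Nyquist|fs/2")
  expect_error(bandpass(tone, 1, 100), "fs")
})

test_that("epoch_grid tiles the recording with half-open 0-based intervals", {
  g <- epoch_grid(3600 * 100, 10, fs = 100)
  expect_equal(nrow(g), 360)
  g2 <- epoch_grid(35 * 100, 10, fs = 100)
  expect_equal(nrow(g2), 3)                       # trailing partial dropped
  expect_equal(g2$start_sample, c(0, 1000, 2000)) # k*L*fs convention
  expect_equal(g2$end_sample, c(1000, 2000, 3000))
  # exact tiling: every used sample covered exactly once
  covered <- unlist(lapply(seq_len(nrow(g2)), function(i) {
    (g2$start_sample[i] + 1):g2$end_sample[i]
  }))
  expect_equal(sort(covered), 1:3000)
  expect_error(epoch_grid(1000, 0, fs = 100), "> 0")
})

test_that("event and hypnogram files round trip", {
  ev <- data.frame(onset_s = c(1, 2.5, 9), label = c("train", "train", "train"),
                   freq_hz = c(10, 40, 20))
  p <- tempfile(fileext = ".tsv")
  write_events(ev, p)
  expect_equal(read_events(p), ev)
  expect_error(write_events(data.frame(onset_s = c(3, 1), label = "a"), p), "sorted")

  hyp <- hypnogram(c("WAKE", "NREM", "NREM", "REM"), epoch_len_s = 10)
  hp <- tempfile(fileext = ".tsv")
  write_hypnogram(hyp, hp)
  expect_equal(read_hypnogram(hp)$stages, hyp$stages)
})
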