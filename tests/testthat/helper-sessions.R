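# Shared fixtures, generated in code. Sessions are desk-scale (short, fs
# reduced from the acquisition 1000 Hz) so the suite stays fast; the physics
# (band placement, SNR, rates) matches the full-scale generator defaults.

fixture_env <- new.env(parent = emptyenv())

# one cached sleep session reused by staging/spindle/spectra tests
sleep_session <- function() {
  if (is.null(fixture_env$sleep)) {
    hyp <- generate_hypnogram(1500, target_nrem_fraction = 0.6,
                              sleep_onset_latency_s = 120, seed = 301)
    fixture_env$sleep <- synthesize_session(hyp, fs = 250, seed = 302)
  }
  fixture_env$sleep
}

# flat-spectrum background ("white" EEG) for analytic ASSR oracles
flat_background <- function(density_uv2hz = 1) {
  list(offset = log10(density_uv2hz), exponent = 1e-9,
       peaks = data.frame(center_hz = numeric(0), amp_uv = numeric(0),
                          sd_hz = numeric(0)),
       emg_rms = 10)
}

expect_within <- function(object, target, tol) {
  expect_true(abs(object - target) <= tol,
              label = sprintf("%.4g within %.3g of %.4g", object, tol, target))
}
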