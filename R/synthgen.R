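# Ground-truthed synthetic EEG/EMG sessions: sleep/wake with stage-dependent
# spectra and inserted spindles, ASSR click-train sessions, and oddball (MMN)
# sessions. Every generator returns the ground truth alongside the signal so
# downstream detectors and pipelines can be scored against it.

#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the session RNG.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Per-stage spectral parameters of the synthetic EEG
#'
#' Each stage is described by an aperiodic 1/f component
#' (`10^offset * f^-exponent`, with a plateau below 0.5 Hz) plus Gaussian
#' oscillatory peaks given as (center Hz, RMS amplitude uV, bandwidth SD Hz),
#' and a nuchal EMG RMS level. Defaults emulate frontal mouse EEG: NREM with
#' strong delta, a sigma peak and a steep aperiodic slope; REM dominated by
#' theta; WAKE flatter with high EMG tone.
#'
#' @param stages optional named list overriding individual stages.
#' @return named list (WAKE/NREM/REM) of stage parameter lists with fields
#'   `offset`, `exponent`, `peaks` (data.frame center_hz/amp_uv/sd_hz),
#'   `emg_rms`.
#' @export
default_stage_params <- function(stages = NULL) {
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center_hz = m[, 1], amp_uv = m[, 2], sd_hz = m[, 3])
  }
  p <- list(
    WAKE = list(offset = 1.2, exponent = 1.5,
                peaks = pk(7, 6, 1.2, 40, 3, 4), emg_rms = 40),
    NREM = list(offset = 1.5, exponent = 2.5,
                peaks = pk(2, 18, 0.8, 13, 3, 1.0, 40, 2, 4), emg_rms = 8),
    REM  = list(offset = 1.0, exponent = 2.0,
                peaks = pk(7, 12, 1.2, 40, 2, 4), emg_rms = 4))
  if (!is.null(stages)) p[names(stages)] <- stages
  validate_stage_params(p)
  p
}

validate_stage_params <- function(p) {
  for (st in names(p)) {
    s <- p[[st]]
    if (s$exponent <= 0) stop("stage ", st, ": aperiodic exponent must be > 0")
    if (nrow(s$peaks) && any(s$peaks$center_hz < 0.5 | s$peaks$center_hz > 100)) {
      stop("stage ", st, ": peak centers must lie in 0.5-100 Hz")
    }
  }
  if (all(c("WAKE", "NREM", "REM") %in% names(p))) {
    if (!(p$WAKE$emg_rms > p$NREM$emg_rms && p$WAKE$emg_rms > p$REM$emg_rms)) {
      stop("EMG RMS must be highest in WAKE")
    }
  }
  invisible(p)
}

#' Spindle insertion parameters
#'
#' Event rate per NREM minute at each center frequency, the duration range
#' and the burst peak amplitude. Durations must lie within 0.3-4 s.
#'
#' @param rate_per_min named numeric: events per NREM minute at 9/11/13/15 Hz.
#' @param duration_range_s length-2 range of event durations (s).
#' @param amp_uv peak amplitude of the Hann-enveloped burst (uV).
#' @param min_gap_s minimum gap between same-frequency events (s); emulates
#'   the refractoriness of thalamocortical spindle generation and keeps the
#'   realized event rate proportional to `rate_per_min` (default 1 s).
#' @return list of spindle generation parameters.
#' @export
spindle_gen_params <- function(rate_per_min = c("9" = 2, "11" = 3, "13" = 3, "15" = 2),
                               duration_range_s = c(0.6, 1.5), amp_uv = 25,
                               min_gap_s = 1.0) {
  if (any(rate_per_min < 0)) stop("spindle rates must be >= 0")
  if (duration_range_s[1] < 0.3 || duration_range_s[2] > 4 ||
      duration_range_s[1] > duration_range_s[2]) {
    stop("spindle durations must lie within [0.3, 4] s")
  }
  if (min_gap_s < 0) stop("min_gap_s must be >= 0")
  list(rate_per_min = rate_per_min, duration_range_s = duration_range_s,
       amp_uv = amp_uv, min_gap_s = min_gap_s)
}

#' Injectable genotype effect scalings
#'
#' Multiplicative scalings applied on top of the baseline generator
#' parameters, encoding a simulated genotype contrast. All scalings must be
#' positive. `gamma_amp` scales the EEG spectral amplitude in the 30-50 Hz
#' band (so band *power* scales by its square); `spindle_rate` scales the
#' inserted event rate; `assr_gain` the entrainment gain; `p3a_amp` the
#' deviant-condition P3a component; `nrem_fraction` the hypnogram's target
#' NREM fraction.
#'
#' @param gamma_amp,spindle_rate,assr_gain,p3a_amp,nrem_fraction positive scalars.
#' @return list of class `effect_config`.
#' @export
effect_config <- function(gamma_amp = 1, spindle_rate = 1, assr_gain = 1,
                          p3a_amp = 1, nrem_fraction = 1) {
  v <- c(gamma_amp, spindle_rate, assr_gain, p3a_amp, nrem_fraction)
  if (any(v <= 0)) stop("all effect scalings must be > 0")
  structure(list(gamma_amp = gamma_amp, spindle_rate = spindle_rate,
                 assr_gain = assr_gain, p3a_amp = p3a_amp,
                 nrem_fraction = nrem_fraction),
            class = "effect_config")
}

# One-sided target PSD (uV^2/Hz) for a stage at frequencies f. The 1/f law
# plateaus at 0.5 Hz and rolls off toward DC like the AC-coupled acquisition
# front end (recordings are hardware-bandpassed from ~1 Hz up).
stage_psd_profile <- function(f, sp, gamma_amp = 1) {
  p <- 10^sp$offset * pmax(f, 0.5)^(-sp$exponent)
  vlf <- f < 0.5
  if (any(vlf)) p[vlf] <- p[vlf] * (f[vlf] / 0.5)^4
  if (nrow(sp$peaks)) {
    for (j in seq_len(nrow(sp$peaks))) {
      h <- sp$peaks$amp_uv[j]^2 / (sp$peaks$sd_hz[j] * sqrt(2 * pi))
      p <- p + h * exp(-(f - sp$peaks$center_hz[j])^2 / (2 * sp$peaks$sd_hz[j]^2))
    }
  }
  if (gamma_amp != 1) {
    g <- f >= 30 & f <= 50
    p[g] <- p[g] * gamma_amp^2
  }
  p
}

# Gaussian noise with a prescribed one-sided PSD, by spectral shaping of
# white noise: Y(f) = W(f) * sqrt(P(f) * fs / 2). DC is zeroed.
shaped_noise <- function(n, fs, psd_fun) {
  W <- stats::fft(stats::rnorm(n))
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # fold to two-sided |f|
  g <- sqrt(psd_fun(pmax(f, fs / n)) * fs / 2)
  g[1] <- 0
  Re(stats::fft(W * g, inverse = TRUE) / n)
}

#' Generate a ground-truth hypnogram
#'
#' Semi-Markov stage sequence on a fixed epoch grid, cycling
#' WAKE -> NREM -> (REM with probability `p_rem`) -> WAKE. NREM and REM bout
#' lengths are shifted-Poisson draws around the given means; each WAKE bout
#' mean is adapted to steer the realized NREM fraction to the target. The
#' session starts with a WAKE bout covering the requested sleep-onset
#' latency.
#'
#' @param duration_s session duration, a multiple of `epoch_len_s`.
#' @param stage_bout_means named numeric: mean bout lengths in seconds for
#'   WAKE, NREM, REM (all > `epoch_len_s`).
#' @param target_nrem_fraction target fraction of epochs in NREM, in (0, 1].
#'   Values >= 0.995 produce a pure-NREM session after the onset latency.
#' @param sleep_onset_latency_s wake time before the first sleep epoch (s).
#' @param p_rem probability that a NREM bout is followed by REM.
#' @param epoch_len_s epoch length (default 10 s).
#' @param seed RNG seed.
#' @return a `hypnogram`.
#' @export
generate_hypnogram <- function(duration_s, stage_bout_means = c(WAKE = 120, NREM = 120, REM = 60),
                               target_nrem_fraction = 0.55,
                               sleep_onset_latency_s = 0, p_rem = 0.3,
                               epoch_len_s = 10, seed = NULL) {
  if (abs(duration_s %% epoch_len_s) > 1e-9) {
    stop("duration_s must be a multiple of epoch_len_s")
  }
  if (target_nrem_fraction <= 0 || target_nrem_fraction > 1) {
    stop("target_nrem_fraction must lie in (0, 1]")
  }
  E <- as.integer(round(duration_s / epoch_len_s))
  lat_e <- as.integer(ceiling(sleep_onset_latency_s / epoch_len_s))
  if (lat_e >= E) stop("sleep-onset latency exceeds session duration")
  f <- target_nrem_fraction

  if (f >= 0.995) {
    stages <- c(rep("WAKE", lat_e), rep("NREM", E - lat_e))
    return(hypnogram(stages, epoch_len_s = epoch_len_s))
  }

  nm <- stage_bout_means["NREM"] / epoch_len_s
  rm_ <- stage_bout_means["REM"] / epoch_len_s
  if (any(stage_bout_means <= epoch_len_s)) stop("bout means must exceed the epoch length")
  # feasibility at the nominal target over the post-onset span
  f_eff <- f * E / (E - lat_e)
  if (f_eff >= 1 || nm * (1 / f_eff - 1) - p_rem * rm_ < 1) {
    stop("infeasible parameters: target NREM fraction ", f,
         " unreachable with the given bout means/latency")
  }

  with_seed(seed, {
    draw <- function(mean_e) 1L + stats::rpois(1, max(mean_e - 1, 0))
    stages <- character(E)
    if (lat_e > 0) stages[seq_len(lat_e)] <- "WAKE"
    used <- lat_e
    nrem <- 0L
    while (used < E) {
      b <- min(draw(nm), E - used)
      stages[used + seq_len(b)] <- "NREM"
      used <- used + b
      nrem <- nrem + b
      if (used >= E) break
      if (stats::runif(1) < p_rem) {
        b <- min(draw(rm_), E - used)
        stages[used + seq_len(b)] <- "REM"
        used <- used + b
        if (used >= E) break
      }
      # steer the WAKE bout so the realized NREM fraction tracks the target
      need <- f * E - nrem
      f_adj <- min(max(need / max(E - used, 1), 0.02), 0.98)
      wm <- max(nm * (1 / f_adj - 1) - p_rem * rm_, 1)
      b <- min(draw(wm), E - used)
      stages[used + seq_len(b)] <- "WAKE"
      used <- used + b
    }
    hypnogram(stages, epoch_len_s = epoch_len_s)
  })
}

#' Synthesize a sleep/wake EEG+EMG session from a hypnogram
#'
#' Per stage bout, the EEG is Gaussian noise spectrally shaped to the
#' stage's aperiodic-plus-peaks profile; the EMG is white noise at the
#' stage's RMS. During NREM, Hann-enveloped sinusoidal spindle bursts are
#' inserted at the configured center frequencies and returned as a
#' sample-accurate ground-truth event table. Events that cannot fit inside
#' their NREM bout are skipped and counted in the `skipped` attribute of the
#' event table.
#'
#' @param hyp a `hypnogram`.
#' @param stage_params output of [default_stage_params()].
#' @param spindle_params output of [spindle_gen_params()].
#' @param fs sampling rate (>= 200 Hz; default 1000).
#' @param seed RNG seed.
#' @param effects an [effect_config()].
#' @param meta metadata list passed to the recording.
#' @return list with `recording` (`eeg_recording` with channels EEG, EMG),
#'   `spindles` (data.frame onset_s/offset_s/freq_hz/amp_uv), `hypnogram`.
#' @export
synthesize_session <- function(hyp, stage_params = default_stage_params(),
                               spindle_params = spindle_gen_params(),
                               fs = 1000, seed = NULL,
                               effects = effect_config(), meta = list()) {
  if (fs < 200) stop("fs must be >= 200 Hz")
  validate_stage_params(stage_params)
  epoch_len_s <- hyp$epoch_len_s
  r <- rle(hyp$stages)
  bout_stage <- r$values
  bout_len_s <- r$lengths * epoch_len_s
  bout_start_s <- c(0, cumsum(bout_len_s))[seq_along(bout_len_s)]

  with_seed(seed, {
    n_total <- as.integer(round(sum(bout_len_s) * fs))
    eeg <- numeric(n_total)
    emg <- numeric(n_total)
    truth <- list()
    skipped <- 0L
    dur_rng <- spindle_params$duration_range_s
    rates <- spindle_params$rate_per_min * effects$spindle_rate

    for (b in seq_along(bout_stage)) {
      st <- bout_stage[b]
      n <- as.integer(round(bout_len_s[b] * fs))
      i0 <- as.integer(round(bout_start_s[b] * fs))
      sp <- stage_params[[st]]
      g <- if (st == "WAKE") 1 else effects$gamma_amp
      eeg_b <- shaped_noise(n, fs, function(f) stage_psd_profile(f, sp, gamma_amp = g))
      emg_b <- stats::rnorm(n, sd = sp$emg_rms)

      if (st == "NREM" && length(rates)) {
        for (fc in as.numeric(names(rates))) {
          lambda <- rates[[as.character(fc)]] * bout_len_s[b] / 60
          k <- stats::rpois(1, lambda)
          if (k == 0) next
          placed <- matrix(numeric(0), ncol = 2)
          gap <- spindle_params$min_gap_s
          for (j in seq_len(k)) {
            # retry-sample a position respecting the refractory gap, so the
            # realized rate is not thinned more at higher injection rates
            ok <- FALSE
            for (try in 1:50) {
              d <- stats::runif(1, dur_rng[1], dur_rng[2])
              if (d >= bout_len_s[b]) next
              on <- stats::runif(1, 0, bout_len_s[b] - d)
              if (!nrow(placed) ||
                  all(on - gap >= placed[, 2] | (on + d + gap) <= placed[, 1])) {
                ok <- TRUE
                break
              }
            }
            if (!ok) { skipped <- skipped + 1L; next }
            placed <- rbind(placed, c(on, on + d))
            s0 <- as.integer(round(on * fs))
            nd <- as.integer(round(d * fs))
            tt <- (seq_len(nd) - 1) / fs
            env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nd) - 1) / (nd - 1))
            burst <- spindle_params$amp_uv * env *
              sin(2 * pi * fc * tt + stats::runif(1, 0, 2 * pi))
            eeg_b[s0 + seq_len(nd)] <- eeg_b[s0 + seq_len(nd)] + burst
            truth[[length(truth) + 1L]] <-
              data.frame(onset_s = bout_start_s[b] + on,
                         offset_s = bout_start_s[b] + on + d,
                         freq_hz = fc, amp_uv = spindle_params$amp_uv)
          }
        }
      }
      eeg[i0 + seq_len(n)] <- eeg_b
      emg[i0 + seq_len(n)] <- emg_b
    }

    spn <- if (length(truth)) do.call(rbind, truth) else
      data.frame(onset_s = numeric(0), offset_s = numeric(0),
                 freq_hz = numeric(0), amp_uv = numeric(0))
    spn <- spn[order(spn$onset_s), , drop = FALSE]
    rownames(spn) <- NULL
    attr(spn, "skipped") <- skipped
    list(recording = recording(list(EEG = eeg, EMG = emg), fs = fs, meta = meta),
         spindles = spn, hypnogram = hyp)
  })
}

#' Default background parameters for auditory sessions
#'
#' Quiet-wake-like 1/f background used while the animal sits through click
#' trains or oddball tones.
#'
#' @param offset,exponent aperiodic parameters (log10 uV^2/Hz and slope).
#' @return a stage-parameter list usable with the signal generators.
#' @export
default_background_params <- function(offset = 1.2, exponent = 1.5) {
  list(offset = offset, exponent = exponent,
       peaks = data.frame(center_hz = numeric(0), amp_uv = numeric(0),
                          sd_hz = numeric(0)),
       emg_rms = 20)
}

#' Generate an ASSR click-train session
#'
#' Trains at each stimulation frequency are presented in randomized order.
#' During each train a sinusoid at the stimulation frequency, with amplitude
#' `entrainment_gain * assr_gain_effect * background RMS`, is added from
#' stimulus onset to offset. The event table carries onset time and
#' frequency.
#'
#' @param stim_freqs stimulation frequencies in Hz (default 10-50 in steps of 10).
#' @param n_trains_per_freq trains per frequency; a scalar, or a vector with
#'   one count per entry of `stim_freqs`.
#' @param train_duration_s train length (>= 1 s so the 0.2-1 s evoked window exists).
#' @param iti_s silent interval between trains (>= 0.6 s so baselines are clean).
#' @param entrainment_gain added-sinusoid amplitude as a fraction of background RMS.
#' @param background_params background spectral parameters
#'   ([default_background_params()]).
#' @param fs sampling rate.
#' @param seed RNG seed.
#' @param effects an [effect_config()]; `assr_gain` multiplies the gain.
#' @param meta metadata for the recording.
#' @return list with `recording` (channel EEG), `events`
#'   (onset_s/label/freq_hz), `gain_used`.
#' @export
generate_assr_session <- function(stim_freqs = seq(10, 50, by = 10),
                                  n_trains_per_freq = 20, train_duration_s = 1,
                                  iti_s = 1.5, entrainment_gain = 0.15,
                                  background_params = default_background_params(),
                                  fs = 1000, seed = NULL,
                                  effects = effect_config(), meta = list()) {
  if (train_duration_s < 1) stop("train_duration_s must be >= 1 s (evoked window is 0.2-1 s)")
  if (iti_s < 0.6) stop("iti_s too short: baseline window (0.5 s) would overlap the previous train")
  if (!length(n_trains_per_freq) %in% c(1L, length(stim_freqs))) {
    stop("n_trains_per_freq must be a scalar or match stim_freqs")
  }
  with_seed(seed, {
    freqs <- sample(rep(stim_freqs, times = n_trains_per_freq))
    slot <- train_duration_s + iti_s
    lead <- 1
    onsets <- lead + (seq_along(freqs) - 1) * slot
    if (any(diff(onsets) < train_duration_s)) stop("overlapping trains")
    dur_s <- ceiling(lead + length(freqs) * slot + 1)
    n <- as.integer(dur_s * fs)
    eeg <- shaped_noise(n, fs, function(f) stage_psd_profile(f, background_params))
    bg_rms <- stats::sd(eeg)
    gain <- entrainment_gain * effects$assr_gain
    amp <- gain * bg_rms
    for (i in seq_along(freqs)) {
      s0 <- as.integer(round(onsets[i] * fs))
      nd <- as.integer(round(train_duration_s * fs))
      tt <- (seq_len(nd) - 1) / fs
      eeg[s0 + seq_len(nd)] <- eeg[s0 + seq_len(nd)] + amp * sin(2 * pi * freqs[i] * tt)
    }
    ev <- data.frame(onset_s = onsets, label = "train", freq_hz = freqs)
    list(recording = recording(list(EEG = eeg), fs = fs, meta = meta),
         events = ev, gain_used = gain)
  })
}

#' Event-related potential component templates
#'
#' Each component is a polarity-signed Gaussian bump: P1 and P3a positive,
#' N1 negative. Amplitudes are peak values in uV, latencies and widths (SD)
#' in ms. The deviant condition's P3a is the novelty component: it is absent
#' from the standard-condition template by default, so the
#' deviant-minus-standard difference waveform carries the full P3a.
#'
#' @param condition "standard" or "deviant".
#' @return data.frame with `name`, `latency_ms`, `polarity`, `amp_uv`, `width_ms`.
#' @export
default_erp_components <- function(condition = c("standard", "deviant")) {
  condition <- match.arg(condition)
  d <- data.frame(
    name = c("P1", "N1", "P3a"),
    latency_ms = c(25, 60, 180),
    polarity = c(1, -1, 1),
    amp_uv = if (condition == "deviant") c(22, 32, 25) else c(20, 22, 0),
    width_ms = c(8, 15, 40))
  validate_erp_components(d)
  d
}

validate_erp_components <- function(d) {
  stopifnot(all(c("name", "latency_ms", "polarity", "amp_uv", "width_ms") %in% names(d)))
  if (any(d$width_ms <= 0)) stop("ERP component widths must be > 0")
  lat <- stats::setNames(d$latency_ms, d$name)
  if (all(c("P1", "N1", "P3a") %in% d$name) &&
      !(lat["P1"] < lat["N1"] && lat["N1"] < lat["P3a"])) {
    stop("component latencies must be ordered P1 < N1 < P3a")
  }
  invisible(d)
}

erp_template <- function(t_s, comps) {
  y <- numeric(length(t_s))
  for (j in seq_len(nrow(comps))) {
    y <- y + comps$polarity[j] * comps$amp_uv[j] *
      exp(-(t_s * 1000 - comps$latency_ms[j])^2 / (2 * comps$width_ms[j]^2))
  }
  y
}

#' Generate an auditory oddball (MMN) session
#'
#' `n_standard` standard and `n_deviant` deviant tone events at a fixed ISI,
#' with deviants placed uniformly at random subject to at least one standard
#' between consecutive deviants. Each event adds its condition's ERP
#' component sum to the ongoing 1/f background.
#'
#' @param n_standard,n_deviant trial counts (defaults 900/100).
#' @param components_standard,components_deviant component tables
#'   ([default_erp_components()]).
#' @param isi_s inter-stimulus interval (s); must exceed the slowest
#'   component's latency + 3 widths.
#' @param background_params background spectral parameters.
#' @param noise_scale multiplier on the background amplitude (0 = noiseless).
#' @param fs sampling rate.
#' @param seed RNG seed.
#' @param effects an [effect_config()]; `p3a_amp` scales the deviant P3a.
#' @param meta metadata for the recording.
#' @return list with `recording` (channel EEG) and `events` (onset_s/label).
#' @export
generate_mmn_session <- function(n_standard = 900, n_deviant = 100,
                                 components_standard = default_erp_components("standard"),
                                 components_deviant = default_erp_components("deviant"),
                                 isi_s = 0.6,
                                 background_params = default_background_params(),
                                 noise_scale = 1, fs = 1000, seed = NULL,
                                 effects = effect_config(), meta = list()) {
  validate_erp_components(components_standard)
  validate_erp_components(components_deviant)
  if (n_deviant >= n_standard) stop("deviants must be the minority condition")
  tail_ms <- max(c(components_standard$latency_ms + 3 * components_standard$width_ms,
                   components_deviant$latency_ms + 3 * components_deviant$width_ms))
  if (isi_s * 1000 < tail_ms) {
    stop("isi_s too short: components extend to ", round(tail_ms), " ms")
  }
  i <- which(components_deviant$name == "P3a")
  if (length(i)) components_deviant$amp_uv[i] <- components_deviant$amp_uv[i] * effects$p3a_amp

  with_seed(seed, {
    n_trials <- n_standard + n_deviant
    # place deviants into distinct gaps between standards: never adjacent
    gaps <- sort(sample.int(n_standard + 1L, n_deviant))
    labels <- rep("standard", n_trials)
    labels[gaps + seq_len(n_deviant) - 1L] <- "deviant"
    lead <- 1
    onsets <- lead + (seq_len(n_trials) - 1) * isi_s
    dur_s <- ceiling(lead + n_trials * isi_s + 1)
    n <- as.integer(dur_s * fs)
    eeg <- if (noise_scale > 0) {
      noise_scale * shaped_noise(n, fs, function(f) stage_psd_profile(f, background_params))
    } else numeric(n)
    nd <- as.integer(round((tail_ms / 1000 + 0.05) * fs))
    t_s <- (seq_len(nd) - 1) / fs
    tpl <- list(standard = erp_template(t_s, components_standard),
                deviant = erp_template(t_s, components_deviant))
    for (k in seq_len(n_trials)) {
      s0 <- as.integer(round(onsets[k] * fs))
      eeg[s0 + seq_len(nd)] <- eeg[s0 + seq_len(nd)] + tpl[[labels[k]]]
    }
    ev <- data.frame(onset_s = onsets, label = labels)
    list(recording = recording(list(EEG = eeg), fs = fs, meta = meta), events = ev)
  })
}
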