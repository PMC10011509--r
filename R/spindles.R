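#' Detect sleep spindles at one center frequency
#'
#' Median-relative two-threshold envelope detector, robust to amplitude
#' scaling across subjects: the EEG is bandpassed to `center_hz +/-
#' half_bw_hz`, the analytic-signal envelope is smoothed with a `smooth_s`
#' moving RMS, and samples exceeding `detect_thr` times the median NREM
#' envelope seed candidate events. Event boundaries are extended outward to
#' the `boundary_thr`-times-median crossing, events closer than
#' `merge_gap_s` are merged, and events are kept if their duration lies in
#' `duration_range_s`, they fall entirely inside NREM epochs, and their
#' envelope-weighted instantaneous frequency lies within `freq_tol_hz` of
#' the center frequency (rejecting spectral leakage from bursts at
#' neighbouring spindle frequencies).
#'
#' @param eeg numeric EEG samples.
#' @param fs sampling rate.
#' @param hyp a `hypnogram` aligned to the signal.
#' @param center_hz spindle center frequency (9, 11, 13 or 15 in this assay).
#' @param half_bw_hz half bandwidth of the detection band (default 1 Hz, so
#'   the four bands do not overlap).
#' @param detect_thr,boundary_thr thresholds as multiples of the median NREM
#'   envelope (defaults 3 and 1.5).
#' @param smooth_s envelope moving-RMS length (default 0.2 s).
#' @param merge_gap_s merge events separated by less than this (default 0.3 s).
#' @param duration_range_s admissible event durations (default 0.5-3 s).
#' @param freq_tol_hz admissible deviation of the event's instantaneous
#'   frequency from `center_hz` (default = `half_bw_hz`).
#' @param flank_veto reject events whose envelope in a flanking band
#'   (center +/- 2*half_bw) exceeds the envelope in the detection band;
#'   this suppresses leakage from bursts at neighbouring spindle
#'   frequencies (default TRUE).
#' @return data.frame of class `spindle_events`: `onset_s`, `offset_s`,
#'   `freq_hz`, `peak_amp_uv`, `mean_amp_uv`.
#' @export
detect_spindles <- function(eeg, fs, hyp, center_hz, half_bw_hz = 1.0,
                            detect_thr = 3, boundary_thr = 1.5,
                            smooth_s = 0.2, merge_gap_s = 0.3,
                            duration_range_s = c(0.5, 3.0),
                            freq_tol_hz = half_bw_hz, flank_veto = TRUE) {
  if (center_hz + half_bw_hz >= fs / 2) stop("detection band outside Nyquist")
  grid <- epoch_grid(length(eeg), hyp$epoch_len_s, fs = fs)
  n_use <- max(grid$end_sample)
  stage_per_sample <- rep(hyp$stages[seq_len(nrow(grid))],
                          each = round(hyp$epoch_len_s * fs))
  nrem <- stage_per_sample == "NREM"
  if (!any(nrem)) stop("no NREM epochs in hypnogram")

  xb <- bandpass(eeg[seq_len(n_use)], center_hz - half_bw_hz,
                 center_hz + half_bw_hz, fs = fs)
  z <- analytic_signal(xb)
  env <- Mod(z)
  k <- max(3L, as.integer(round(smooth_s * fs)))
  sm <- stats::filter(env^2, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- env[is.na(sm)]^2
  env <- sqrt(as.numeric(sm))

  med <- stats::median(env[nrem])
  if (med <= 0) stop("median NREM envelope is zero")
  seed <- env > detect_thr * med & nrem
  if (!any(seed)) return(empty_spindles())
  r <- rle(seed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values)
  ev <- data.frame(s0 = starts[hit], s1 = ends[hit])

  # frequency-specificity vetoes run on the seed runs, before extension and
  # merging, so that leakage excursions from bursts at neighbouring spindle
  # frequencies can neither survive nor contaminate true events.
  on_freq <- vapply(seq_len(nrow(ev)), function(i) {
    s <- ev$s0[i]:max(ev$s1[i] - 1L, ev$s0[i])
    fi <- Arg(z[pmin(s + 1L, length(z))] * Conj(z[s])) * fs / (2 * pi)
    wgt <- env[s]^2
    sum(fi * wgt) / sum(wgt)
  }, numeric(1))
  ev <- ev[abs(on_freq - center_hz) <= freq_tol_hz, , drop = FALSE]
  if (!nrow(ev)) return(empty_spindles())

  if (flank_veto) {
    pad <- as.integer(fs)
    band_rms <- function(xseg, lo, hi, a, b) {
      if (lo <= 0.5 || hi >= fs / 2) return(0)
      e <- Mod(analytic_signal(bandpass(xseg, lo, hi, fs = fs)))
      sqrt(mean(e[a:b]^2))
    }
    ok <- vapply(seq_len(nrow(ev)), function(i) {
      a0 <- max(1L, ev$s0[i] - pad)
      b0 <- min(n_use, ev$s1[i] + pad)
      seg <- eeg[a0:b0]
      a <- ev$s0[i] - a0 + 1L
      b <- ev$s1[i] - a0 + 1L
      own <- band_rms(seg, center_hz - half_bw_hz, center_hz + half_bw_hz, a, b)
      own > band_rms(seg, center_hz - 3 * half_bw_hz, center_hz - half_bw_hz, a, b) &&
        own > band_rms(seg, center_hz + half_bw_hz, center_hz + 3 * half_bw_hz, a, b)
    }, logical(1))
    ev <- ev[ok, , drop = FALSE]
    if (!nrow(ev)) return(empty_spindles())
  }

  # extend each surviving seed run outward to the boundary-threshold
  # crossing; the boundary is floored at a fraction of the event's own peak
  # envelope so that filter ringing below the burst does not smear onsets
  n_env <- length(env)
  ev <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    s0 <- ev$s0[i]; s1 <- ev$s1[i]
    thr_b <- max(boundary_thr * med, 0.25 * max(env[s0:s1]))
    while (s0 > 1L && env[s0 - 1L] >= thr_b) s0 <- s0 - 1L
    while (s1 < n_env && env[s1 + 1L] >= thr_b) s1 <- s1 + 1L
    data.frame(s0 = s0, s1 = s1)
  }))
  ev <- unique(ev[order(ev$s0), , drop = FALSE])

  # merge events with gap < merge_gap_s
  gap <- merge_gap_s * fs
  keep <- list(ev[1, ])
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      last <- keep[[length(keep)]]
      if (ev$s0[i] - last$s1 < gap) {
        keep[[length(keep)]]$s1 <- max(last$s1, ev$s1[i])
      } else keep[[length(keep) + 1L]] <- ev[i, ]
    }
  }
  ev <- do.call(rbind, keep)

  dur <- (ev$s1 - ev$s0 + 1L) / fs
  inside <- vapply(seq_len(nrow(ev)), function(i) {
    all(nrem[ev$s0[i]:ev$s1[i]])
  }, logical(1))
  ev <- ev[dur >= duration_range_s[1] & dur <= duration_range_s[2] & inside, ,
           drop = FALSE]
  if (!nrow(ev)) return(empty_spindles())

  out <- data.frame(
    onset_s = (ev$s0 - 1L) / fs,
    offset_s = ev$s1 / fs,
    freq_hz = center_hz,
    peak_amp_uv = vapply(seq_len(nrow(ev)), function(i) max(env[ev$s0[i]:ev$s1[i]]),
                         numeric(1)),
    mean_amp_uv = vapply(seq_len(nrow(ev)), function(i) mean(env[ev$s0[i]:ev$s1[i]]),
                         numeric(1)))
  class(out) <- c("spindle_events", "data.frame")
  out
}

empty_spindles <- function() {
  out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                    freq_hz = numeric(0), peak_amp_uv = numeric(0),
                    mean_amp_uv = numeric(0))
  class(out) <- c("spindle_events", "data.frame")
  out
}

#' Detect spindles at several center frequencies
#' @inheritParams detect_spindles
#' @param centers_hz vector of center frequencies (default 9, 11, 13, 15).
#' @param ... passed to [detect_spindles()].
#' @return combined `spindle_events` data.frame.
#' @export
detect_spindles_multi <- function(eeg, fs, hyp, centers_hz = c(9, 11, 13, 15), ...) {
  out <- do.call(rbind, lapply(centers_hz, function(fc) {
    detect_spindles(eeg, fs, hyp, center_hz = fc, ...)
  }))
  class(out) <- c("spindle_events", "data.frame")
  out
}

#' Spindle density per NREM minute
#'
#' Event count divided by NREM time, per center frequency. By design the
#' normalizing NREM time is taken from light-cycle epochs only.
#'
#' @param events a `spindle_events` data.frame.
#' @param hyp a `hypnogram`.
#' @param freqs center frequencies to report (default 9, 11, 13, 15).
#' @param light_only count only light-cycle NREM epochs (default TRUE).
#' @return data.frame `freq_hz`, `n_events`, `density_per_min`.
#' @export
spindle_density <- function(events, hyp, freqs = c(9, 11, 13, 15),
                            light_only = TRUE) {
  sel <- hyp$stages == "NREM"
  if (light_only) sel <- sel & hyp$light
  nrem_min <- sum(sel) * hyp$epoch_len_s / 60
  if (nrem_min <= 0) stop("zero NREM time")
  data.frame(
    freq_hz = freqs,
    n_events = vapply(freqs, function(f) sum(events$freq_hz == f), numeric(1)),
    density_per_min = vapply(freqs, function(f) sum(events$freq_hz == f), numeric(1)) / nrem_min)
}

#' Match detected spindles to ground truth
#'
#' Greedy one-to-one matching by onset proximity; a detection matches a
#' truth event if their onsets differ by at most `tol_s` and frequencies
#' agree.
#'
#' @param detected,truth spindle event tables with `onset_s`, `freq_hz`.
#' @param tol_s onset tolerance in seconds (default 0.25).
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
spindle_f1 <- function(detected, truth, tol_s = 0.25) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L
  if (nrow(detected)) {
    for (i in order(detected$onset_s)) {
      cand <- which(!used & truth$freq_hz == detected$freq_hz[i] &
                      abs(truth$onset_s - detected$onset_s[i]) <= tol_s)
      if (length(cand)) {
        used[cand[which.min(abs(truth$onset_s[cand] - detected$onset_s[i]))]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(detected) - tp
  fn <- nrow(truth) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall, f1 = f1)
}
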