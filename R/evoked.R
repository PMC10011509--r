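#' Cut stimulus-locked epochs from a recording
#'
#' Slices a per-trial window around each event onset and subtracts the mean
#' over the baseline window from each trial. Trials whose window would run
#' past the recording edge are dropped (counted in `n_dropped_edge`); trials
#' whose baseline-corrected absolute amplitude exceeds `reject_uv` are
#' rejected as artifacts (counted in `n_rejected`).
#'
#' @param rec an `eeg_recording`.
#' @param events event table with `onset_s`, `label`, optionally `freq_hz`.
#' @param t_min,t_max epoch window relative to stimulus onset (s).
#' @param baseline_window length-2 window (s, relative to onset) whose mean
#'   is subtracted per trial; NULL skips baseline correction.
#' @param channel channel to epoch (default first).
#' @param reject_uv artifact rejection ceiling in uV (default 400).
#' @return object of class `eeg_epochs`: list with `data` (trials x samples
#'   matrix, uV), `time` (s), `labels`, `freq_hz`, `fs`, `n_dropped_edge`,
#'   `n_rejected`.
#' @export
epoch_events <- function(rec, events, t_min, t_max, baseline_window = NULL,
                         channel = NULL, reject_uv = 400) {
  if (is.null(channel)) channel <- names(rec$channels)[1]
  x <- rec$channels[[channel]]
  fs <- rec$fs
  rel <- seq(round(t_min * fs), round(t_max * fs))
  time <- rel / fs
  on_samp <- round(events$onset_s * fs)
  ok_edge <- on_samp + rel[1] >= 0 & on_samp + rel[length(rel)] < length(x)
  n_dropped <- sum(!ok_edge)
  idx <- which(ok_edge)
  if (!length(idx)) stop("no events fit inside the recording")
  m <- t(vapply(idx, function(i) x[on_samp[i] + rel + 1L], numeric(length(rel))))
  if (!is.null(baseline_window)) {
    bsel <- time >= baseline_window[1] & time <= baseline_window[2]
    if (!any(bsel)) stop("baseline window outside the epoch window")
    m <- m - rowMeans(m[, bsel, drop = FALSE])
  }
  peak <- apply(abs(m), 1, max)
  keep <- peak <= reject_uv
  structure(list(
    data = m[keep, , drop = FALSE], time = time,
    labels = events$label[idx][keep],
    freq_hz = if (!is.null(events$freq_hz)) events$freq_hz[idx][keep] else NULL,
    fs = fs, n_dropped_edge = n_dropped, n_rejected = sum(!keep)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", nrow(x$data), " trials x ", ncol(x$data), " samples, ",
      min(x$time), "-", max(x$time), " s (", x$n_dropped_edge, " edge-dropped, ",
      x$n_rejected, " artifact-rejected)\n", sep = "")
  invisible(x)
}

#' ASSR evoked/baseline power ratio
#'
#' Welch PSDs are computed per trial on the evoked (0.2-1 s post-stimulus)
#' and baseline (-0.5-0 s) segments, averaged across trials, and the ratio
#' is read at the frequency bin containing the stimulation frequency.
#' Averaging PSDs before forming the ratio is the lower-variance estimator.
#'
#' @param epochs an `eeg_epochs` whose window covers -0.5 to 1 s; if it has
#'   per-trial `freq_hz`, only trials at `stim_freq_hz` are used.
#' @param stim_freq_hz stimulation frequency used to select trials (Hz).
#' @param window_s,overlap_s Welch parameters (defaults 0.5 and 0.25 s).
#' @param evoked_window,baseline_window analysis segments (s re stimulus).
#' @param analysis_freq_hz frequency at which the ratio is read (defaults to
#'   `stim_freq_hz`; set differently for an off-frequency control).
#' @return list: `ratio`, `stim_freq_hz`, `bin_hz`, `n_trials`,
#'   `evoked_power`, `baseline_power` (uV^2/Hz at the bin).
#' @export
assr_power_ratio <- function(epochs, stim_freq_hz, window_s = 0.5,
                             overlap_s = 0.25, evoked_window = c(0.2, 1),
                             baseline_window = c(-0.5, 0),
                             analysis_freq_hz = stim_freq_hz) {
  if (min(epochs$time) > baseline_window[1] || max(epochs$time) < evoked_window[2]) {
    stop("epoch window must cover ", baseline_window[1], " to ", evoked_window[2], " s")
  }
  fs <- epochs$fs
  if (analysis_freq_hz >= fs / 2 || analysis_freq_hz < 1 / window_s) {
    stop("stim_freq outside the resolvable frequency grid")
  }
  rows <- if (!is.null(epochs$freq_hz)) which(epochs$freq_hz == stim_freq_hz) else
    seq_len(nrow(epochs$data))
  if (!length(rows)) stop("no trials at ", stim_freq_hz, " Hz")
  esel <- epochs$time >= evoked_window[1] & epochs$time <= evoked_window[2]
  bsel <- epochs$time >= baseline_window[1] & epochs$time <= baseline_window[2]
  pe <- pb <- NULL
  for (i in rows) {
    se <- welch_psd(epochs$data[i, esel], fs, window_s, overlap_s)
    sb <- welch_psd(epochs$data[i, bsel], fs, window_s, overlap_s)
    if (is.null(pe)) { pe <- se$power; pb <- sb$power; fr <- se$freq }
    else { pe <- pe + se$power; pb <- pb + sb$power }
  }
  pe <- pe / length(rows)
  pb <- pb / length(rows)
  bin <- which.min(abs(fr - analysis_freq_hz))
  list(ratio = pe[bin] / pb[bin], stim_freq_hz = stim_freq_hz, bin_hz = fr[bin],
       n_trials = length(rows), evoked_power = pe[bin], baseline_power = pb[bin])
}

#' Trial-averaged event-related potentials per condition
#'
#' @param epochs an `eeg_epochs` (already baseline-corrected by
#'   [epoch_events()]).
#' @return object of class `erp`: list with `time` (s), `waveforms` (named
#'   list of mean waveforms per condition, uV), `n_trials` (named counts).
#' @export
erp_average <- function(epochs) {
  labs <- unique(epochs$labels)
  wf <- lapply(labs, function(l) colMeans(epochs$data[epochs$labels == l, , drop = FALSE]))
  names(wf) <- labs
  n <- vapply(labs, function(l) sum(epochs$labels == l), numeric(1))
  names(n) <- labs
  structure(list(time = epochs$time, waveforms = wf, n_trials = n), class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat("<erp> conditions:", paste(names(x$waveforms), "(n=", x$n_trials, ")",
                                 sep = "", collapse = ", "),
      "on", length(x$time), "samples\n")
  invisible(x)
}

#' Deviant-minus-standard difference waveform
#'
#' @param erp_standard,erp_deviant `erp` objects (single-condition) or bare
#'   numeric waveforms on the same time grid.
#' @param time time grid, required when passing bare vectors.
#' @return an `erp` with one waveform named "difference".
#' @export
erp_difference <- function(erp_standard, erp_deviant, time = NULL) {
  get1 <- function(e) {
    if (inherits(e, "erp")) {
      stopifnot(length(e$waveforms) == 1L)
      list(w = e$waveforms[[1]], t = e$time, n = e$n_trials[[1]])
    } else list(w = as.numeric(e), t = time, n = NA_real_)
  }
  s <- get1(erp_standard); d <- get1(erp_deviant)
  if (length(s$w) != length(d$w)) stop("waveform time grids differ in length")
  if (!is.null(s$t) && !is.null(d$t) && any(abs(s$t - d$t) > 1e-9)) {
    stop("waveform time grids differ")
  }
  structure(list(time = s$t, waveforms = list(difference = d$w - s$w),
                 n_trials = c(difference = min(s$n, d$n))), class = "erp")
}

#' Extract one condition from a multi-condition ERP
#' @param erp an `erp`.
#' @param condition condition name.
#' @return a single-condition `erp`.
#' @export
erp_condition <- function(erp, condition) {
  if (!condition %in% names(erp$waveforms)) stop("no condition '", condition, "'")
  structure(list(time = erp$time, waveforms = erp$waveforms[condition],
                 n_trials = erp$n_trials[condition]), class = "erp")
}

#' Locate P1, N1 and P3a peaks on an ERP waveform
#'
#' P1 is the maximum in its window; N1 the minimum in its window occurring
#' after the found P1 latency; P3a the maximum in its window after the found
#' N1 latency. A component is flagged absent when its extremum has the wrong
#' sign or sits on the boundary of its (possibly order-restricted) search
#' window, as happens for monotone segments with no interior extremum.
#'
#' @param erp a single-condition `erp`, or numeric waveform with `time`.
#' @param windows named list of search windows in ms (defaults: P1 10-50,
#'   N1 30-100, P3a 100-300).
#' @param time time grid in seconds for bare waveforms.
#' @return data.frame of class `erp_peaks`: `component`, `latency_ms`,
#'   `amplitude_uv`, `win_lo_ms`, `win_hi_ms`, `present`.
#' @export
find_erp_peaks <- function(erp, windows = list(P1 = c(10, 50), N1 = c(30, 100),
                                               P3a = c(100, 300)),
                           time = NULL) {
  if (inherits(erp, "erp")) {
    stopifnot(length(erp$waveforms) == 1L)
    w <- erp$waveforms[[1]]
    t_ms <- erp$time * 1000
  } else {
    w <- as.numeric(erp)
    if (is.null(time)) stop("`time` required with a bare waveform")
    t_ms <- time * 1000
  }
  if (max(t_ms) < max(vapply(windows, max, numeric(1)))) {
    stop("search windows extend past the epoch")
  }
  pick <- function(name, lo_ms, sign) {
    win <- windows[[name]]
    lo <- max(win[1], lo_ms)
    sel <- which(t_ms >= lo & t_ms <= win[2])
    if (length(sel) < 3) {
      return(data.frame(component = name, latency_ms = NA_real_,
                        amplitude_uv = NA_real_, win_lo_ms = win[1],
                        win_hi_ms = win[2], present = FALSE))
    }
    i <- if (sign > 0) sel[which.max(w[sel])] else sel[which.min(w[sel])]
    amp <- w[i]
    interior <- i != sel[1] && i != sel[length(sel)]
    present <- interior && (sign * amp > 0)
    data.frame(component = name, latency_ms = if (present) t_ms[i] else NA_real_,
               amplitude_uv = if (present) amp else NA_real_,
               win_lo_ms = win[1], win_hi_ms = win[2], present = present)
  }
  p1 <- pick("P1", -Inf, +1)
  n1 <- pick("N1", if (p1$present) p1$latency_ms else -Inf, -1)
  p3 <- pick("P3a", if (n1$present) n1$latency_ms else -Inf, +1)
  out <- rbind(p1, n1, p3)
  class(out) <- c("erp_peaks", "data.frame")
  out
}
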