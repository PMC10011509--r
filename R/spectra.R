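#' Canonical rodent EEG frequency bands
#'
#' slow 0.5-1, delta 1-4, theta 4-8, alpha 8-12, sigma 12-15, beta 15-30,
#' gamma 30-50 Hz.
#'
#' @return data.frame with columns `band`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("slow", "delta", "theta", "alpha", "sigma", "beta", "gamma"),
    low_hz = c(0.5, 1, 4, 8, 12, 15, 30),
    high_hz = c(1, 4, 8, 12, 15, 30, 50),
    stringsAsFactors = FALSE)
}

#' Welch power spectral density
#'
#' Hann-tapered, averaged segment periodograms. The one-sided density is
#' scaled so that its integral over frequency equals the signal variance
#' (Parseval); units are uV^2/Hz for uV inputs.
#'
#' @param x numeric samples.
#' @param fs sampling rate (Hz).
#' @param window_s segment length (s).
#' @param overlap_s segment overlap (s), `0 <= overlap_s < window_s`.
#' @param demean subtract the segment means before tapering (default TRUE).
#' @param taper "hann" (default) or "rect". With a rectangular taper and a
#'   single demeaned segment the integral of the density equals the sample
#'   variance exactly (discrete Parseval); the Hann taper trades that exact
#'   identity for leakage control.
#' @return object of class `eeg_spectrum`: list with `freq` (Hz), `power`
#'   (uV^2/Hz), `fs`, `window_s`, `overlap_s`, `n_segments`.
#' @export
welch_psd <- function(x, fs, window_s = 4, overlap_s = window_s / 2, demean = TRUE,
                      taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  nw <- round(window_s * fs)
  nov <- round(overlap_s * fs)
  if (length(x) < nw) stop("signal shorter than one Welch window")
  if (nov < 0 || nov >= nw) stop("overlap must satisfy 0 <= overlap < window")
  step <- nw - nov
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- if (taper == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  } else rep(1, nw)
  U <- sum(w^2)
  nfft <- nw
  nhalf <- nfft %/% 2 + 1L
  acc <- numeric(nhalf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(nhalf)]
    acc <- acc + (Mod(X)^2)
  }
  p <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist for even nfft)
  dbl <- rep(2, nhalf)
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nhalf] <- 1
  p <- p * dbl
  structure(list(freq = (seq_len(nhalf) - 1) * fs / nfft, power = p, fs = fs,
                 window_s = window_s, overlap_s = overlap_s,
                 n_segments = length(starts)),
            class = "eeg_spectrum")
}

#' @export
print.eeg_spectrum <- function(x, ...) {
  cat("<eeg_spectrum> ", length(x$freq), " bins, 0-", max(x$freq), " Hz, ",
      x$n_segments, " Welch segments (window ", x$window_s, " s, overlap ",
      x$overlap_s, " s)\n", sep = "")
  invisible(x)
}

#' Average several spectra on a common grid
#' @param spectra list of `eeg_spectrum` objects sharing one frequency grid.
#' @return an `eeg_spectrum` with the mean density.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1)
  f0 <- spectra[[1]]$freq
  for (s in spectra) {
    if (length(s$freq) != length(f0) || any(abs(s$freq - f0) > 1e-9)) {
      stop("spectra are not on a common frequency grid")
    }
  }
  out <- spectra[[1]]
  out$power <- rowMeans(vapply(spectra, function(s) s$power, numeric(length(f0))))
  out$n_segments <- sum(vapply(spectra, function(s) s$n_segments, numeric(1)))
  out
}

# integrate density over [low, high) by trapezoid with interpolated band edges
trapz_band <- function(freq, power, low, high) {
  f <- freq[freq > low & freq < high]
  p <- stats::approx(freq, power, xout = c(low, f, high))$y
  f <- c(low, f, high)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Absolute band power
#'
#' Trapezoidal integral of the power density over `[low_hz, high_hz)`, with
#' linear interpolation at the band edges.
#'
#' @param spectrum an `eeg_spectrum`.
#' @param low_hz,high_hz band edges (within the spectrum's range).
#' @return absolute power (uV^2).
#' @export
band_power <- function(spectrum, low_hz, high_hz) {
  if (!(low_hz < high_hz)) stop("empty band: low must be < high")
  if (low_hz < min(spectrum$freq) || high_hz > max(spectrum$freq)) {
    stop("band ", low_hz, "-", high_hz, " Hz outside spectrum range")
  }
  trapz_band(spectrum$freq, spectrum$power, low_hz, high_hz)
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the probability-normalized density over a frequency
#' range, divided by log of the bin count; 1 for a flat spectrum, 0 when all
#' power sits in one bin. Invariant to multiplicative rescaling.
#'
#' @param spectrum an `eeg_spectrum`.
#' @param f_range length-2 range in Hz (default 0.5-50).
#' @return entropy in \[0, 1\].
#' @export
spectral_entropy <- function(spectrum, f_range = c(0.5, 50)) {
  sel <- spectrum$freq >= f_range[1] & spectrum$freq <= f_range[2]
  p <- spectrum$power[sel]
  if (sum(sel) < 2) stop("need >= 2 bins in f_range")
  tot <- sum(p)
  if (tot <= 0) stop("all-zero power in f_range")
  p <- p / tot
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(length(p))
}

#' Aperiodic (1/f) parameterization of a power spectrum
#'
#' Fits the knee-free aperiodic model `log10 P(f) = b - chi * log10 f`
#' together with Gaussian oscillatory peaks, in the spirit of spectral
#' parameterization tools: (1) line fit in log-log space; (2) residual peaks
#' above `peak_threshold_sd` times the robustly estimated residual SD (taken
#' from the below-median residuals, so large peaks do not inflate their own
#' detection threshold) are fitted as Gaussians (largest first, up to
#' `max_peaks`) and subtracted; (3) the aperiodic line is refit on
#' peak-masked bins.
#'
#' @param spectrum an `eeg_spectrum` with positive power over the fit range.
#' @param fit_range length-2 frequency range in Hz (default 1-50).
#' @param max_peaks maximum number of peaks to fit (default 4).
#' @param peak_threshold_sd detection threshold in residual SDs (default 2).
#' @return object of class `aperiodic_fit`: list with `offset` (log10 uV^2/Hz),
#'   `exponent`, `peaks` (data.frame center_hz/height/sd_hz), `mse`
#'   (log10-power units), `fit_range`, `converged`.
#' @export
fit_aperiodic <- function(spectrum, fit_range = c(1, 50), max_peaks = 4,
                          peak_threshold_sd = 2) {
  sel <- spectrum$freq >= fit_range[1] & spectrum$freq <= fit_range[2]
  f <- spectrum$freq[sel]
  p <- spectrum$power[sel]
  if (length(f) < 5) stop("fit range covers too few bins")
  if (any(p <= 0)) stop("non-positive power inside the fit range")
  lf <- log10(f)
  lp <- log10(p)

  line_fit <- function(lf, lp) stats::lm.fit(cbind(1, lf), lp)$coefficients
  co <- line_fit(lf, lp)
  resid <- lp - (co[1] + co[2] * lf)

  peaks <- data.frame(center_hz = numeric(0), height = numeric(0), sd_hz = numeric(0))
  gauss <- function(f, c0, h, s) h * exp(-(f - c0)^2 / (2 * s^2))
  work <- resid
  converged <- TRUE
  for (k in seq_len(max_peaks)) {
    # robust residual scale: SD of the below-median residuals, so that large
    # peaks do not inflate their own detection threshold
    thr <- peak_threshold_sd * stats::sd(work[work <= stats::median(work)])
    i <- which.max(work)
    if (work[i] < thr || work[i] <= 0) break
    c0 <- f[i]; h0 <- work[i]
    # half-height width estimate, floored to one bin
    above <- work >= h0 / 2
    lo <- i; while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- i; while (hi < length(f) && above[hi + 1]) hi <- hi + 1
    s0 <- max((f[hi] - f[lo]) / 2.355, diff(f)[1] / 2)
    fit <- tryCatch(
      stats::optim(c(c0, h0, s0), function(th) {
        if (th[3] <= 0 || th[2] <= 0) return(1e6)
        sum((work - gauss(f, th[1], th[2], th[3]))^2)
      }, method = "Nelder-Mead", control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) { converged <- FALSE; break }
    th <- fit$par
    if (th[1] < fit_range[1] || th[1] > fit_range[2]) break
    peaks <- rbind(peaks, data.frame(center_hz = th[1], height = th[2], sd_hz = th[3]))
    work <- work - gauss(f, th[1], th[2], th[3])
  }

  mask <- rep(TRUE, length(f))
  if (nrow(peaks)) {
    for (j in seq_len(nrow(peaks))) {
      mask <- mask & abs(f - peaks$center_hz[j]) > 2 * peaks$sd_hz[j]
    }
  }
  if (sum(mask) < 3) mask <- rep(TRUE, length(f))
  co <- line_fit(lf[mask], lp[mask])
  model <- co[1] + co[2] * lf
  if (nrow(peaks)) {
    for (j in seq_len(nrow(peaks))) {
      model <- model + gauss(f, peaks$center_hz[j], peaks$height[j], peaks$sd_hz[j])
    }
  }
  structure(list(offset = unname(co[1]), exponent = unname(-co[2]), peaks = peaks,
                 mse = mean((lp - model)^2), fit_range = fit_range,
                 converged = converged),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat("<aperiodic_fit> offset=", signif(x$offset, 4), " exponent=",
      signif(x$exponent, 4), ", ", nrow(x$peaks), " peak(s), mse=",
      signif(x$mse, 3), "\n", sep = "")
  if (nrow(x$peaks)) {
    cat("  peaks at ", paste(signif(x$peaks$center_hz, 4), collapse = ", "),
        " Hz\n", sep = "")
  }
  invisible(x)
}

#' Tort phase-amplitude modulation index
#'
#' Phase is taken from the analytic signal of the `phase_band`-filtered
#' signal and amplitude from the envelope of the `amp_band`-filtered signal.
#' Mean amplitude per phase bin is normalized to a distribution P over
#' `n_bins` bins; MI = (log N - H(P)) / log N, i.e. the KL divergence from
#' uniform scaled to \[0, 1\].
#'
#' @param x numeric samples (>= 10 s recommended).
#' @param fs sampling rate.
#' @param phase_band length-2 Hz band providing phase (e.g. c(2, 6)).
#' @param amp_band length-2 Hz band providing amplitude (e.g. c(30, 50)).
#' @param n_bins number of phase bins (default 18).
#' @return modulation index in \[0, 1\].
#' @export
tort_mi <- function(x, fs, phase_band = c(2, 6), amp_band = c(30, 50), n_bins = 18) {
  if (length(x) < 10 * fs) warning("signal shorter than 10 s; MI may be unstable")
  ph <- Arg(analytic_signal(bandpass(x, phase_band[1], phase_band[2], fs = fs)))
  am <- Mod(analytic_signal(bandpass(x, amp_band[1], amp_band[2], fs = fs)))
  if (all(am == 0)) stop("zero amplitude envelope")
  bin <- pmin(floor((ph + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  m <- vapply(seq_len(n_bins), function(b) {
    if (any(bin == b)) mean(am[bin == b]) else 0
  }, numeric(1))
  mi_from_bins(m)
}

# MI of a binned mean-amplitude distribution: (log N - H(P)) / log N
mi_from_bins <- function(m) {
  P <- m / sum(m)
  nz <- P > 0
  H <- -sum(P[nz] * log(P[nz]))
  (log(length(m)) - H) / log(length(m))
}

#' Stage-averaged resting-state spectrum
#'
#' Per-epoch Welch spectra (window 4 s, overlap 2 s within each 10-s epoch by
#' default) averaged over all epochs of one sleep stage.
#'
#' @param eeg numeric EEG samples.
#' @param fs sampling rate.
#' @param hyp a `hypnogram` aligned to the signal.
#' @param stage stage label to average over ("NREM", "REM" or "WAKE").
#' @param window_s,overlap_s Welch parameters within each epoch.
#' @return an `eeg_spectrum`, or an error if the stage never occurs.
#' @export
stage_psd <- function(eeg, fs, hyp, stage = "NREM", window_s = 4, overlap_s = 2) {
  grid <- epoch_grid(length(eeg), hyp$epoch_len_s, fs = fs)
  keep <- which(hyp$stages[seq_len(nrow(grid))] == stage)
  if (!length(keep)) stop("no ", stage, " epochs in hypnogram")
  specs <- lapply(keep, function(k) {
    welch_psd(epoch_slice(eeg, grid, k - 1L), fs, window_s, overlap_s)
  })
  average_spectra(specs)
}
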