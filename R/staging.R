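#' Construct a hypnogram
#'
#' Per-epoch sleep-stage labels on a fixed epoch grid, with an optional
#' light-cycle mask.
#'
#' @param stages character vector of labels in WAKE/NREM/REM.
#' @param epoch_len_s epoch length (s), default 10.
#' @param light logical per-epoch light-cycle mask; default all TRUE.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len_s = 10, light = NULL) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("WAKE", "NREM", "REM"))
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  if (is.null(light)) light <- rep(TRUE, length(stages))
  if (length(light) != length(stages)) stop("light mask length must match stages")
  structure(list(stages = stages, epoch_len_s = epoch_len_s, light = light),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(factor(x$stages, levels = c("WAKE", "NREM", "REM")))
  cat("<hypnogram> ", length(x$stages), " x ", x$epoch_len_s, "-s epochs (",
      round(length(x$stages) * x$epoch_len_s / 3600, 2), " h): ",
      paste(names(tb), tb, sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Per-epoch staging features
#'
#' For every epoch of the grid: log band powers (delta 1-4, theta 4-8, sigma
#' 12-15, gamma 30-50 Hz), the theta/delta power ratio, EMG RMS and spectral
#' entropy (0.5-50 Hz). Epochs with (near) zero signal are flagged `bad` and
#' should be excluded downstream.
#'
#' @param eeg,emg numeric sample vectors covering the grid.
#' @param fs sampling rate.
#' @param epoch_len_s epoch length (default 10 s).
#' @param window_s,overlap_s Welch parameters within each epoch.
#' @return data.frame, one row per epoch: `epoch`, `log_delta`, `log_theta`,
#'   `log_sigma`, `log_gamma`, `theta_delta`, `emg_rms`, `entropy`, `bad`.
#' @export
epoch_features <- function(eeg, emg, fs, epoch_len_s = 10, window_s = 2,
                           overlap_s = 1) {
  grid <- epoch_grid(length(eeg), epoch_len_s, fs = fs)
  if (length(emg) < max(grid$end_sample)) stop("EMG does not cover the epoch grid")
  out <- lapply(seq_len(nrow(grid)), function(i) {
    xs <- eeg[(grid$start_sample[i] + 1L):grid$end_sample[i]]
    ms <- emg[(grid$start_sample[i] + 1L):grid$end_sample[i]]
    if (stats::sd(xs) < 1e-9) {
      return(data.frame(epoch = grid$epoch[i], log_delta = NA_real_,
                        log_theta = NA_real_, log_sigma = NA_real_,
                        log_gamma = NA_real_, theta_delta = NA_real_,
                        emg_rms = sqrt(mean(ms^2)), entropy = NA_real_, bad = TRUE))
    }
    sp <- welch_psd(xs, fs, window_s, overlap_s)
    bp <- function(lo, hi) band_power(sp, lo, hi)
    de <- bp(1, 4); th <- bp(4, 8); si <- bp(12, 15); ga <- bp(30, 50)
    data.frame(epoch = grid$epoch[i], log_delta = log10(de), log_theta = log10(th),
               log_sigma = log10(si), log_gamma = log10(ga),
               theta_delta = th / de, emg_rms = sqrt(mean(ms^2)),
               entropy = spectral_entropy(sp, c(0.5, min(50, fs / 2 - 1))),
               bad = FALSE)
  })
  do.call(rbind, out)
}

# deterministic 2-means split of a vector; returns the two cluster centers
# and their midpoint (initialized at the 25th/75th percentiles)
bimodal_threshold <- function(x, iter = 50) {
  c1 <- stats::quantile(x, 0.25, names = FALSE)
  c2 <- stats::quantile(x, 0.75, names = FALSE)
  for (i in seq_len(iter)) {
    lab <- abs(x - c1) <= abs(x - c2)
    if (!any(lab) || all(lab)) break
    n1 <- mean(x[lab]); n2 <- mean(x[!lab])
    if (n1 == c1 && n2 == c2) break
    c1 <- n1; c2 <- n2
  }
  list(threshold = (c1 + c2) / 2, lo = min(c1, c2), hi = max(c1, c2))
}

#' Classify sleep stages from epoch features
#'
#' Transparent rule cascade with per-recording adaptive thresholds:
#' (1) epochs whose EMG RMS exceeds the WAKE threshold are WAKE; (2) among
#' the remaining (sleep) epochs, those with theta/delta ratio above
#' `theta_delta_thr` and sigma power below the sleep-epoch median are REM;
#' (3) the rest are NREM. A 3-epoch majority smoother removes isolated
#' flips, and REM immediately following WAKE is relabeled WAKE (REM onset
#' from wake does not occur in healthy rodents).
#'
#' The default WAKE threshold is the midpoint of a two-means split of log
#' EMG RMS, which adapts to any wake/sleep ratio;
#' `threshold_method = "quantile"` uses the EMG 60th percentile instead.
#' When the two EMG clusters differ by less than a factor of 2 in RMS the
#' distribution is treated as unimodal -- the animal shows no EMG evidence
#' of sleep -- and every epoch is labeled WAKE (the conservative call, since
#' sustained atonia without bimodality indicates an electrode problem
#' rather than sleep).
#'
#' @param features output of [epoch_features()].
#' @param theta_delta_thr REM theta/delta threshold (default 1.5).
#' @param threshold_method "bimodal" (default) or "quantile".
#' @param emg_quantile quantile for `threshold_method = "quantile"`.
#' @param epoch_len_s epoch length of the output hypnogram.
#' @return a `hypnogram`. Bad epochs are labeled WAKE (conservative).
#' @export
classify_stages <- function(features, theta_delta_thr = 1.5,
                            threshold_method = c("bimodal", "quantile"),
                            emg_quantile = 0.6, epoch_len_s = 10) {
  threshold_method <- match.arg(threshold_method)
  if (nrow(features) < 60) stop("need >= 60 epochs for adaptive thresholds")
  ok <- !features$bad
  if (stats::sd(features$emg_rms[ok]) < 1e-12) {
    stop("degenerate features: EMG RMS has no variance")
  }
  lemg <- log(pmax(features$emg_rms, 1e-12))
  if (threshold_method == "bimodal") {
    bt <- bimodal_threshold(lemg[ok])
    thr <- if (bt$hi - bt$lo < log(2)) -Inf else bt$threshold
  } else {
    thr <- stats::quantile(lemg[ok], emg_quantile, names = FALSE)
  }
  wake <- lemg > thr
  stage <- rep("WAKE", nrow(features))
  sleep <- ok & !wake
  if (any(sleep)) {
    sig_med <- stats::median(features$log_sigma[sleep])
    rem <- sleep & features$theta_delta > theta_delta_thr &
      features$log_sigma < sig_med
    stage[sleep] <- ifelse(rem[sleep], "REM", "NREM")
  }
  stage[!ok] <- "WAKE"

  # 3-epoch majority smoother: an epoch flanked by two agreeing neighbours
  # of a different stage takes their label
  n <- length(stage)
  if (n >= 3) {
    sm <- stage
    mid <- 2:(n - 1)
    flip <- stage[mid - 1] == stage[mid + 1] & stage[mid] != stage[mid - 1]
    sm[mid][flip] <- stage[mid - 1][flip]
    stage <- sm
  }
  prev <- c(NA, stage[-n])
  stage[which(stage == "REM" & prev == "WAKE")] <- "WAKE"
  hypnogram(stage, epoch_len_s = epoch_len_s)
}

#' Sleep metrics over a light-cycle window
#'
#' Stage percentages, the sleep-onset score (% of epochs asleep, NREM or
#' REM, in the first hour of the window), per-stage bout counts and mean
#' bout lengths, and fragmentation (stage transitions per hour).
#'
#' @param hyp a `hypnogram`.
#' @param window_s length-2 window in seconds from session start; default
#'   the first 12 h (clipped to the session).
#' @return list of class `sleep_metrics`.
#' @export
sleep_metrics <- function(hyp, window_s = NULL) {
  total_s <- length(hyp$stages) * hyp$epoch_len_s
  if (is.null(window_s)) window_s <- c(0, min(total_s, 12 * 3600))
  if (window_s[2] > total_s || window_s[1] < 0 || window_s[1] >= window_s[2]) {
    stop("window outside session")
  }
  e0 <- floor(window_s[1] / hyp$epoch_len_s) + 1L
  e1 <- floor((window_s[2] - 1e-9) / hyp$epoch_len_s) + 1L
  st <- hyp$stages[e0:e1]
  if (!length(st)) stop("empty window")
  n <- length(st)
  pct <- function(s) 100 * sum(st == s) / n

  n_first <- min(n, as.integer(round(3600 / hyp$epoch_len_s)))
  first <- st[seq_len(n_first)]
  onset_score <- 100 * sum(first %in% c("NREM", "REM")) / n_first

  r <- rle(st)
  bouts <- lapply(c("WAKE", "NREM", "REM"), function(s) {
    len <- r$lengths[r$values == s] * hyp$epoch_len_s
    list(count = length(len), mean_s = if (length(len)) mean(len) else NA_real_)
  })
  names(bouts) <- c("WAKE", "NREM", "REM")
  hours <- n * hyp$epoch_len_s / 3600
  structure(list(
    pct_wake = pct("WAKE"), pct_nrem = pct("NREM"), pct_rem = pct("REM"),
    sleep_onset_score = onset_score, bouts = bouts,
    transitions_per_h = (length(r$lengths) - 1L) / hours,
    window_s = window_s), class = "sleep_metrics")
}

#' @export
print.sleep_metrics <- function(x, ...) {
  cat("<sleep_metrics> %WAKE=", round(x$pct_wake, 1), " %NREM=",
      round(x$pct_nrem, 1), " %REM=", round(x$pct_rem, 1),
      " | sleep-onset score=", round(x$sleep_onset_score, 1),
      " | transitions/h=", round(x$transitions_per_h, 1), "\n", sep = "")
  for (s in names(x$bouts)) {
    cat("  ", s, ": ", x$bouts[[s]]$count, " bouts, mean ",
        round(x$bouts[[s]]$mean_s, 1), " s\n", sep = "")
  }
  invisible(x)
}

#' Epoch-wise agreement between two hypnograms
#' @param hyp,truth hypnograms on the same grid.
#' @return fraction of epochs with matching labels.
#' @export
staging_accuracy <- function(hyp, truth) {
  n <- min(length(hyp$stages), length(truth$stages))
  mean(hyp$stages[seq_len(n)] == truth$stages[seq_len(n)])
}
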