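#' Construct an EEG/EMG recording
#'
#' Container for a multichannel polysomnography recording held in memory.
#' Channels are stored in physical units (microvolts) at a common sampling
#' rate. Metadata carries the subject identity and group labels used by the
#' group-statistics stage.
#'
#' @param channels named list of equal-length numeric vectors (uV).
#' @param fs sampling rate in Hz (> 0).
#' @param start_time POSIXct start of the recording (default: epoch origin).
#' @param meta list of session metadata; recognised fields are `subject`,
#'   `genotype` and `age`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(channels, fs, start_time = as.POSIXct("2000-01-01", tz = "UTC"),
                      meta = list()) {
  if (!is.list(channels) || length(channels) < 1L || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of numeric vectors")
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("channels must have equal length; got ", paste(lens, collapse = ", "))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be a positive scalar")
  for (nm in names(channels)) {
    if (anyNA(channels[[nm]])) stop("channel '", nm, "' contains NA samples")
    channels[[nm]] <- as.numeric(channels[[nm]])
  }
  structure(list(channels = channels, fs = fs, start_time = start_time, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat("<eeg_recording> ", length(x$channels), " channel(s) [",
      paste(names(x$channels), collapse = ", "), "], ",
      n, " samples @ ", x$fs, " Hz (", round(n / x$fs, 1), " s)\n", sep = "")
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return scalar seconds.
#' @export
rec_duration <- function(rec) length(rec$channels[[1]]) / rec$fs

# --- EDF (European Data Format) I/O ----------------------------------------
#
# 16-bit EDF with one-second data records.  Header layout per the EDF
# specification: 256-byte fixed header + 256 bytes per signal, then
# little-endian int16 data records.  Physical scaling is stored per channel.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over each channel's physical range and
#' written as one-second data records. A trailing partial second, if any, is
#' dropped with a warning (EDF stores whole records only).
#'
#' @param rec an `eeg_recording`; sampling rate must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- length(rec$channels)
  n <- length(rec$channels[[1]])
  n_rec <- n %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (n %% fs != 0) warning("dropping trailing partial second (", n %% fs, " samples)")

  phys_min <- phys_max <- numeric(ns)
  phys_str <- character(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]][seq_len(n_rec * fs)]
    # round the physical range up to 3 significant digits so that the 8-char
    # ASCII header field represents it exactly (no rescaling error on read)
    r <- max(abs(x), 1e-3)
    e <- 10^(floor(log10(r)) - 2)
    r <- ceiling(r / e) * e
    s <- formatC(r, format = "f", digits = max(0, -floor(log10(e))))
    if (nchar(s) > 7) s <- formatC(r, format = "g", digits = 4)
    phys_str[i] <- s
    r <- as.numeric(s)
    phys_min[i] <- -r
    phys_max[i] <- r
    gain <- (phys_max[i] - phys_min[i]) / 65535
    dig[[i]] <- as.integer(round((x - phys_min[i]) / gain) - 32768)
  }

  meta <- rec$meta
  patient <- if (!is.null(meta$subject)) meta$subject else "X"
  recinfo <- paste0("genotype=", if (!is.null(meta$genotype)) meta$genotype else "NA",
                    " age=", if (!is.null(meta$age)) meta$age else "NA")
  st <- as.POSIXlt(rec$start_time, tz = "UTC")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr(patient, 80); wr(recinfo, 80)
  wr(format(st, "%d.%m.%y"), 8); wr(format(st, "%H.%M.%S"), 8)
  wr(256 + 256 * ns, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (nm in names(rec$channels)) wr(nm, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(paste0("-", phys_str[i]), 8)
  for (i in seq_len(ns)) wr(phys_str[i], 8)
  for (i in seq_len(ns)) wr(-32768, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  # interleave records without an R-level per-record loop
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)    # samples x records
  out <- matrix(0L, nrow = fs * ns, ncol = n_rec)
  for (i in seq_len(ns)) {
    out[(i - 1L) * fs + seq_len(fs), ] <- matrix(dig[[i]][idx], nrow = fs)
  }
  writeBin(as.vector(out), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Samples are rescaled to physical units using the per-channel header
#' scaling; the sampling rate is taken from the header (samples per record /
#' record duration). Group metadata written by [write_edf()] is recovered
#' from the recording-identification field.
#'
#' @param path EDF file path.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (sz < 256) stop("EDF format error: file shorter than the 256-byte header")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); patient <- rd(80); recinfo <- rd(80); dt <- rd(8); tm <- rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF format error: header declares no signals")
  if (is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0) {
    stop("EDF format error: bad record count/duration fields")
  }
  if (sz < 256 + 256 * ns) stop("EDF format error: truncated signal header")
  labs <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                       # transducer
  for (i in seq_len(ns)) rd(8)                        # dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)                       # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr))) stop("EDF format error: corrupt signal header")
  expected <- hdr_bytes + 2 * n_rec * sum(spr)
  if (sz < expected) {
    stop("EDF format error: file truncated (", sz, " bytes, expected ", expected, ")")
  }
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * sum(spr)) stop("EDF format error: short data section")

  offs <- c(0L, cumsum(spr))
  rec_stride <- sum(spr)
  channels <- vector("list", ns)
  names(channels) <- labs
  for (i in seq_len(ns)) {
    pick <- as.vector(outer(offs[i] + seq_len(spr[i]),
                            (seq_len(n_rec) - 1L) * rec_stride, `+`))
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    channels[[i]] <- (raw[pick] - dmin[i]) * gain + pmin[i]
    if (anyNA(channels[[i]])) stop("EDF format error: NA samples in channel '", labs[i], "'")
  }

  meta <- list(subject = patient)
  kv <- regmatches(recinfo, gregexpr("[A-Za-z0-9_]+=[^ ]+", recinfo))[[1]]
  for (p in kv) {
    k <- sub("=.*", "", p); v <- sub(".*=", "", p)
    if (v != "NA") meta[[k]] <- v
  }
  start <- as.POSIXct(paste(dt, tm), format = "%d.%m.%y %H.%M.%S", tz = "UTC")
  if (is.na(start)) start <- as.POSIXct("2000-01-01", tz = "UTC")
  recording(channels, fs = spr[1] / rec_dur, start_time = start, meta = meta)
}

# --- events and hypnogram files --------------------------------------------

#' Read/write stimulus event tables
#'
#' Tab-delimited with columns `onset_s`, `label` and optional `freq_hz`.
#' Onsets must be sorted ascending.
#'
#' @param events data.frame with columns `onset_s`, `label`, optionally `freq_hz`.
#' @param path file path.
#' @return `read_events` returns the event data.frame; `write_events` the path.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events), all(c("onset_s", "label") %in% names(events)))
  if (is.unsorted(events$onset_s)) stop("event onsets must be sorted ascending")
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(ev))) {
    stop("event file must have columns onset_s, label: ", path)
  }
  if (is.unsorted(ev$onset_s)) stop("event onsets not sorted in ", path)
  ev
}

#' Read/write hypnograms as tab-delimited text
#'
#' Columns `epoch_index` (0-based) and `stage` (WAKE/NREM/REM).
#'
#' @param hyp a `hypnogram` (see [hypnogram()]).
#' @param path file path.
#' @return `read_hypnogram` returns a `hypnogram`; `write_hypnogram` the path.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.table(
    data.frame(epoch_index = seq_along(hyp$stages) - 1L, stage = hyp$stages),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @param epoch_len_s epoch length of the stored hypnogram (s).
#' @export
read_hypnogram <- function(path, epoch_len_s = 10) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  hypnogram(d$stage[order(d$epoch_index)], epoch_len_s = epoch_len_s)
}

# --- filtering and epoch grid ----------------------------------------------

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase). When the low
#' edge is at or above 0.5 Hz the channel mean is removed first, so DC cannot
#' leak through filter start-up transients.
#'
#' @param x numeric vector of samples, or an `eeg_recording`.
#' @param low_hz,high_hz band edges, 0 < low < high < fs/2.
#' @param fs sampling rate (ignored when `x` is a recording).
#' @param channel channel name when `x` is a recording.
#' @param order filter order (default 4).
#' @return filtered samples, same length as the input.
#' @export
bandpass <- function(x, low_hz, high_hz, fs = NULL, channel = NULL, order = 4) {
  if (inherits(x, "eeg_recording")) {
    if (is.null(channel)) channel <- names(x$channels)[1]
    fs <- x$fs
    x <- x$channels[[channel]]
    if (is.null(x)) stop("no channel named '", channel, "'")
  }
  if (is.null(fs)) stop("`fs` required when filtering a bare vector")
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2 (got ", low_hz, "-", high_hz,
         " Hz at fs=", fs, ")")
  }
  if (low_hz >= 0.5) x <- x - mean(x)
  b <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Fixed-length epoch grid over a recording
#'
#' Contiguous, non-overlapping, half-open sample intervals in the 0-based
#' convention: epoch k covers samples `[k*L*fs, (k+1)*L*fs)`. A trailing
#' partial epoch is dropped.
#'
#' @param x an `eeg_recording` or total sample count.
#' @param epoch_len_s epoch length in seconds.
#' @param fs sampling rate when `x` is a sample count.
#' @return data.frame with `epoch` (0-based), `start_sample`, `end_sample`
#'   (half-open, 0-based).
#' @export
epoch_grid <- function(x, epoch_len_s, fs = NULL) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    n <- length(x$channels[[1]])
  } else {
    n <- as.numeric(x)
    if (is.null(fs)) stop("`fs` required with a bare sample count")
  }
  if (epoch_len_s <= 0) stop("epoch_len_s must be > 0")
  spe <- round(epoch_len_s * fs)
  k <- n %/% spe
  data.frame(epoch = seq_len(k) - 1L,
             start_sample = (seq_len(k) - 1L) * spe,
             end_sample = seq_len(k) * spe)
}

#' Extract the samples of one grid epoch
#' @param x numeric sample vector.
#' @param grid output of [epoch_grid()].
#' @param k 0-based epoch index.
#' @return numeric vector of the epoch's samples.
#' @export
epoch_slice <- function(x, grid, k) {
  row <- grid[grid$epoch == k, ]
  if (nrow(row) != 1L) stop("epoch ", k, " not on grid")
  x[(row$start_sample + 1L):row$end_sample]
}

# Analytic signal via FFT: X(f) doubled on positive frequencies, zeroed on
# negative ones. Used for envelopes (Mod) and instantaneous phase (Arg).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
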