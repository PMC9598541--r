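# Jerk-locked back-averaging of EEG on EMG onsets, EMG onset detection and
# inter-discharge interval statistics.

#' Construct a polygraphic recording
#'
#' Multichannel EEG + EMG time series at a common sampling rate, in
#' microvolts. EMG channels are recognised by a channel type vector or, by
#' default, by labels starting with `"EMG"`.
#'
#' @param data Numeric matrix, samples x channels, with unique column
#'   names (channel labels), values in microvolts.
#' @param sfreq Sampling rate in Hz (> 0).
#' @param channel_types Optional character vector (`"eeg"`/`"emg"`), one
#'   per channel.
#' @param montage Montage tag: `"referential"`, `"common_average"` or
#'   `"bipolar"`.
#' @return An object of class `polygraphic_recording`.
#' @export
polygraphic_recording <- function(data, sfreq, channel_types = NULL,
                                  montage = c("referential", "common_average",
                                              "bipolar")) {
  montage <- match.arg(montage)
  if (!is.matrix(data) || is.null(colnames(data))) {
    abort_cst("cst_format_error", "data must be a matrix with channel names")
  }
  if (anyDuplicated(colnames(data))) {
    abort_cst("cst_format_error", "channel labels must be unique")
  }
  if (length(sfreq) != 1L || !is.finite(sfreq) || sfreq <= 0) {
    abort_cst("cst_argument_error", "sfreq must be a positive number")
  }
  if (is.null(channel_types)) {
    channel_types <- ifelse(grepl("^EMG", colnames(data), ignore.case = TRUE),
                            "emg", "eeg")
  }
  if (length(channel_types) != ncol(data)) {
    abort_cst("cst_argument_error", "one channel type per channel required")
  }
  structure(list(data = data, sfreq = sfreq,
                 channel_types = channel_types, montage = montage),
            class = "polygraphic_recording")
}

#' @export
print.polygraphic_recording <- function(x, ...) {
  cat(sprintf("<polygraphic_recording> %d ch (%d EEG, %d EMG), %.6g s at %g Hz, %s montage\n",
              ncol(x$data), sum(x$channel_types == "eeg"),
              sum(x$channel_types == "emg"),
              nrow(x$data) / x$sfreq, x$sfreq, x$montage))
  invisible(x)
}

rec_times <- function(rec) (seq_len(nrow(rec$data)) - 1) / rec$sfreq

#' Re-reference EEG channels to the common average
#'
#' Subtracts the instantaneous mean over all EEG channels from each EEG
#' channel; EMG channels are untouched. After re-referencing the mean over
#' EEG channels is zero at every sample.
#'
#' @param rec A [polygraphic_recording()].
#' @return The recording with montage `"common_average"`.
#' @export
common_average <- function(rec) {
  eeg <- rec$channel_types == "eeg"
  if (!any(eeg)) abort_cst("cst_argument_error", "recording has no EEG channels")
  rec$data[, eeg] <- rec$data[, eeg, drop = FALSE] -
    rowMeans(rec$data[, eeg, drop = FALSE])
  rec$montage <- "common_average"
  rec
}

#' Write / read a polygraphic recording as TSV
#'
#' Plain TSV time-series interchange: first column `time_s`, remaining
#' columns one channel each (microvolts), header row of labels. The
#' sampling rate is recovered from the time column on read.
#'
#' @param rec A [polygraphic_recording()].
#' @param path File path.
#' @return `path` (write) or a `polygraphic_recording` (read).
#' @export
write_polygraphy_tsv <- function(rec, path) {
  df <- data.frame(time_s = rec_times(rec), rec$data, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_polygraphy_tsv
#' @export
read_polygraphy_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "time_s") {
    abort_cst("cst_format_error", "first column must be time_s")
  }
  dt <- diff(df$time_s)
  if (!length(dt) || any(dt <= 0)) {
    abort_cst("cst_format_error", "time column must be strictly increasing")
  }
  polygraphic_recording(as.matrix(df[, -1, drop = FALSE]),
                        sfreq = 1 / stats::median(dt))
}

# Centered moving average with edge padding.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  na <- is.na(sm)
  sm[na] <- x[na]
  sm
}

# Refine one burst onset by fitting the smoothed rectified envelope with a
# folded-normal hinge: m(t) = sqrt(baseline^2 + (k * max(0, t - t0))^2).
# The baseline term models the rectified noise floor, so the fit is
# unbiased for ramp-like ("diamond") burst envelopes; t0 is located by a
# grid search over samples with parabolic interpolation of the residual
# sum of squares.
refine_onset_hinge <- function(sm, ipk, med, fs) {
  pk <- sm[ipk]
  win <- max(1L, ipk - round(0.25 * fs)):ipk
  below <- sm[win] <= med + 0.85 * (pk - med)
  win <- win[below | seq_along(win) < length(win) / 2]
  if (length(win) < 8L) return(NA_real_)
  y <- sm[win]
  t <- (win - 1) / fs
  cand <- t[3:(length(t) - 3)]
  if (length(cand) < 3L) return(NA_real_)
  rss <- vapply(cand, function(t0) {
    z <- pmax(0, t - t0)
    stats::optimize(function(k) sum((y - sqrt(med^2 + (k * z)^2))^2),
                    c(1, 5e4))$objective
  }, numeric(1))
  j <- which.min(rss)
  if (j > 1L && j < length(cand)) {
    dt <- cand[2] - cand[1]
    den <- rss[j - 1] - 2 * rss[j] + rss[j + 1]
    cand[j] + if (is.finite(den) && den > 0) {
      max(min(0.5 * dt * (rss[j - 1] - rss[j + 1]) / den, dt), -dt)
    } else 0
  } else {
    cand[j]
  }
}

#' Detect EMG burst onsets
#'
#' High-passes the EMG channel, rectifies it, smooths with a short double
#' moving average and thresholds at `baseline median + k * MAD`. Events
#' must stay above threshold for at least `min_duration_s` and are
#' separated by a refractory period. Each onset is then refined by fitting
#' the rising envelope with a folded-normal hinge model
#' `sqrt(baseline^2 + (slope * max(0, t - t0))^2)`, which accounts for the
#' rectified noise floor and is unbiased for ramp-like ("diamond") burst
#' envelopes; if the rise is too fast to be resolved by the smoother
#' (e.g. rectangular bursts), the first raw supra-threshold sample is used
#' instead.
#'
#' A flat EMG yields an empty result, not an error.
#'
#' @param rec A [polygraphic_recording()].
#' @param channel EMG channel label.
#' @param highpass High-pass corner frequency in Hz (default 20; 0
#'   disables filtering).
#' @param k Threshold multiplier on the MAD (default 5).
#' @param refractory_s Minimum separation between onsets in seconds
#'   (default 0.5).
#' @param min_duration_s Minimum supra-threshold duration in seconds
#'   (default 0.03).
#' @param smooth_s Moving-average width in seconds (default 0.013, applied
#'   twice).
#' @param refine Apply hinge-model onset refinement (default TRUE).
#' @return Strictly increasing numeric vector of onset times in seconds.
#' @export
detect_emg_onsets <- function(rec, channel, highpass = 20, k = 5,
                              refractory_s = 0.5, min_duration_s = 0.03,
                              smooth_s = 0.013, refine = TRUE) {
  if (!channel %in% colnames(rec$data)) {
    abort_cst("cst_argument_error", sprintf("no channel named '%s'", channel))
  }
  fs <- rec$sfreq
  x <- rec$data[, channel]
  if (!all(is.finite(x))) {
    abort_cst("cst_format_error", "EMG channel contains non-finite values")
  }
  if (highpass > 0 && highpass < fs / 2) {
    bf <- signal::butter(4, highpass / (fs / 2), type = "high")
    x <- signal::filtfilt(bf, x)
  }
  r <- abs(x)
  w <- max(1L, round(smooth_s * fs))
  sm <- moving_average(moving_average(r, w), w)
  med <- stats::median(sm)
  madv <- stats::mad(sm)
  thr <- med + k * madv
  above <- sm > thr
  if (!any(above)) return(numeric(0))
  # Runs of supra-threshold samples.
  rle_a <- rle(above)
  ends <- cumsum(rle_a$lengths)
  starts <- ends - rle_a$lengths + 1L
  keep <- rle_a$values & rle_a$lengths >= max(1L, round(min_duration_s * fs))
  starts <- starts[keep]
  ends <- ends[keep]
  if (!length(starts)) return(numeric(0))

  onset_idx <- numeric(length(starts))
  for (q in seq_along(starts)) {
    s0 <- starts[q]
    # First raw supra-threshold sample near the run start.
    lo_search <- max(1L, s0 - 2L * w)
    raw_hit <- which(r[lo_search:ends[q]] > thr)
    crude <- if (length(raw_hit)) lo_search + raw_hit[1] - 1L else s0
    onset_idx[q] <- crude
    if (!refine) next
    # Local peak of the smoothed envelope after the run start.
    hi_search <- min(length(sm), s0 + round(0.4 * fs))
    ipk <- s0 - 1L + which.max(sm[s0:hi_search])
    pk <- sm[ipk]
    rise10 <- med + 0.1 * (pk - med)
    # Walk back from the peak to where the envelope was below 10% of peak.
    i <- ipk
    while (i > 1L && sm[i] > rise10 && ipk - i < round(0.5 * fs)) i <- i - 1L
    rise_span <- (ipk - i) / fs
    if (rise_span <= 3 * w / fs) next   # rise not resolved; keep raw crossing
    t0 <- refine_onset_hinge(sm, ipk, med, fs)
    if (!is.finite(t0)) next
    t0 <- min(max(t0, (s0 - 1L) / fs - 0.1), (ipk - 1L) / fs)
    onset_idx[q] <- t0 * fs + 1
  }
  onsets <- (onset_idx - 1) / fs
  onsets <- sort(onsets)
  # Refractory: greedy, keep the first of any pair closer than refractory_s.
  kept <- numeric(0)
  last <- -Inf
  for (t in onsets) {
    if (t - last >= refractory_s) {
      kept <- c(kept, t)
      last <- t
    }
  }
  kept
}

#' Jerk-locked back-average of EEG
#'
#' Averages EEG epochs time-locked to EMG jerk onsets. EEG is
#' re-referenced to the common average first (configurable), each epoch is
#' baseline-corrected by the mean of its pre-event segment, and epochs
#' whose window falls outside the recording are dropped. The per-channel
#' peak is the signed extremum of largest magnitude inside the pre-motor
#' search window, and its latency (ms, negative = EEG precedes EMG) is the
#' time of that extremum.
#'
#' @param rec A [polygraphic_recording()].
#' @param onsets Numeric vector of event times in seconds (e.g. from
#'   [detect_emg_onsets()]).
#' @param window_s Epoch window relative to onset, seconds (default
#'   `c(-0.5, 0.5)`).
#' @param baseline_s Baseline window for per-epoch subtraction (default
#'   `c(-0.5, -0.3)`).
#' @param peak_window_s Peak search window (default `c(-0.2, 0)`).
#' @param reref `"common_average"` (default) or `"none"`.
#' @return An object of class `jerk_locked_average`: `average` (time x
#'   channel matrix, microvolts), `times_ms`, `n_events`, `peaks` (data
#'   frame with `channel`, `peak_uV`, `latency_ms`), `window_s`,
#'   `montage`.
#' @export
back_average <- function(rec, onsets, window_s = c(-0.5, 0.5),
                         baseline_s = c(-0.5, -0.3),
                         peak_window_s = c(-0.2, 0),
                         reref = c("common_average", "none")) {
  reref <- match.arg(reref)
  if (!length(onsets)) {
    abort_cst("cst_insufficient_events", "no events to average")
  }
  if (reref == "common_average") rec <- common_average(rec)
  eeg <- rec$channel_types == "eeg"
  dat <- rec$data[, eeg, drop = FALSE]
  fs <- rec$sfreq
  rel <- seq(round(window_s[1] * fs), round(window_s[2] * fs))
  times_ms <- rel / fs * 1000
  bl_sel <- times_ms >= baseline_s[1] * 1000 & times_ms <= baseline_s[2] * 1000
  acc <- matrix(0, length(rel), ncol(dat))
  n_used <- 0L
  for (t0 in onsets) {
    i0 <- round(t0 * fs) + 1L
    idx <- i0 + rel
    if (idx[1] < 1L || idx[length(idx)] > nrow(dat)) next
    seg <- dat[idx, , drop = FALSE]
    bl <- colMeans(seg[bl_sel, , drop = FALSE])
    acc <- acc + sweep(seg, 2L, bl)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    abort_cst("cst_insufficient_events",
              "no event has a full epoch window inside the recording")
  }
  avg <- acc / n_used
  colnames(avg) <- colnames(dat)
  pk_sel <- which(times_ms >= peak_window_s[1] * 1000 &
                    times_ms <= peak_window_s[2] * 1000)
  peaks <- data.frame(channel = colnames(dat),
                      peak_uV = NA_real_, latency_ms = NA_real_,
                      stringsAsFactors = FALSE)
  for (j in seq_len(ncol(avg))) {
    jj <- pk_sel[which.max(abs(avg[pk_sel, j]))]
    peaks$peak_uV[j] <- avg[jj, j]
    peaks$latency_ms[j] <- times_ms[jj]
  }
  structure(list(average = avg, times_ms = times_ms, n_events = n_used,
                 peaks = peaks, window_s = window_s, montage = rec$montage),
            class = "jerk_locked_average")
}

#' @export
print.jerk_locked_average <- function(x, ...) {
  top <- x$peaks[which.max(abs(x$peaks$peak_uV)), ]
  cat(sprintf("<jerk_locked_average> %d events, %d channels; largest peak %.3g uV at %.3g ms on %s\n",
              x$n_events, ncol(x$average), top$peak_uV, top$latency_ms,
              top$channel))
  invisible(x)
}

#' Peak absolute amplitude over a channel subset
#'
#' @param jla A [back_average()] result.
#' @param channels Channel labels to consider (default: all).
#' @return Largest absolute per-channel peak amplitude, microvolts.
#' @export
peak_amplitude <- function(jla, channels = NULL) {
  pk <- jla$peaks
  if (!is.null(channels)) {
    miss <- setdiff(channels, pk$channel)
    if (length(miss)) {
      abort_cst("cst_argument_error",
                sprintf("unknown channel(s): %s", paste(miss, collapse = ", ")))
    }
    pk <- pk[pk$channel %in% channels, , drop = FALSE]
  }
  max(abs(pk$peak_uV))
}

#' Write a jerk-locked average to TSV + JSON
#'
#' @param jla A [back_average()] result.
#' @param matrix_path Output TSV for the channel x time average (first
#'   column `time_ms`).
#' @param summary_path Output JSON with `n_events` and per-channel peak
#'   amplitudes and latencies.
#' @return `matrix_path`, invisibly.
#' @export
write_back_average <- function(jla, matrix_path, summary_path = NULL) {
  df <- data.frame(time_ms = jla$times_ms, jla$average, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(list(n_events = jla$n_events, montage = jla$montage,
                              peaks = jla$peaks),
                         summary_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(matrix_path)
}

#' Inter-discharge interval statistics
#'
#' Successive differences of periodic-complex onset times with summary
#' statistics (median, IQR, min, max in seconds).
#'
#' @param onsets Numeric vector of at least two onset times in seconds.
#' @return List of class `interval_summary` with `intervals`, `n`,
#'   `median`, `iqr`, `min`, `max`.
#' @export
interdischarge_intervals <- function(onsets) {
  if (length(onsets) < 2L) {
    abort_cst("cst_insufficient_events", "need at least 2 onsets")
  }
  d <- diff(sort(onsets))
  structure(list(intervals = d, n = length(d),
                 median = stats::median(d), iqr = stats::IQR(d),
                 min = min(d), max = max(d)),
            class = "interval_summary")
}

#' @export
print.interval_summary <- function(x, ...) {
  cat(sprintf("<interval_summary> %d intervals: median %.3g s (IQR %.3g), range %.3g-%.3g s\n",
              x$n, x$median, x$iqr, x$min, x$max))
  invisible(x)
}
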