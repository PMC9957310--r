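#' Per-window spectral and amplitude features of an EMG recording
#'
#' Splits a (band-passed) recording into non-overlapping windows from
#' shift start (default 10 min), and computes for each: percentiles of
#' the rectified amplitude (p10/p50/p90 of `|x|`), mean and median power
#' frequency over the 20--450 Hz band (Welch estimate, 1-s Hann segments,
#' 50% overlap), total band power, the window mid-time in work minutes,
#' and an `in_break` flag. Windows with less than `min_fraction` of their
#' nominal samples are dropped; windows with no usable spectral content
#' (zero band power) get `NA` frequencies and are pre-flagged anomalous.
#'
#' @param recording an `emg_recording` (band-pass it first with
#'   [emg_bandpass()]).
#' @param schedule a [shift_schedule()] (for break flags and work time).
#' @param window_minutes analysis window length in minutes.
#' @param min_fraction minimum fraction of nominal samples for a window
#'   to be emitted (the final partial window is the usual case).
#' @param band numeric `c(low, high)` analysis band in Hz.
#' @return data.frame with columns `subject_id`, `side`, `window_index`,
#'   `t_start` (seconds of day), `t_mid` (minutes of work time at window
#'   centre), `in_break`, `amp_p10`, `amp_p50`, `amp_p90`, `mnf`, `mdf`,
#'   `total_power`, `anomalous`.
#' @export
emg_window_features <- function(recording, schedule,
                                window_minutes = 10, min_fraction = 0.5,
                                band = c(20, 450)) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$sampling_rate
  wlen <- as.integer(round(window_minutes * 60 * fs))
  n <- length(recording$samples)
  if (n < wlen * min_fraction) {
    warning("recording shorter than one minimum window; no features",
            call. = FALSE)
    return(empty_features())
  }
  starts <- seq(1L, n, by = wlen)
  rows <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    s <- starts[j]
    e <- min(n, s + wlen - 1L)
    if ((e - s + 1L) < wlen * min_fraction) next
    x <- recording$samples[s:e]
    t_start <- recording$start_time + (s - 1L) / fs
    t_end <- recording$start_time + e / fs
    ax <- abs(x)
    qs <- stats::quantile(ax, c(0.1, 0.5, 0.9), names = FALSE)
    tp <- NA_real_; mdf <- NA_real_; mnf <- NA_real_; bad <- FALSE
    if (length(x) >= fs && stats::sd(x) > 0) {
      psd <- welch_psd(x, fs)
      bp <- band_select(psd, band[1], band[2])
      tp <- sum(bp$power) * (psd$freq[2] - psd$freq[1])  # band power (mV^2)
      if (tp > 0) {
        mdf <- median_power_frequency(psd, band[1], band[2])
        mnf <- mean_power_frequency(psd, band[1], band[2])
      } else bad <- TRUE
    } else {
      tp <- 0; bad <- TRUE
    }
    rows[[j]] <- data.frame(
      subject_id = recording$subject_id, side = recording$side,
      window_index = j, t_start = t_start,
      t_mid = work_minutes_elapsed((t_start + t_end) / 2, schedule),
      in_break = mean(in_break(seq(t_start, t_end - 1), schedule)) > 0.5,
      amp_p10 = qs[1], amp_p50 = qs[2], amp_p90 = qs[3],
      mnf = mnf, mdf = mdf, total_power = tp, anomalous = bad,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_features())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_features <- function() {
  data.frame(subject_id = character(), side = character(),
             window_index = integer(), t_start = numeric(),
             t_mid = numeric(), in_break = logical(),
             amp_p10 = numeric(), amp_p50 = numeric(),
             amp_p90 = numeric(), mnf = numeric(), mdf = numeric(),
             total_power = numeric(), anomalous = logical(),
             stringsAsFactors = FALSE)
}
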