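#' Simulate bilateral trapezius surface EMG for one subject
#'
#' Generates a 1000-Hz band-limited Gaussian signal in 1-second blocks.
#' Each block's power spectral density is a Butterworth band-pass envelope
#' (4th order) of width `truth$emg_band_width` centred at the programmed
#' median power frequency
#' `intercept(side, subject) + slope(subject) * work-minutes elapsed`,
#' synthesized in the frequency domain (independent complex-Gaussian
#' coefficients shaped by the envelope), so the spectral centre drifts
#' linearly over work time and is frozen during the break. With
#' `truth$emg_stochastic = FALSE` a deterministic constant-amplitude,
#' phase-continuous tone tracking the programmed centre is produced
#' instead (the zero-noise limit).
#'
#' If `truth$emg_contam_windows > 0`, that many 10-minute windows per
#' recording are contaminated, alternating hard amplitude clipping with
#' large in-band sinusoidal interference plus low-frequency drift; the
#' affected window indices are stored in
#' `attr(recording, "contaminated_windows")` as ground truth for
#' anomaly-screen testing.
#'
#' @inheritParams simulate_heart_rate
#' @param sides which sides to generate (default both).
#' @return list with elements `left` and `right` (or the requested
#'   subset), each an [emg_recording()] covering
#'   `[shift_start, shift_end)`.
#' @export
simulate_emg <- function(subject, schedule, truth, seed = NULL,
                         sides = c("left", "right")) {
  sid <- as.character(subject$subject_id)
  seed <- seed %||% derive_seed(truth$seed, "emg", sid)
  out <- list()
  for (side in sides) {
    out[[side]] <- simulate_emg_side(
      sid, side,
      intercept = truth$emg_intercept[sid, side],
      slope = truth$emg_slope[[sid]],
      schedule = schedule, truth = truth,
      seed = derive_seed(seed, side))
  }
  out
}

#' Construct an EMG recording object
#'
#' @param subject_id identifier.
#' @param side `"left"` or `"right"`.
#' @param samples numeric amplitude vector (mV).
#' @param sampling_rate Hz (nominal 1000; must exceed 900 Hz so the
#'   20--450 Hz analysis band is below Nyquist).
#' @param start_time seconds of day of the first sample.
#' @return object of class `emg_recording`.
#' @export
emg_recording <- function(subject_id, side, samples, sampling_rate = 1000,
                          start_time = 0) {
  if (sampling_rate <= 2 * 450)
    stop_param("sampling_rate must exceed 900 Hz (Nyquist for the 20-450 Hz band)")
  if (!all(is.finite(samples))) stop_param("EMG samples must be finite")
  structure(list(subject_id = as.character(subject_id), side = side,
                 sampling_rate = sampling_rate, start_time = start_time,
                 samples = as.numeric(samples)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: subject %s %s, %d samples @ %g Hz from %s (%.1f min)\n",
              x$subject_id, x$side, length(x$samples), x$sampling_rate,
              seconds_to_clock(x$start_time),
              length(x$samples) / x$sampling_rate / 60))
  invisible(x)
}

# Squared magnitude of an analog Butterworth band-pass prototype.
butter_bandpass_mag2 <- function(f, low, high, order = 4) {
  f0sq <- low * high
  bw <- high - low
  r <- ifelse(f > 0, (f^2 - f0sq) / (bw * f), Inf)
  1 / (1 + r^(2 * order))
}

simulate_emg_side <- function(subject_id, side, intercept, slope,
                              schedule, truth, seed) {
  fs <- 1000L
  n_sec <- as.integer(schedule$shift_end - schedule$shift_start)
  block_mid <- schedule$shift_start + seq_len(n_sec) - 0.5
  centre <- intercept + slope * work_minutes_elapsed(block_mid, schedule)
  w <- truth$emg_band_width
  if (any(centre - w / 2 <= 20) || any(centre + w / 2 >= 450))
    stop_param("programmed EMG spectrum leaves the (20, 450) Hz band; ",
               "reduce |slope|, the band width, or move the intercept")
  rms <- truth$emg_amp_rms
  x <- if (isTRUE(truth$emg_stochastic)) {
    with_seed(seed, synth_gauss_blocks(centre, w, rms, fs))
  } else {
    # phase-continuous tone at the drifting centre frequency
    phase <- 2 * pi * cumsum(rep(centre / fs, each = fs))
    sqrt(2) * rms * sin(phase)
  }
  rec <- emg_recording(subject_id, side, x, fs, schedule$shift_start)
  if (truth$emg_contam_windows > 0) {
    rec <- with_seed(derive_seed(seed, "contam"),
                     inject_contamination(rec, truth$emg_contam_windows, rms))
  }
  rec
}

# Block-wise frequency-domain synthesis: per 1-s block, complex-Gaussian
# Fourier coefficients shaped by the Butterworth envelope centred at
# centre[b]; inverse FFT gives a real Gaussian signal with the target PSD
# and RMS. Processed in chunks to bound memory.
synth_gauss_blocks <- function(centre, width, rms, fs = 1000L,
                               chunk = 1800L) {
  nb <- length(centre)
  out <- numeric(nb * fs)
  nfreq <- fs %/% 2L            # positive-frequency bins 1..nfreq-1 + Nyquist
  freqs <- seq_len(nfreq - 1L)  # 1..499 Hz at 1-s blocks
  for (s in seq(1L, nb, by = chunk)) {
    e <- min(nb, s + chunk - 1L)
    m <- e - s + 1L
    # envelope: (nfreq-1) x m
    A <- sqrt(butter_bandpass_mag2(
      matrix(freqs, nfreq - 1L, m),
      rep(centre[s:e] - width / 2, each = nfreq - 1L),
      rep(centre[s:e] + width / 2, each = nfreq - 1L)))
    # scale each block so the time-domain variance is rms^2
    scale <- rms / sqrt(2 * colSums(A^2) / fs^2)
    A <- A * rep(scale, each = nfreq - 1L)
    Z <- (matrix(stats::rnorm((nfreq - 1L) * m), nfreq - 1L, m) +
          1i * matrix(stats::rnorm((nfreq - 1L) * m), nfreq - 1L, m)) / sqrt(2)
    X <- matrix(0 + 0i, fs, m)
    X[freqs + 1L, ] <- A * Z
    X[fs + 1L - freqs, ] <- Conj(A * Z)
    out[((s - 1L) * fs + 1L):(e * fs)] <- Re(stats::mvfft(X, inverse = TRUE)) / fs
  }
  out
}

inject_contamination <- function(rec, n_windows, rms) {
  fs <- rec$sampling_rate
  wlen <- 600L * fs
  n_avail <- length(rec$samples) %/% wlen
  n_windows <- min(n_windows, n_avail)
  idx <- sort(sample(seq_len(n_avail), n_windows))
  x <- rec$samples
  for (j in seq_along(idx)) {
    rng <- ((idx[j] - 1L) * wlen + 1L):(idx[j] * wlen)
    if (j %% 2L == 1L) {
      # hard clipping: electrode saturation
      x[rng] <- pmin(pmax(x[rng], -0.5 * rms), 0.5 * rms)
    } else {
      # strap/cable interference: strong in-band tone + sub-band drift
      tt <- seq_along(rng) / fs
      x[rng] <- x[rng] + 5 * rms * sin(2 * pi * 30 * tt) +
        10 * rms * sin(2 * pi * 2 * tt)
    }
  }
  rec$samples <- x
  attr(rec, "contaminated_windows") <- idx
  rec
}
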