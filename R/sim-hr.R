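#' Simulate a 1-Hz heart-rate series for one subject
#'
#' The noiseless profile is piecewise constant: the subject's sitting
#' baseline before the shift, `baseline + hr_gain * exertion(bout)` during
#' each work bout, and `baseline + hr_gain * exertion(T2)` during the
#' break (light recovery activity). Gaussian noise and, optionally,
#' isolated spike artifacts (the kind a moving-median filter must remove)
#' are added on top.
#'
#' @param subject one roster row (data.frame or list with `subject_id`).
#' @param schedule a [shift_schedule()].
#' @param truth a [ground_truth()].
#' @param seed optional integer; defaults to a stream derived from
#'   `truth$seed` and the subject id.
#' @return an `hr_series` object: list with `subject_id`, `time` (seconds
#'   of day, 1-Hz, covering the pre-shift window through shift end) and
#'   `bpm`.
#' @export
simulate_heart_rate <- function(subject, schedule, truth, seed = NULL) {
  sid <- as.character(subject$subject_id)
  seed <- seed %||% derive_seed(truth$seed, "hr", sid)
  time <- seq(schedule$hr_windows$T0[1], schedule$shift_end - 1)
  e <- truth$exertion[sid, ]
  base <- truth$hr_baseline[[sid]]
  prof <- rep(base, length(time))
  work1 <- time >= schedule$shift_start & time < schedule$break_start
  brk   <- in_break(time, schedule)
  work2 <- time >= schedule$break_end & time < schedule$shift_end
  prof[work1] <- base + truth$hr_gain * e[["T1"]]
  prof[brk]   <- base + truth$hr_gain * e[["T2"]]
  prof[work2] <- base + truth$hr_gain * e[["T3"]]
  with_seed(seed, {
    bpm <- prof + stats::rnorm(length(time), 0, truth$hr_noise_sd)
    if (truth$hr_spike_rate > 0) {
      hit <- stats::runif(length(time)) < truth$hr_spike_rate
      # single-sample dropouts/doubling artifacts typical of chest-strap HR
      bpm[hit] <- bpm[hit] + sample(c(-40, 60, 90), sum(hit), replace = TRUE)
    }
    structure(list(subject_id = sid, time = time, bpm = bpm),
              class = "hr_series")
  })
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("1-Hz heart-rate series: subject %s, %d samples [%s, %s], mean %.1f bpm\n",
              x$subject_id, length(x$time),
              seconds_to_clock(min(x$time)), seconds_to_clock(max(x$time)),
              mean(x$bpm)))
  invisible(x)
}
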