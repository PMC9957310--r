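#' Shift schedule for a field measurement day
#'
#' Encodes the work-shift structure a cohort follows: shift start and end,
#' one mid-shift break, the four survey timepoints T0--T3, and the
#' heart-rate averaging windows aligned to them. Times are represented
#' internally as seconds of day; all windows are half-open `[start, end)`.
#'
#' The default timing follows the study design the package targets: work
#' from 7:30 to 15:00 with a single break starting at 9:00 (i.e. after 90
#' minutes of work). Two break presets ship because field protocols differ:
#' `"rest30"` (30-minute rest, the default) and `"fullbreak"` (break until
#' 10:30). Survey timepoints are
#' \describe{
#'   \item{T0}{before the shift, during a 15-min quiet-sitting heart-rate
#'     measurement;}
#'   \item{T1}{at the start of the break, i.e. after the first work bout;
#'     its heart-rate window is the last 10 min of work before the break;}
#'   \item{T2}{at the end of the break; its heart-rate window is the last
#'     10 min of the break (rested state);}
#'   \item{T3}{at the end of the shift; heart-rate window is the last
#'     10 min of work.}
#' }
#'
#' @param shift_start,shift_end,break_start,break_end clock times
#'   (`"HH:MM"` strings or seconds of day).
#' @param preset one of `"rest30"`, `"fullbreak"`, `"demo"`; supplies
#'   defaults for any time not given explicitly. `"demo"` is a compressed
#'   85-minute day (40-min bout, 15-min break, 30-min bout) for fast
#'   end-to-end runs.
#' @return an object of class `shift_schedule`: a list with numeric fields
#'   `shift_start`, `shift_end`, `break_start`, `break_end`, a named list
#'   `survey_times` (T0--T3, seconds of day) and a named list `hr_windows`
#'   (T0--T3, each `c(start, end)` in seconds of day; durations 15, 10, 10
#'   and 10 minutes).
#' @examples
#' sch <- shift_schedule()
#' seconds_to_clock(sch$break_end)
#' @export
shift_schedule <- function(shift_start = NULL, shift_end = NULL,
                           break_start = NULL, break_end = NULL,
                           preset = c("rest30", "fullbreak", "demo")) {
  preset <- match.arg(preset)
  def <- switch(preset,
    rest30    = list(ss = "7:30", se = "15:00", bs = "9:00", be = "9:30"),
    fullbreak = list(ss = "7:30", se = "15:00", bs = "9:00", be = "10:30"),
    demo      = list(ss = "7:30", se = "8:55",  bs = "8:10", be = "8:25"))
  ss <- clock_to_seconds(shift_start %||% def$ss)
  se <- clock_to_seconds(shift_end   %||% def$se)
  bs <- clock_to_seconds(break_start %||% def$bs)
  be <- clock_to_seconds(break_end   %||% def$be)
  if (!(ss < bs && bs < be && be < se))
    stop_param("schedule must satisfy shift_start < break_start < break_end < shift_end")
  if (bs - ss < 600 || se - be < 600 || be - bs < 600)
    stop_param("work bouts and break must each last at least 10 minutes")
  sch <- structure(list(
    shift_start = ss, shift_end = se,
    break_start = bs, break_end = be,
    survey_times = list(T0 = ss - 900, T1 = bs, T2 = be, T3 = se),
    hr_windows = list(
      T0 = c(ss - 900, ss),
      T1 = c(bs - 600, bs),
      T2 = c(be - 600, be),
      T3 = c(se - 600, se))
  ), class = "shift_schedule")
  sch
}

#' @export
print.shift_schedule <- function(x, ...) {
  cat("Shift schedule\n")
  cat(sprintf("  shift %s - %s, break %s - %s\n",
              seconds_to_clock(x$shift_start), seconds_to_clock(x$shift_end),
              seconds_to_clock(x$break_start), seconds_to_clock(x$break_end)))
  for (tp in names(x$hr_windows)) {
    w <- x$hr_windows[[tp]]
    cat(sprintf("  %s: survey %s, HR window [%s, %s)\n", tp,
                seconds_to_clock(x$survey_times[[tp]]),
                seconds_to_clock(w[1]), seconds_to_clock(w[2])))
  }
  invisible(x)
}

#' Is a second-of-day time inside the break?
#' @param t numeric seconds of day.
#' @param schedule a [shift_schedule()].
#' @return logical vector.
#' @export
in_break <- function(t, schedule) {
  t >= schedule$break_start & t < schedule$break_end
}

#' Work minutes elapsed at a given time of day
#'
#' Minutes of actual work accumulated since shift start; the clock pauses
#' during the break. This is the time regressor of the fatigue-slope model.
#'
#' @inheritParams in_break
#' @return numeric vector of minutes.
#' @export
work_minutes_elapsed <- function(t, schedule) {
  s <- pmax(pmin(t, schedule$shift_end), schedule$shift_start) - schedule$shift_start
  # subtract the elapsed portion of the break
  binto <- pmax(0, pmin(t, schedule$break_end) - schedule$break_start)
  binto[t < schedule$break_start] <- 0
  (s - binto) / 60
}

#' Total scheduled work minutes of a shift (break excluded)
#' @param schedule a [shift_schedule()].
#' @return numeric scalar, minutes.
#' @export
total_work_minutes <- function(schedule) {
  (schedule$shift_end - schedule$shift_start -
     (schedule$break_end - schedule$break_start)) / 60
}
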