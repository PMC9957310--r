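#' Moving-median filter for heart-rate cleaning
#'
#' Replaces each sample by the median of a centred window (default 5
#' points), the standard artifact-rejection step for 1-Hz chest-strap
#' heart rate. At the series edges the window shrinks symmetrically to
#' the samples available (staying centred and odd; no padding, so no data
#' are invented at recording boundaries); length is preserved and the
#' filter stays idempotent on monotone stretches.
#'
#' @param x an `hr_series` object (from [simulate_heart_rate()] or
#'   [read_hr_csv()]) or a plain numeric vector.
#' @param window odd positive integer window length.
#' @return same type as `x`, with filtered values.
#' @examples
#' moving_median_filter(c(60, 60, 200, 60, 60))  # spike removed
#' @export
moving_median_filter <- function(x, window = 5L) {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2 == 0)
    stop_param("window must be an odd positive integer")
  if (inherits(x, "hr_series")) {
    x$bpm <- moving_median_filter(x$bpm, window)
    return(x)
  }
  n <- length(x)
  if (window == 1L || n == 0L) return(x)
  h <- (window - 1L) %/% 2L
  shrunk <- function(i) {
    hh <- min(h, i - 1L, n - i)  # symmetric odd window at the edges
    stats::median(x[(i - hh):(i + hh)])
  }
  if (n <= window)
    return(vapply(seq_len(n), shrunk, numeric(1)))
  out <- as.numeric(stats::runmed(x, window, endrule = "keep"))
  for (i in c(seq_len(h), seq(n - h + 1L, n))) out[i] <- shrunk(i)
  out
}

#' Mean heart rate over a schedule-aligned window
#'
#' Arithmetic mean of samples with `start <= time < end`, with a coverage
#' fraction (samples present over samples expected at the nominal 1-Hz
#' spacing). Results with coverage below `min_coverage` are flagged, not
#' dropped.
#'
#' @param series an `hr_series`.
#' @param window numeric `c(start, end)` in seconds of day (half-open).
#' @param min_coverage minimum acceptable coverage fraction.
#' @return list with `mean_bpm`, `coverage`, `n`, `low_coverage` flag.
#' @export
period_mean <- function(series, window, min_coverage = 0.5) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  keep <- series$time >= window[1] & series$time < window[2]
  n <- sum(keep)
  if (n == 0L)
    stop("no heart-rate samples in window [",
         seconds_to_clock(window[1]), ", ", seconds_to_clock(window[2]),
         ")", call. = FALSE)
  expected <- window[2] - window[1]
  cov <- n / expected
  list(mean_bpm = mean(series$bpm[keep]), coverage = cov, n = n,
       low_coverage = cov < min_coverage)
}

#' Percent heart-rate reserve for one subject-period
#'
#' Evaluates the standard age-predicted formulas: maximal heart rate
#' `HRmax = 220 - age`, resting heart rate approximated from pre-shift
#' quiet sitting as `HRrest = HRsit - 10`, and
#' `%HRR = (HRwork - HRrest) / (HRmax - HRrest)`. Values outside `[0, 1]`
#' are returned as-is with `out_of_range = TRUE` (never clipped); the
#' square root is reported when `%HRR >= 0`.
#'
#' @param hr_work mean working heart rate (bpm).
#' @param hr_sit mean pre-shift sitting heart rate (bpm).
#' @param age age in years.
#' @return list with `hr_rest`, `hr_max`, `hrr`, `hrr_sqrt`,
#'   `out_of_range`.
#' @examples
#' compute_hrr(130, 70, 20)$hrr  # (130 - 60) / (200 - 60) = 0.5
#' @export
compute_hrr <- function(hr_work, hr_sit, age) {
  hr_rest <- hr_sit - 10
  hr_max <- 220 - age
  if (hr_max <= hr_rest)
    stop("degenerate heart-rate reserve: HRmax (", hr_max,
         ") <= HRrest (", hr_rest, ")", call. = FALSE)
  hrr <- (hr_work - hr_rest) / (hr_max - hr_rest)
  list(hr_rest = hr_rest, hr_max = hr_max, hrr = hrr,
       hrr_sqrt = if (hrr >= 0) sqrt(hrr) else NA_real_,
       out_of_range = hrr < 0 || hrr > 1)
}

#' Square-root normalizing transform with normality diagnostics
#'
#' Applies the element-wise square root used to bring right-skewed
#' percent-heart-rate-reserve values towards normality, and reports
#' Shapiro-Wilk statistics before and after so the choice is auditable.
#' Negative inputs are excluded from the transform (their count is
#' reported); with fewer than 3 usable values the transform is still
#' returned but the tests are `NA`.
#'
#' @param values numeric vector (percent heart-rate reserve fractions).
#' @return list with `transformed`, `n_excluded_negative`, `shapiro_before`
#'   and `shapiro_after` (each a list with `statistic` and `p_value`).
#' @export
sqrt_transform_with_normality <- function(values) {
  neg <- !is.na(values) & values < 0
  use <- values[!neg & !is.na(values)]
  sw <- function(x) {
    if (length(x) < 3L || length(unique(x)) < 3L || length(x) > 5000L)
      return(list(statistic = NA_real_, p_value = NA_real_))
    t <- stats::shapiro.test(x)
    list(statistic = unname(t$statistic), p_value = t$p.value)
  }
  list(transformed = sqrt(use),
       n_excluded_negative = sum(neg),
       shapiro_before = sw(use),
       shapiro_after = sw(sqrt(use)))
}

#' Percent heart-rate reserve table for a set of subjects
#'
#' Runs the full heart-rate branch for each subject: 5-point moving-median
#' cleaning, schedule-aligned period means (T0 sitting; T1--T3 work/rest
#' windows), and the reserve formulas.
#'
#' @param hr_list named list of `hr_series`, one per subject id.
#' @param roster data.frame with `subject_id`, `age`, `group`.
#' @param schedule a [shift_schedule()].
#' @param filter_window moving-median window (odd integer).
#' @param min_coverage coverage threshold passed to [period_mean()].
#' @return data.frame with one row per subject x period (T1--T3):
#'   `subject_id`, `group`, `period`, `hr_work`, `hr_sit`, `hr_rest`,
#'   `hr_max`, `hrr`, `hrr_sqrt`, `coverage`, `low_coverage`,
#'   `out_of_range`.
#' @export
hrr_table <- function(hr_list, roster, schedule, filter_window = 5L,
                      min_coverage = 0.5) {
  rows <- list()
  for (i in seq_len(nrow(roster))) {
    sid <- roster$subject_id[i]
    ser <- hr_list[[sid]]
    if (is.null(ser)) next
    filt <- moving_median_filter(ser, filter_window)
    sit <- period_mean(filt, schedule$hr_windows$T0, min_coverage)
    for (tp in c("T1", "T2", "T3")) {
      pm <- period_mean(filt, schedule$hr_windows[[tp]], min_coverage)
      h <- compute_hrr(pm$mean_bpm, sit$mean_bpm, roster$age[i])
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, group = roster$group[i], period = tp,
        hr_work = pm$mean_bpm, hr_sit = sit$mean_bpm,
        hr_rest = h$hr_rest, hr_max = h$hr_max,
        hrr = h$hrr, hrr_sqrt = h$hrr_sqrt,
        coverage = pm$coverage,
        low_coverage = pm$low_coverage || sit$low_coverage,
        out_of_range = h$out_of_range,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
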