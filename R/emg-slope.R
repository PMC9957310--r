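#' Fatigue slope of the median power frequency for one subject-side
#'
#' Ordinary least-squares fit of the per-window spectral fatigue metric
#' on work time, `MPF = b0 + bTime * time`: a negative slope (Hz per
#' work-minute) indicates progressive spectral compression, the direct
#' electromyographic sign of localized muscle fatigue. Break windows and
#' windows flagged anomalous are excluded; at least 3 usable windows are
#' required, otherwise a missing-result row is returned.
#'
#' @param features data.frame from [emg_window_features()] for a single
#'   subject-side (after [detect_anomalous_windows()]).
#' @param metric `"mdf"` (median power frequency, default) or `"mnf"`.
#' @param exclude_break drop in-break windows (default `TRUE`).
#' @return one-row data.frame: `subject_id`, `side`, `b0` (Hz), `b_time`
#'   (Hz/min), `stderr`, `r_squared`, `n_windows`.
#' @export
fit_fatigue_slope <- function(features, metric = c("mdf", "mnf"),
                              exclude_break = TRUE) {
  metric <- match.arg(metric)
  sid <- unique(features$subject_id)
  side <- unique(features$side)
  if (length(sid) > 1L || length(side) > 1L)
    stop_param("fit_fatigue_slope expects a single subject-side; ",
               "use pooled_slope_model() or fit_all_slopes() across them")
  use <- features[!features$anomalous &
                  (!exclude_break | !features$in_break) &
                  is.finite(features[[metric]]), , drop = FALSE]
  miss <- data.frame(subject_id = sid %||% NA_character_,
                     side = side %||% NA_character_,
                     b0 = NA_real_, b_time = NA_real_, stderr = NA_real_,
                     r_squared = NA_real_, n_windows = nrow(use),
                     stringsAsFactors = FALSE)
  if (nrow(use) < 3L || stats::var(use$t_mid) == 0) return(miss)
  fit <- stats::lm(use[[metric]] ~ use$t_mid)
  sm <- summary(fit)
  data.frame(subject_id = sid, side = side,
             b0 = unname(stats::coef(fit)[1]),
             b_time = unname(stats::coef(fit)[2]),
             stderr = sm$coefficients[2, 2],
             r_squared = sm$r.squared,
             n_windows = nrow(use), stringsAsFactors = FALSE)
}

#' Fatigue slopes for every subject-side in a feature table
#'
#' @param features data.frame of window features covering any number of
#'   subject-sides.
#' @inheritParams fit_fatigue_slope
#' @return data.frame with one row per subject-side (see
#'   [fit_fatigue_slope()]).
#' @export
fit_all_slopes <- function(features, metric = c("mdf", "mnf"),
                           exclude_break = TRUE) {
  metric <- match.arg(metric)
  key <- interaction(features$subject_id, features$side, drop = TRUE)
  out <- do.call(rbind, lapply(split(features, key), fit_fatigue_slope,
                               metric = metric,
                               exclude_break = exclude_break))
  rownames(out) <- NULL
  out
}

#' Pooled fatigue-slope model adjusted for side and subject
#'
#' Fixed-effects linear model `MPF ~ time + side + subject` over all
#' non-break, non-anomalous windows: per-subject intercepts absorb
#' between-worker spectral differences and the side term absorbs the
#' bilateral (dominant vs non-dominant) offset, so the time coefficient
#' is the pooled fatigue slope. Aliased terms (e.g. a single subject or
#' side) are dropped by the usual least-squares pivoting with a warning.
#'
#' @inheritParams fit_all_slopes
#' @return object of class `pooled_slope_model`: list with `b_time`,
#'   `stderr`, `p_value`, `n_windows`, `n_subjects`, the underlying `lm`
#'   fit (`fit`), and `slopes` (per-subject-side OLS slopes from
#'   [fit_all_slopes()], the quantities used in association analyses).
#' @export
pooled_slope_model <- function(features, metric = c("mdf", "mnf"),
                               exclude_break = TRUE) {
  metric <- match.arg(metric)
  use <- features[!features$anomalous &
                  (!exclude_break | !features$in_break) &
                  is.finite(features[[metric]]), , drop = FALSE]
  if (length(unique(use$subject_id)) < 2L)
    warning("pooled model fitted with < 2 subjects; subject adjustment ",
            "is aliased", call. = FALSE)
  dat <- data.frame(y = use[[metric]], t_mid = use$t_mid,
                    side = factor(use$side),
                    subject = factor(use$subject_id))
  terms <- c("t_mid",
             if (nlevels(dat$side) > 1L) "side",
             if (nlevels(dat$subject) > 1L) "subject")
  fit <- stats::lm(stats::reformulate(terms, "y"), data = dat)
  if (any(is.na(stats::coef(fit))))
    warning("rank-deficient pooled model: aliased terms dropped",
            call. = FALSE)
  sm <- summary(fit)$coefficients
  structure(list(
    b_time = sm["t_mid", 1], stderr = sm["t_mid", 2],
    p_value = sm["t_mid", 4],
    n_windows = nrow(dat),
    n_subjects = nlevels(dat$subject),
    fit = fit,
    slopes = fit_all_slopes(features, metric = metric,
                            exclude_break = exclude_break)),
    class = "pooled_slope_model")
}

#' @export
print.pooled_slope_model <- function(x, ...) {
  cat(sprintf(
    "Pooled MPF fatigue slope (side- and subject-adjusted):\n  b_time = %.4f Hz/min (SE %.4f, p = %.3g), %d windows, %d subjects\n",
    x$b_time, x$stderr, x$p_value, x$n_windows, x$n_subjects))
  invisible(x)
}

#' @export
coef.pooled_slope_model <- function(object, ...) stats::coef(object$fit)
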