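#' Validate a raw survey-response table
#'
#' Checks required columns, scale ranges (Borg RPE 6--20; Omni RPE 0--10;
#' Borg CR10 0--10, half steps tolerated), body-site conventions (overall
#' for the RPE scales, a shoulder for CR10) and duplicate
#' (subject, timepoint, scale, site) keys. Rejected rows are returned
#' with reasons rather than silently dropped.
#'
#' @param raw data.frame with columns `subject_id`, `timepoint`, `scale`,
#'   `body_site`, `value`.
#' @param ranges named list overriding the numeric range per scale.
#' @return list with `responses` (accepted rows) and `rejected` (rows
#'   plus a `reason` column).
#' @export
validate_responses <- function(raw,
                               ranges = list(BorgRPE = c(6, 20),
                                             OmniRPE = c(0, 10),
                                             BorgCR10 = c(0, 10))) {
  req <- c("subject_id", "timepoint", "scale", "body_site", "value")
  if (!all(req %in% names(raw)))
    stop("survey table lacks required column(s): ",
         paste(setdiff(req, names(raw)), collapse = ", "), call. = FALSE)
  raw <- raw[, req]
  reason <- rep(NA_character_, nrow(raw))
  bad_tp <- !(raw$timepoint %in% c("T0", "T1", "T2", "T3"))
  reason[bad_tp] <- "unknown timepoint"
  bad_scale <- !(raw$scale %in% names(ranges))
  reason[bad_scale & is.na(reason)] <- "unknown scale"
  for (sc in names(ranges)) {
    i <- raw$scale == sc & is.na(reason)
    oob <- i & (is.na(raw$value) | raw$value < ranges[[sc]][1] |
                  raw$value > ranges[[sc]][2])
    reason[oob] <- "value out of range"
  }
  wrong_site <- is.na(reason) &
    ((raw$scale %in% c("BorgRPE", "OmniRPE") & raw$body_site != "overall") |
     (raw$scale == "BorgCR10" &
        !(raw$body_site %in% c("left_shoulder", "right_shoulder"))))
  reason[wrong_site] <- "body_site inconsistent with scale"
  key <- paste(raw$subject_id, raw$timepoint, raw$scale, raw$body_site)
  dup <- duplicated(key) & is.na(reason)
  reason[dup] <- "duplicate response"
  keep <- is.na(reason)
  list(responses = raw[keep, , drop = FALSE],
       rejected = cbind(raw[!keep, , drop = FALSE],
                        reason = reason[!keep]))
}

#' Baseline deltas of survey ratings
#'
#' Codes each rating at T1--T3 as the change from the same subject's
#' pre-shift (T0) rating on the same scale and body site. Subjects
#' lacking a T0 rating yield explicit missing-data rows (`delta = NA`),
#' never zeros.
#'
#' @param responses validated response data.frame.
#' @return data.frame `subject_id`, `timepoint`, `scale`, `body_site`,
#'   `delta`.
#' @export
delta_from_baseline <- function(responses) {
  key <- function(d) paste(d$subject_id, d$scale, d$body_site)
  base <- responses[responses$timepoint == "T0", ]
  b <- stats::setNames(base$value, key(base))
  later <- responses[responses$timepoint != "T0", ]
  data.frame(subject_id = later$subject_id, timepoint = later$timepoint,
             scale = later$scale, body_site = later$body_site,
             delta = later$value - unname(b[key(later)]),
             stringsAsFactors = FALSE)
}

#' Shift-long Borg CR10 change per shoulder
#'
#' End-of-shift minus pre-shift CR10 rating for each shoulder, with the
#' shoulder additionally labelled dominant or non-dominant using the
#' roster. Missing endpoints yield `NA` changes.
#'
#' @param responses validated response data.frame (CR10 rows used).
#' @param roster data.frame with `subject_id` and `dominant_side`.
#' @return data.frame `subject_id`, `body_site`, `side`, `dominance`,
#'   `cr10_change`.
#' @export
cr10_shift_change <- function(responses, roster) {
  cr <- responses[responses$scale == "BorgCR10", ]
  grid <- expand.grid(subject_id = unique(roster$subject_id),
                      body_site = c("left_shoulder", "right_shoulder"),
                      stringsAsFactors = FALSE)
  val <- function(tp) {
    d <- cr[cr$timepoint == tp, ]
    stats::setNames(d$value, paste(d$subject_id, d$body_site))[
      paste(grid$subject_id, grid$body_site)]
  }
  side <- sub("_shoulder", "", grid$body_site)
  dom <- stats::setNames(roster$dominant_side, roster$subject_id)[
    grid$subject_id]
  data.frame(subject_id = grid$subject_id, body_site = grid$body_site,
             side = side,
             dominance = ifelse(side == dom, "dominant", "nondominant"),
             cr10_change = unname(val("T3") - val("T0")),
             stringsAsFactors = FALSE)
}
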