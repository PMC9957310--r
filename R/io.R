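# CSV dialects shared by the generator and the analysis pipeline.
# All files are plain comma-separated text; EMG files carry a one-line
# metadata header because repeating per-sample metadata at 1000 Hz would
# triple file sizes.

#' Write / read a subject roster CSV
#' @param roster data.frame from [simulate_cohort()].
#' @param path file path.
#' @return `read_roster_csv` returns the roster data.frame.
#' @export
write_roster_csv <- function(roster, path) {
  data.table::fwrite(roster, path)
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = list(
    character = c("subject_id", "group", "dominant_side"))))
}

#' Write / read a 1-Hz heart-rate series CSV
#'
#' Columns `subject_id`, `time` (seconds of day), `bpm`.
#' @param series an `hr_series`.
#' @param path file path.
#' @return `read_hr_csv` returns an `hr_series`.
#' @export
write_hr_csv <- function(series, path) {
  data.table::fwrite(data.frame(subject_id = series$subject_id,
                                time = series$time, bpm = series$bpm), path)
  invisible(path)
}

#' @rdname write_hr_csv
#' @export
read_hr_csv <- function(path) {
  d <- data.table::fread(path)
  if (!all(c("subject_id", "time", "bpm") %in% names(d)))
    stop("heart-rate CSV needs columns subject_id, time, bpm", call. = FALSE)
  if (is.unsorted(d$time, strictly = TRUE))
    stop("heart-rate timestamps must be strictly increasing", call. = FALSE)
  structure(list(subject_id = as.character(d$subject_id[1]),
                 time = as.numeric(d$time), bpm = as.numeric(d$bpm)),
            class = "hr_series")
}

#' Write / read an EMG recording CSV
#'
#' One metadata header line
#' (`#ergofield-emg subject_id=... side=... start_time=... sampling_rate=...`)
#' followed by a single `amplitude_mv` column.
#' @param recording an `emg_recording`.
#' @param path file path.
#' @return `read_emg_csv` returns an `emg_recording`.
#' @export
write_emg_csv <- function(recording, path) {
  hdr <- sprintf("#ergofield-emg subject_id=%s side=%s start_time=%g sampling_rate=%g",
                 recording$subject_id, recording$side,
                 recording$start_time, recording$sampling_rate)
  writeLines(hdr, path)
  data.table::fwrite(data.frame(amplitude_mv = recording$samples), path,
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_emg_csv
#' @export
read_emg_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#ergofield-emg"))
    stop("not an EMG CSV (missing metadata header): ", path, call. = FALSE)
  kv <- strsplit(strsplit(sub("^#ergofield-emg ", "", hdr), " ")[[1]], "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  d <- data.table::fread(path, skip = 1L)
  emg_recording(meta[["subject_id"]], meta[["side"]], d$amplitude_mv,
                as.numeric(meta[["sampling_rate"]]),
                as.numeric(meta[["start_time"]]))
}

#' Write / read the survey-response CSV
#' @param responses data.frame of responses.
#' @param path file path.
#' @return `read_survey_csv` returns the data.frame.
#' @export
write_survey_csv <- function(responses, path) {
  data.table::fwrite(responses, path)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = list(
    character = c("subject_id", "timepoint", "scale", "body_site"))))
}
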