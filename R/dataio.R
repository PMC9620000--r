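#' Read a pupil sample table
#'
#' A sample table is a long-format CSV with one row per eye-tracker sample:
#' `participant_id`, `list_id`, `eye` (`"left"` or `"right"`), `time_s`
#' (seconds from list onset) and `pupil` (diameter in mm). A missing pupil
#' sample is an empty field, never 0. Time must be strictly increasing within
#' each (participant, list, eye) recording; the nominal sampling interval is
#' 1/1200 s.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble with columns `participant_id`, `list_id`, `eye`,
#'   `time_s`, `pupil`.
#' @export
read_sample_table <- function(path) {
  x <- read_csv_exact(path, c(
    participant_id = "character", list_id = "character",
    eye = "character", time_s = "double", pupil = "double"
  ))
  validate_sample_table(x)
  x
}

# base-R CSV reader: strtod parsing recovers shortest-roundtrip doubles
# exactly, so write + read is bit-identical
read_csv_exact <- function(path, col_classes) {
  x <- utils::read.csv(path,
    colClasses = col_classes, na.strings = c("", "NA"),
    check.names = FALSE
  )
  miss <- setdiff(names(col_classes), names(x))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  }
  tibble::as_tibble(x[names(col_classes)])
}

#' @rdname read_sample_table
#' @param x A sample table.
#' @export
write_sample_table <- function(x, path) {
  validate_sample_table(x)
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' Validate study tables against their invariants
#'
#' Checks column presence, value ranges and ordering rules (strictly
#' increasing time within each recording, seven sentences per list with
#' increasing onsets, scores within range) and reports the first offending
#' row. Each reader calls its validator; they are exported so externally
#' assembled tables can be checked too.
#'
#' @param x The table to validate.
#' @return The table, invisibly; an error describes the first violation.
#' @export
validate_sample_table <- function(x) {
  need <- c("participant_id", "list_id", "eye", "time_s", "pupil")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("sample table is missing columns: ", paste(miss, collapse = ", "))
  }
  bad_eye <- which(!x$eye %in% c("left", "right"))
  if (length(bad_eye)) {
    stop("invalid eye value at row ", bad_eye[1])
  }
  bad_pupil <- which(!is.na(x$pupil) & x$pupil <= 0)
  if (length(bad_pupil)) {
    stop("non-positive pupil diameter at row ", bad_pupil[1])
  }
  # strictly increasing time within each recording (consecutive-row check;
  # avoids building a pasted key over millions of samples)
  n <- nrow(x)
  if (n > 1L) {
    same <- x$participant_id[-1] == x$participant_id[-n] &
      x$list_id[-1] == x$list_id[-n] & x$eye[-1] == x$eye[-n]
    bad_t <- which(c(FALSE, same) & c(TRUE, diff(x$time_s) <= 0))
    if (length(bad_t)) {
      stop("time not strictly increasing at row ", bad_t[1])
    }
  }
  invisible(x)
}

# contiguous (participant, list, eye) runs of a sample table
sample_runs <- function(x) {
  n <- nrow(x)
  chg <- if (n > 1L) {
    x$participant_id[-1] != x$participant_id[-n] |
      x$list_id[-1] != x$list_id[-n] | x$eye[-1] != x$eye[-n]
  } else {
    logical(0)
  }
  starts <- which(c(TRUE, chg))
  ends <- c(starts[-1] - 1L, n)
  tibble::tibble(
    participant_id = x$participant_id[starts],
    list_id = x$list_id[starts],
    eye = x$eye[starts],
    start = starts, end = ends
  )
}

#' Read or write an event table
#'
#' One row per sentence: `participant_id`, `list_id`, `position` (serial
#' position 1-7), `sentence_onset_s`, `sentence_offset_s`, `noise_reduction`
#' (`"on"`/`"off"`), `repeated_correct` and `recalled` (logical). Every list
#' holds exactly seven sentences with increasing onsets; event times share the
#' sample-table clock (seconds from list onset).
#'
#' @param path Path to a CSV file.
#' @return A tibble of events.
#' @export
read_event_table <- function(path) {
  x <- read_csv_exact(path, c(
    participant_id = "character", list_id = "character",
    position = "integer", sentence_onset_s = "double",
    sentence_offset_s = "double", noise_reduction = "character",
    repeated_correct = "logical", recalled = "logical"
  ))
  validate_event_table(x)
  x
}

#' @rdname read_event_table
#' @param x An event table.
#' @export
write_event_table <- function(x, path) {
  validate_event_table(x)
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname validate_sample_table
#' @export
validate_event_table <- function(x) {
  need <- c(
    "participant_id", "list_id", "position", "sentence_onset_s",
    "sentence_offset_s", "noise_reduction", "repeated_correct", "recalled"
  )
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("event table is missing columns: ", paste(miss, collapse = ", "))
  }
  bad_nr <- which(!x$noise_reduction %in% c("on", "off"))
  if (length(bad_nr)) stop("invalid noise_reduction at row ", bad_nr[1])
  bad_pos <- which(is.na(x$position) | x$position < 1L | x$position > 7L)
  if (length(bad_pos)) stop("position outside 1-7 at row ", bad_pos[1])
  per_list <- table(paste(x$participant_id, x$list_id, sep = "\r"))
  if (any(per_list != 7L)) {
    stop("every (participant, list) must hold exactly 7 sentences")
  }
  key <- paste(x$participant_id, x$list_id, sep = "\r")
  same <- c(FALSE, key[-1] == key[-length(key)])
  bad_t <- which(same & c(TRUE, diff(x$sentence_onset_s) <= 0))
  if (length(bad_t)) stop("onsets not increasing within list at row ", bad_t[1])
  invisible(x)
}

#' Read or write a participant table
#'
#' One row per participant: `participant_id`, `age` (years), `pta_left` and
#' `pta_right` (four-frequency pure-tone averages at 0.5/1/2/4 kHz, dB HL),
#' and `rs_score` (Reading Span score, percent of target words correctly
#' recalled, 0-100).
#'
#' @param path Path to a CSV file.
#' @return A tibble of participants.
#' @export
read_participant_table <- function(path) {
  x <- read_csv_exact(path, c(
    participant_id = "character", age = "double", pta_left = "double",
    pta_right = "double", rs_score = "double"
  ))
  validate_participant_table(x)
  x
}

#' @rdname read_participant_table
#' @param x A participant table.
#' @export
write_participant_table <- function(x, path) {
  validate_participant_table(x)
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname validate_sample_table
#' @export
validate_participant_table <- function(x) {
  need <- c("participant_id", "age", "pta_left", "pta_right", "rs_score")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("participant table is missing columns: ", paste(miss, collapse = ", "))
  }
  bad_rs <- which(x$rs_score < 0 | x$rs_score > 100)
  if (length(bad_rs)) stop("rs_score outside [0, 100] at row ", bad_rs[1])
  bad_pta <- which(x$pta_left < 0 | x$pta_right < 0)
  if (length(bad_pta)) stop("negative PTA at row ", bad_pta[1])
  invisible(x)
}

#' Select the analysis eye
#'
#' The right eye is analysed by default unless more data (present, non-missing
#' pupil samples) is available for the left eye. Ties go to the right eye.
#' Counts are taken before any cleaning.
#'
#' @param samples_left,samples_right Sample-table rows for the left and right
#'   eye of the same recording (either may have zero rows).
#' @return The chosen eye's rows, with attribute `"eye"` set to `"left"` or
#'   `"right"`.
#' @export
select_eye <- function(samples_left, samples_right) {
  n_left <- if (is.null(samples_left)) 0L else sum(!is.na(samples_left$pupil))
  n_right <- if (is.null(samples_right)) 0L else sum(!is.na(samples_right$pupil))
  if (n_left == 0L && n_right == 0L) {
    stop("both eyes have no present samples")
  }
  if (n_left > n_right) {
    out <- samples_left
    attr(out, "eye") <- "left"
  } else {
    out <- samples_right
    attr(out, "eye") <- "right"
  }
  out
}
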