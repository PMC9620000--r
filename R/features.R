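#' Epoch a cleaned trace around a sentence onset
#'
#' Re-indexes the samples in `[onset - pre_s, onset + post_s)` to time from
#' sentence onset. At 1200 Hz the default window holds 6000 samples spanning
#' \[-1, 4) s. When the recording does not cover the full window the trial is
#' marked missing (`NULL` is returned).
#'
#' @param trace A cleaned trace for one recording: a data frame with `time_s`
#'   and `pupil` (gap-free), optionally `is_interpolated`.
#' @param onset_s Sentence onset, seconds on the trace clock.
#' @param pre_s,post_s Window extent before and after the onset (seconds).
#' @param rate Sampling rate in Hz (used only for the coverage check).
#' @return A tibble with `t_rel` (seconds from onset) and `pupil`, or `NULL`
#'   when coverage is insufficient.
#' @export
epoch_trial <- function(trace, onset_s, pre_s = 1.0, post_s = 4.0,
                        rate = 1200) {
  n <- nrow(trace)
  if (n == 0L) {
    return(NULL)
  }
  covered <- trace$time_s[1] <= onset_s - pre_s + 1e-9 &&
    trace$time_s[n] >= onset_s + post_s - 1.5 / rate
  if (!covered) {
    return(NULL)
  }
  i_lo <- findInterval(onset_s - pre_s - 1e-9, trace$time_s) + 1L
  i_hi <- findInterval(onset_s + post_s - 1e-9, trace$time_s)
  idx <- i_lo:i_hi
  tibble::tibble(t_rel = trace$time_s[idx] - onset_s, pupil = trace$pupil[idx])
}

# row indices of each cleaned (participant, list) trace, keyed by
# participant\rlist, from contiguous runs (no whole-table paste)
cleaned_trace_index <- function(samples) {
  runs <- sample_runs(samples)
  run_map <- split(
    seq_len(nrow(runs)),
    paste(runs$participant_id, runs$list_id, sep = "\r")
  )
  lapply(run_map, function(rid) {
    unlist(lapply(rid, function(i) runs$start[i]:runs$end[i]))
  })
}

#' Baseline pupil dilation of an epoch
#'
#' Arithmetic mean of the pupil diameter over the 1 s baseline window
#' \[-pre_s, 0) before sentence onset. One second is the longest pre-onset
#' interval with homogeneous acoustics in the paradigm (the babble precedes
#' sentences 2-7 by exactly 1 s).
#'
#' @param epoch Epoch from [epoch_trial()].
#' @param pre_s Baseline window length (seconds).
#' @return Baseline diameter in mm.
#' @export
baseline_value <- function(epoch, pre_s = 1.0) {
  idx <- epoch$t_rel >= -pre_s & epoch$t_rel < 0
  if (!any(idx)) stop("empty baseline window")
  mean(epoch$pupil[idx])
}

#' Baseline-corrected peak pupil dilation
#'
#' Maximum pupil diameter in the four seconds starting at sentence onset,
#' minus the baseline. Negative values (pupil constriction) are retained.
#'
#' @param epoch Epoch from [epoch_trial()].
#' @param baseline Baseline diameter from [baseline_value()].
#' @param post_s Response window length (seconds from onset).
#' @return PPD in mm.
#' @export
peak_pupil_dilation <- function(epoch, baseline, post_s = 4.0) {
  idx <- epoch$t_rel >= 0 & epoch$t_rel < post_s
  if (!any(idx)) stop("empty response window")
  max(epoch$pupil[idx]) - baseline
}

#' Drop sentences whose target word was not repeated
#'
#' Only target words that were correctly repeated enter the recall analysis
#' (about 2% of targets are typically not heard). The dropped fraction is
#' attached as attribute `"dropped_fraction"`.
#'
#' @param features A trial-feature table with a `repeated_correct` column.
#' @return The table restricted to repeated trials.
#' @export
filter_repeated <- function(features) {
  n <- nrow(features)
  out <- features[features$repeated_correct %in% TRUE, ]
  if (n > 0L && nrow(out) == 0L) {
    warning("no repeated trials remain")
  }
  attr(out, "dropped_fraction") <- if (n) (n - nrow(out)) / n else 0
  out
}

#' Extract trial features from a cleaned study
#'
#' Computes baseline and baseline-corrected PPD for every kept trial of every
#' included participant, and joins participant covariates (age, Reading Span
#' score, and PTA as the mean of the left- and right-ear four-frequency
#' averages).
#'
#' @param cleaned Output of [clean_study()].
#' @param events Event table.
#' @param participants Participant table.
#' @param pre_s,post_s Baseline and response windows (seconds).
#' @param rate Sampling rate in Hz.
#' @return A trial-feature tibble, one row per kept trial, with `baseline`,
#'   `ppd`, `fraction_valid`, design variables and covariates.
#' @export
extract_features <- function(cleaned, events, participants,
                             pre_s = 1.0, post_s = 4.0, rate = 1200) {
  validate_participant_table(participants)
  trials <- cleaned$trials
  trials <- trials[trials$kept & !trials$excluded_participant, ]
  trace_idx <- cleaned$trace_index
  if (is.null(trace_idx)) trace_idx <- cleaned_trace_index(cleaned$samples)
  rows <- vector("list", nrow(trials))
  ev_key <- paste(events$participant_id, events$list_id, events$position,
    sep = "\r"
  )
  for (i in seq_len(nrow(trials))) {
    pid <- trials$participant_id[i]
    lid <- trials$list_id[i]
    pos <- trials$position[i]
    ev <- events[match(paste(pid, lid, pos, sep = "\r"), ev_key), ]
    tr <- cleaned$samples[trace_idx[[paste(pid, lid, sep = "\r")]], ]
    ep <- epoch_trial(tr, ev$sentence_onset_s,
      pre_s = pre_s, post_s = post_s,
      rate = rate
    )
    if (is.null(ep)) next
    b <- baseline_value(ep, pre_s = pre_s)
    rows[[i]] <- tibble::tibble(
      participant_id = pid, list_id = lid, position = pos,
      noise_reduction = ev$noise_reduction,
      baseline = b,
      ppd = peak_pupil_dilation(ep, b, post_s = post_s),
      fraction_valid = trials$fraction_valid[i],
      repeated_correct = ev$repeated_correct,
      recalled = ev$recalled
    )
  }
  feats <- dplyr::bind_rows(rows)
  covars <- tibble::tibble(
    participant_id = participants$participant_id,
    age = participants$age,
    pta = (participants$pta_left + participants$pta_right) / 2,
    rs_score = participants$rs_score
  )
  dplyr::left_join(feats, covars, by = "participant_id")
}

#' Group time courses and per-participant PPD summaries
#'
#' Pointwise mean and standard error (SD/sqrt(n)) of the baseline-corrected
#' dilation per recall outcome and serial position, plus per-participant mean
#' PPD for recalled vs not recalled words. Empty groups are omitted with a
#' warning.
#'
#' @param epochs A tibble of baseline-corrected epoch samples with columns
#'   `participant_id`, `position`, `recalled`, `t_rel` and `dilation`; one
#'   row per sample per trial.
#' @param features A trial-feature table (for the per-participant summary);
#'   optional.
#' @return A list with `time_course` (per `recalled` x `position` x `t_rel`:
#'   `mean`, `se`, `n`) and, when `features` is given, `participant_ppd`
#'   (mean PPD per participant and outcome).
#' @export
time_course_summary <- function(epochs, features = NULL) {
  if (nrow(epochs) == 0L) stop("no epochs to summarise")
  tc <- epochs |>
    dplyr::group_by(.data$recalled, .data$position, .data$t_rel) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$trial_id),
      mean = mean(.data$dilation),
      se = if (dplyr::n() > 1) stats::sd(.data$dilation) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
  out <- list(time_course = tc)
  if (!is.null(features)) {
    out$participant_ppd <- features |>
      dplyr::group_by(.data$participant_id, .data$recalled) |>
      dplyr::summarise(
        mean_ppd = mean(.data$ppd), n = dplyr::n(),
        .groups = "drop"
      )
  }
  out
}

#' Build baseline-corrected epoch samples for time-course plots
#'
#' Convenience helper that epochs every kept trial of a cleaned study and
#' stacks the baseline-corrected samples in long format, ready for
#' [time_course_summary()].
#'
#' @inheritParams extract_features
#' @param downsample Keep every `downsample`-th sample of each epoch (the
#'   1200 Hz grid is denser than any plot needs).
#' @return A tibble with `participant_id`, `list_id`, `position`, `recalled`,
#'   `trial_id`, `t_rel`, `dilation`.
#' @export
epoch_samples <- function(cleaned, events, pre_s = 1.0, post_s = 4.0,
                          rate = 1200, downsample = 12L) {
  trials <- cleaned$trials
  trials <- trials[trials$kept & !trials$excluded_participant, ]
  trace_idx <- cleaned$trace_index
  if (is.null(trace_idx)) trace_idx <- cleaned_trace_index(cleaned$samples)
  ev_key <- paste(events$participant_id, events$list_id, events$position,
    sep = "\r"
  )
  rows <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    pid <- trials$participant_id[i]
    lid <- trials$list_id[i]
    pos <- trials$position[i]
    ev <- events[match(paste(pid, lid, pos, sep = "\r"), ev_key), ]
    tr <- cleaned$samples[trace_idx[[paste(pid, lid, sep = "\r")]], ]
    ep <- epoch_trial(tr, ev$sentence_onset_s,
      pre_s = pre_s, post_s = post_s,
      rate = rate
    )
    if (is.null(ep)) next
    b <- baseline_value(ep, pre_s = pre_s)
    keep <- seq(1L, nrow(ep), by = as.integer(downsample))
    rows[[i]] <- tibble::tibble(
      participant_id = pid, list_id = lid, position = pos,
      recalled = ev$recalled,
      trial_id = paste(pid, lid, pos, sep = "_"),
      t_rel = round(ep$t_rel[keep] - ep$t_rel[1], 9) - pre_s,
      dilation = ep$pupil[keep] - b
    )
  }
  dplyr::bind_rows(rows)
}
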