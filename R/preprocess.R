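#' Detect blinks with a sliding-window threshold
#'
#' A sample is flagged as part of a blink when its pupil diameter lies more
#' than `k` standard deviations below the mean pupil size within a sliding
#' window centred on it (1 s, i.e. 1200 samples at the 1200 Hz tracker rate).
#' Window statistics use present (non-missing) samples only, and the window
#' shrinks at the recording edges. Samples that are already missing (tracker
#' dropouts) are flagged as well, so that they receive the same padding as
#' threshold-detected blinks.
#'
#' @param pupil Numeric vector of pupil diameters (mm), `NA` for missing.
#' @param rate Sampling rate in Hz.
#' @param window_s Sliding-window length in seconds.
#' @param k Threshold in standard deviations below the window mean.
#' @return Integer vector of flagged sample indices (1-based).
#' @export
detect_blinks <- function(pupil, rate = 1200, window_s = 1.0, k = 3.0) {
  n <- length(pupil)
  present <- !is.na(pupil)
  if (!any(present)) stop("all samples are missing")
  w <- as.integer(round(window_s * rate))
  if (w < 2L) stop("window must hold at least 2 samples")
  # centred window [i - before, i + after], length w in the interior
  before <- w %/% 2L
  after <- w - before - 1L

  # windowed mean/SD from cumulative sums, centered by the global mean to
  # limit cancellation error on long near-constant stretches
  m0 <- mean(pupil[present])
  v <- ifelse(present, pupil - m0, 0)
  cs1 <- c(0, cumsum(v))
  cs2 <- c(0, cumsum(v * v))
  csn <- c(0, cumsum(as.numeric(present)))
  i <- seq_len(n)
  lo <- pmax(i - before, 1L)
  hi <- pmin(i + after, n)
  sum1 <- cs1[hi + 1L] - cs1[lo]
  sum2 <- cs2[hi + 1L] - cs2[lo]
  cnt <- csn[hi + 1L] - csn[lo]

  m <- m0 + sum1 / cnt
  varw <- (sum2 - sum1 * sum1 / cnt) / (cnt - 1)
  varw[cnt < 2] <- NA_real_
  varw <- pmax(varw, 0) # guard tiny negative from rounding
  s <- sqrt(varw)
  # the absolute guard (1e-9 mm, far below any physical signal) keeps
  # rounding noise in the running sums from flagging constant stretches
  low <- present & !is.na(s) & pupil < m - k * s - 1e-9 * (1 + abs(m))
  which(low | !present)
}

#' Pad flagged blink samples and merge into removal segments
#'
#' Each run of flagged samples is extended by `pre_samples` before and
#' `post_samples` after (77 samples = 64 ms and 181 samples = 151 ms at
#' 1200 Hz), clipped to the recording, and overlapping extensions are merged.
#' The returned segments cover exactly the union of the padded runs.
#'
#' @param flags Integer vector of flagged sample indices (1-based), as
#'   returned by [detect_blinks()].
#' @param n Number of samples in the recording.
#' @param pre_samples,post_samples Padding before and after each flagged run.
#' @return A tibble of segments with 1-based inclusive `start` and `end`.
#' @export
pad_and_remove <- function(flags, n, pre_samples = 77, post_samples = 181) {
  if (length(flags) == 0L) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  flags <- sort(unique(as.integer(flags)))
  if (flags[1] < 1L || flags[length(flags)] > n) {
    stop("flag index outside recording")
  }
  starts <- pmax(flags - as.integer(pre_samples), 1L)
  ends <- pmin(flags + as.integer(post_samples), as.integer(n))
  # merge overlapping/adjacent padded intervals
  keep_start <- c(TRUE, starts[-1] > cummax(ends[-length(ends)]) + 1L)
  grp <- cumsum(keep_start)
  tibble::tibble(
    start = starts[keep_start],
    end = as.integer(tapply(ends, grp, max))
  )
}

#' Materialise removal segments as a logical mask
#'
#' @param segments Segments from [pad_and_remove()].
#' @param n Recording length in samples.
#' @return Logical vector of length `n`, `TRUE` where removed.
#' @export
segments_to_mask <- function(segments, n) {
  removed <- logical(n)
  if (nrow(segments)) {
    for (j in seq_len(nrow(segments))) {
      removed[segments$start[j]:segments$end[j]] <- TRUE
    }
  }
  removed
}

#' Linearly interpolate removed samples
#'
#' Each removed sample is replaced by the straight line between the nearest
#' surviving samples on each side. Leading or trailing gaps with no anchor on
#' one side are filled by nearest-value hold; they are still counted as
#' interpolated. Surviving samples are never altered.
#'
#' @param pupil Numeric vector of pupil diameters, `NA` allowed.
#' @param segments Removal segments from [pad_and_remove()].
#' @return A list with `pupil` (gap-free trace), `interpolated` (logical
#'   mask) and `fraction` (removed samples / total samples).
#' @export
interpolate_gaps <- function(pupil, segments) {
  n <- length(pupil)
  removed <- segments_to_mask(segments, n)
  removed <- removed | is.na(pupil)
  keep <- !removed
  if (!any(keep)) stop("no surviving samples to interpolate from")
  out <- pupil
  if (any(removed)) {
    idx <- seq_len(n)
    fill <- stats::approx(idx[keep], pupil[keep],
      xout = idx[removed],
      method = "linear", rule = 2
    )$y
    out[removed] <- fill
  }
  list(pupil = out, interpolated = removed, fraction = mean(removed))
}

#' Clean one pupil trace
#'
#' Runs blink detection, padded removal and linear interpolation on a single
#' continuous recording. The pre-interpolation survival mask is retained so
#' that trial validity can be judged on data that was actually measured.
#'
#' @param pupil Numeric vector of pupil diameters, `NA` for missing.
#' @inheritParams detect_blinks
#' @inheritParams pad_and_remove
#' @return A list with `pupil` (cleaned, gap-free), `removed` (logical mask of
#'   samples that were missing or blink-removed), `segments`, and
#'   `interpolated_fraction`.
#' @export
preprocess_trace <- function(pupil, rate = 1200, window_s = 1.0, k = 3.0,
                             pre_samples = 77, post_samples = 181) {
  flags <- detect_blinks(pupil, rate = rate, window_s = window_s, k = k)
  segments <- pad_and_remove(flags, length(pupil),
    pre_samples = pre_samples, post_samples = post_samples
  )
  interp <- interpolate_gaps(pupil, segments)
  reason <- rep("", length(pupil))
  reason[interp$interpolated] <- "padding"
  reason[flags] <- "blink"
  reason[is.na(pupil)] <- "dropout"
  list(
    pupil = interp$pupil,
    removed = interp$interpolated,
    reason = reason,
    segments = segments,
    interpolated_fraction = interp$fraction
  )
}

#' Trial validity
#'
#' Fraction of samples inside the trial window that were not removed as
#' missing or blink (judged before interpolation). Trials with less than 60%
#' valid data are discarded; exactly 60% is kept.
#'
#' @param removed Logical removal mask for the whole recording.
#' @param window_idx Integer indices of the trial window.
#' @param min_valid Minimum valid fraction for a trial to be kept.
#' @return A list with `fraction_valid` and `kept`.
#' @export
trial_validity <- function(removed, window_idx, min_valid = 0.60) {
  if (length(window_idx) == 0L) stop("empty trial window")
  fraction <- mean(!removed[window_idx])
  list(fraction_valid = fraction, kept = fraction >= min_valid)
}

#' Participant validity
#'
#' A participant is excluded when more than `threshold` (15%) of their
#' administered sentences were discarded; exactly 15% is kept.
#'
#' @param kept_flags Logical vector, one per administered trial.
#' @param threshold Maximum tolerated fraction of missing sentences.
#' @return `TRUE` to keep the participant.
#' @export
participant_validity <- function(kept_flags, threshold = 0.15) {
  if (length(kept_flags) == 0L) stop("participant has zero trials")
  mean(!kept_flags) <= threshold
}

#' Clean a whole study
#'
#' Selects the analysis eye per participant, cleans every (participant, list)
#' recording, judges per-trial validity in the epoch window around each
#' sentence onset, and applies the participant-level exclusion rule. Every
#' exclusion is logged with a reason code in the returned report.
#'
#' @param samples Sample table (possibly both eyes).
#' @param events Event table.
#' @param rate Sampling rate in Hz.
#' @param window_s,k,pre_samples,post_samples Blink-detection and padding
#'   parameters, see [detect_blinks()] and [pad_and_remove()].
#' @param min_valid Minimum per-trial valid fraction (default 0.60).
#' @param max_missing Maximum per-participant fraction of discarded sentences
#'   (default 0.15).
#' @param epoch_pre_s,epoch_post_s Trial window relative to sentence onset,
#'   `[-epoch_pre_s, epoch_post_s)` seconds.
#' @param validate Check the input tables' invariants first (skip only for
#'   freshly generated tables that are known to satisfy them).
#' @return A list with `samples` (cleaned, selected-eye samples with
#'   `is_interpolated` and a `removed_reason` code: `"dropout"`, `"blink"`,
#'   `"padding"` or empty), `trials` (per-trial validity and kept flags),
#'   `report` (a cleaning report, see Details) and `eyes` (chosen eye per
#'   participant).
#'
#' @details The report holds `n_trials_total` and `n_trials_discarded` over
#'   participants that survive the exclusion rule, the corresponding
#'   percentage, the mean percentage of interpolated samples within valid
#'   trial windows, and one row per excluded participant with a reason code.
#' @export
clean_study <- function(samples, events, rate = 1200, window_s = 1.0, k = 3.0,
                        pre_samples = 77, post_samples = 181,
                        min_valid = 0.60, max_missing = 0.15,
                        epoch_pre_s = 1.0, epoch_post_s = 4.0,
                        validate = TRUE) {
  if (validate) {
    validate_sample_table(samples)
    validate_event_table(events)
  }

  participants <- unique(samples$participant_id)
  cleaned_list <- vector("list", 0L)
  trial_rows <- vector("list", 0L)
  eye_choice <- character(0)

  # contiguous-run index of the sample table; a trace may span several runs
  runs <- sample_runs(samples)
  runs$present <- vapply(
    seq_len(nrow(runs)),
    function(i) sum(!is.na(samples$pupil[runs$start[i]:runs$end[i]])),
    numeric(1)
  )
  run_map <- split(
    seq_len(nrow(runs)),
    paste(runs$participant_id, runs$list_id, runs$eye, sep = "\r")
  )
  trace_rows <- function(pid, lid, eye) {
    rid <- run_map[[paste(pid, lid, eye, sep = "\r")]]
    if (is.null(rid)) {
      return(NULL)
    }
    unlist(lapply(rid, function(i) runs$start[i]:runs$end[i]))
  }
  ev_map <- split(
    seq_len(nrow(events)),
    paste(events$participant_id, events$list_id, sep = "\r")
  )

  for (pid in participants) {
    prun <- runs[runs$participant_id == pid, ]
    n_left <- sum(prun$present[prun$eye == "left"])
    n_right <- sum(prun$present[prun$eye == "right"])
    if (n_left == 0 && n_right == 0) next
    eye <- if (n_left > n_right) "left" else "right"
    eye_choice[pid] <- eye

    for (lid in unique(prun$list_id)) {
      rows <- trace_rows(pid, lid, eye)
      if (is.null(rows)) next
      tr <- samples[rows, ]
      nt <- nrow(tr)
      pp <- preprocess_trace(tr$pupil,
        rate = rate, window_s = window_s, k = k,
        pre_samples = pre_samples, post_samples = post_samples
      )
      ev <- events[ev_map[[paste(pid, lid, sep = "\r")]], ]
      if (nrow(ev)) {
        for (j in seq_len(nrow(ev))) {
          onset <- ev$sentence_onset_s[j]
          i_lo <- findInterval(onset - epoch_pre_s - 1e-9, tr$time_s) + 1L
          i_hi <- findInterval(onset + epoch_post_s - 1e-9, tr$time_s)
          covered <- i_lo <= i_hi &&
            tr$time_s[1] <= onset - epoch_pre_s + 1e-9 &&
            tr$time_s[nt] >= onset + epoch_post_s - 1.5 / rate
          if (!covered) {
            frac <- 0
            kept <- FALSE
            interp_frac <- NA_real_
          } else {
            tv <- trial_validity(pp$removed, i_lo:i_hi,
              min_valid = min_valid
            )
            frac <- tv$fraction_valid
            kept <- tv$kept
            interp_frac <- mean(pp$removed[i_lo:i_hi])
          }
          trial_rows[[length(trial_rows) + 1L]] <- tibble::tibble(
            participant_id = pid, list_id = lid, position = ev$position[j],
            fraction_valid = frac, kept = kept,
            interpolated_fraction = interp_frac
          )
        }
      }
      cleaned_list[[length(cleaned_list) + 1L]] <- tibble::tibble(
        participant_id = pid, list_id = lid, eye = eye,
        time_s = tr$time_s, pupil = pp$pupil,
        is_interpolated = pp$removed,
        removed_reason = pp$reason
      )
      names(cleaned_list)[length(cleaned_list)] <- paste(pid, lid, sep = "\r")
    }
  }

  # row index of each trace in the bound cleaned table, carried along so
  # downstream epoching need not rebuild it
  lens <- vapply(cleaned_list, nrow, integer(1))
  trace_index <- vector("list", length(cleaned_list))
  names(trace_index) <- names(cleaned_list)
  at <- 0L
  for (i in seq_along(cleaned_list)) {
    trace_index[[i]] <- at + seq_len(lens[i])
    at <- at + lens[i]
  }

  trials <- dplyr::bind_rows(trial_rows)
  cleaned <- dplyr::bind_rows(cleaned_list)

  # participant-level exclusion on fraction of discarded sentences
  excluded <- character(0)
  for (pid in unique(trials$participant_id)) {
    flags <- trials$kept[trials$participant_id == pid]
    if (!participant_validity(flags, threshold = max_missing)) {
      excluded <- c(excluded, pid)
    }
  }
  no_eye <- setdiff(participants, names(eye_choice))
  report_excl <- tibble::tibble(
    participant_id = c(excluded, no_eye),
    reason = c(
      rep("missing_trials_gt_15pct", length(excluded)),
      rep("no_present_samples", length(no_eye))
    )
  )

  kept_trials <- trials[!trials$participant_id %in% excluded, ]
  n_total <- nrow(kept_trials)
  n_disc <- sum(!kept_trials$kept)
  valid <- kept_trials[kept_trials$kept, ]
  report <- list(
    n_trials_total = n_total,
    n_trials_discarded = n_disc,
    pct_trials_discarded = if (n_total) 100 * n_disc / n_total else NA_real_,
    pct_samples_interpolated = if (nrow(valid)) {
      100 * mean(valid$interpolated_fraction)
    } else {
      NA_real_
    },
    participants_excluded = report_excl
  )
  trials$excluded_participant <- trials$participant_id %in% excluded

  list(
    samples = cleaned, trials = trials, report = report, eyes = eye_choice,
    trace_index = trace_index
  )
}
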