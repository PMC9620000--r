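#' Configuration of a synthetic SWIR + pupillometry study
#'
#' Defines the generative model for complete synthetic studies: cohort
#' composition, trial structure, recall model coefficients, random-effect
#' standard deviations, and pupil-trace parameters. The defaults emulate the
#' study conditions the analysis is designed for: 21 participants completing
#' 28 lists of 7 sentences at a 1200 Hz tracker rate, with the recall-model
#' coefficients seeded from the published fit (intercept 0.61, PPD 0.60, RS
#' 0.03, noise reduction -0.01, age -0.01, PTA 0.01 -- simulation defaults,
#' not claims), participant intercept SD 1.0 and serial-position intercept SD
#' 0.3 on top of a fixed primacy/recency profile whose last position is the
#' maximum (strong recency). Pupil diameters are in mm with a ~4 mm baseline.
#'
#' @param preset `"study"` for the full-scale defaults, `"small"` for a
#'   6-participant, 6-list preset that a recovery loop can afford to run many
#'   times.
#' @param ... Named overrides of any configuration element.
#' @return A `sim_config` list.
#' @export
sim_config <- function(preset = c("study", "small"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_participants = 21L, n_lists = 28L, list_length = 7L,
    sample_rate = 1200,
    beta = c(
      intercept = 0.61, ppd = 0.60, rs_score = 0.03,
      noise_reduction = -0.01, age = -0.01, pta = 0.01
    ),
    sigma_participant = 1.0, sigma_trial = 0.3,
    position_profile = c(0.6, 0.0, -0.4, -0.5, -0.4, 0.2, 2.5),
    amp_mean = 0.45, amp_sd = 0.20, amp_min = 0.05,
    baseline_mean = 4.0, baseline_sd = 0.3,
    drift_amp = 0.10, drift_periods = c(17, 7),
    kernel_peak_s = 2.0, kernel_shape = 8, kernel_taper = c(3.5, 4.0),
    noise_sd = 0.015,
    blink_rate = 0.20, blink_dur = c(0.10, 0.30),
    dip_rate = 0.10, dip_dur = c(0.03, 0.07), dip_depth = c(1.5, 2.5),
    left_eye_blink_mult = 1.5, both_eyes = TRUE,
    sentence_dur = c(2.2, 2.8), sentence_gap = 3.5, first_onset_s = 3.0,
    repeat_prob = 0.98,
    age_mean = 58, age_sd = 11.3, age_range = c(22, 73),
    pta_mean = 49.2, pta_sd = 11.5,
    rs_mean = 41.8, rs_sd = 12.1,
    seed = NULL
  )
  if (preset == "small") {
    cfg$n_participants <- 6L
    cfg$n_lists <- 6L
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$n_lists %% 2L != 0L) {
    stop("n_lists must be even (half per noise-reduction condition)")
  }
  stopifnot(
    cfg$sigma_participant >= 0, cfg$sigma_trial >= 0, cfg$amp_sd >= 0,
    cfg$noise_sd >= 0, cfg$blink_rate >= 0, cfg$dip_rate >= 0,
    cfg$repeat_prob > 0, cfg$repeat_prob <= 1,
    length(cfg$position_profile) == cfg$list_length
  )
  structure(cfg, class = "sim_config")
}

# Event-locked pupil dilation kernel: gamma-like rise/decay peaking at
# `peak_s` with unit amplitude, cosine-tapered to exactly zero by the end of
# the response window so successive baselines are uncontaminated.
pupil_kernel <- function(t, peak_s = 2.0, shape = 8, taper = c(3.5, 4.0)) {
  k <- numeric(length(t))
  inside <- t > 0 & t < taper[2]
  x <- t[inside]
  v <- (x / peak_s)^shape * exp(shape * (1 - x / peak_s))
  tp <- x > taper[1]
  v[tp] <- v[tp] * 0.5 * (1 + cos(pi * (x[tp] - taper[1]) / (taper[2] - taper[1])))
  k[inside] <- v
  k
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) {
    i <- x < lower
    x[i] <- stats::rnorm(sum(i), mean, sd)
  }
  x
}

sim_participants <- function(cfg) {
  np <- cfg$n_participants
  pta_base <- clamp(stats::rnorm(np, cfg$pta_mean, cfg$pta_sd), 25, 75)
  rs_raw <- clamp(stats::rnorm(np, cfg$rs_mean, cfg$rs_sd), 0, 100)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(np)),
    age = round(clamp(
      stats::rnorm(np, cfg$age_mean, cfg$age_sd),
      cfg$age_range[1], cfg$age_range[2]
    )),
    pta_left = round(clamp(pta_base + stats::rnorm(np, 0, 2), 0, 90), 1),
    pta_right = round(clamp(pta_base + stats::rnorm(np, 0, 2), 0, 90), 1),
    rs_score = round(rs_raw / 100 * 24) / 24 * 100
  )
}

#' Simulate a complete synthetic study
#'
#' Generates raw two-eye pupil sample tables, an event table and a
#' participant table with known ground truth. Per sentence a latent dilation
#' amplitude `a` is drawn; the recall outcome is Bernoulli with logit
#' `b0 + b_ppd (a - mean) + b_rs RS_c + b_nr NR + b_age age_c + b_pta PTA_c +
#' u_participant + position effect`. The trace is participant baseline + slow
#' sinusoidal drift + event-locked dilations of amplitude `a` peaking ~2 s
#' post-onset + white measurement noise, with blinks inserted as tracker
#' dropouts and brief partial-closure dips. The babble-noise timing follows
#' the paradigm: 3 s lead before sentence 1, 1 s before sentences 2-7.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; same seed gives bit-identical output. Falls back
#'   to `config$seed`; when both are `NULL` the current RNG state is used.
#' @return A list with `samples`, `events`, `participants` (the three study
#'   tables) and `truth` (per-trial latent amplitude, linear predictor and
#'   recall probability, plus participant and position effects).
#' @export
simulate_study <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  rate <- cfg$sample_rate
  np <- cfg$n_participants
  nl <- cfg$n_lists
  ns <- cfg$list_length

  parts <- sim_participants(cfg)
  age_c <- parts$age - mean(parts$age)
  pta_c <- (parts$pta_left + parts$pta_right) / 2 -
    mean((parts$pta_left + parts$pta_right) / 2)
  rs_c <- parts$rs_score - mean(parts$rs_score)
  u_p <- stats::rnorm(np, 0, cfg$sigma_participant)
  u_pos <- stats::rnorm(ns, 0, cfg$sigma_trial)
  pos_eff <- cfg$position_profile + u_pos
  baseline_p <- rnorm_trunc(np, cfg$baseline_mean, cfg$baseline_sd, 2.0)

  b <- cfg$beta
  event_rows <- vector("list", np * nl)
  truth_rows <- vector("list", np * nl)
  sample_rows <- vector("list", np * nl * (1L + cfg$both_eyes))
  s_i <- 0L

  # sample-grid index range for a time interval (t[i] = (i-1)/rate)
  idx_range <- function(a, b, n_total) {
    i0 <- max(1L, as.integer(floor(a * rate)) + 2L)
    i1 <- min(n_total, as.integer(ceiling(b * rate)))
    if (i0 > i1) integer(0) else i0:i1
  }

  noisy_eye <- function(clean, t, n_total, blink_rate) {
    sig <- clean + stats::rnorm(n_total, 0, cfg$noise_sd)
    t_end <- t[n_total]
    nd <- stats::rpois(1, cfg$dip_rate * t_end)
    if (nd > 0) {
      centers <- stats::runif(nd, 0, t_end)
      half <- stats::runif(nd, cfg$dip_dur[1], cfg$dip_dur[2]) / 2
      depth <- stats::runif(nd, cfg$dip_depth[1], cfg$dip_depth[2])
      for (d in seq_len(nd)) {
        idx <- idx_range(centers[d] - half[d], centers[d] + half[d], n_total)
        if (length(idx)) {
          sig[idx] <- pmax(
            sig[idx] - depth[d] * (1 - abs(t[idx] - centers[d]) / half[d]),
            0.3
          )
        }
      }
    }
    nb <- stats::rpois(1, blink_rate * t_end)
    if (nb > 0) {
      starts <- stats::runif(nb, 0, t_end)
      durs <- stats::runif(nb, cfg$blink_dur[1], cfg$blink_dur[2])
      for (d in seq_len(nb)) {
        idx <- idx_range(starts[d], starts[d] + durs[d], n_total)
        sig[idx] <- NA_real_
      }
    }
    sig
  }

  for (p in seq_len(np)) {
    conds <- sample(rep(c("on", "off"), each = nl / 2L))
    for (l in seq_len(nl)) {
      lid <- sprintf("L%02d", l)
      durs <- stats::runif(ns, cfg$sentence_dur[1], cfg$sentence_dur[2])
      onsets <- numeric(ns)
      onsets[1] <- cfg$first_onset_s
      for (k in seq_len(ns - 1L)) {
        onsets[k + 1L] <- onsets[k] + durs[k] + cfg$sentence_gap
      }
      onsets <- round(onsets * rate) / rate # stimulus clock on sample grid
      offsets <- round((onsets + durs) * rate) / rate

      a <- rnorm_trunc(ns, cfg$amp_mean, cfg$amp_sd, cfg$amp_min)
      nr <- conds[l]
      eta <- b[["intercept"]] + b[["ppd"]] * (a - cfg$amp_mean) +
        b[["rs_score"]] * rs_c[p] + b[["noise_reduction"]] * (nr == "on") +
        b[["age"]] * age_c[p] + b[["pta"]] * pta_c[p] +
        u_p[p] + pos_eff
      pr <- stats::plogis(eta)
      recalled <- stats::rbinom(ns, 1, pr) == 1
      repeated <- stats::rbinom(ns, 1, cfg$repeat_prob) == 1

      event_rows[[(p - 1L) * nl + l]] <- tibble::tibble(
        participant_id = parts$participant_id[p], list_id = lid,
        position = seq_len(ns),
        sentence_onset_s = onsets, sentence_offset_s = offsets,
        noise_reduction = nr, repeated_correct = repeated,
        recalled = recalled
      )
      truth_rows[[(p - 1L) * nl + l]] <- tibble::tibble(
        participant_id = parts$participant_id[p], list_id = lid,
        position = seq_len(ns), amplitude = a, eta = eta, p_recall = pr,
        recalled = recalled
      )

      t_end <- onsets[ns] + 5.0
      n_total <- as.integer(round(t_end * rate)) + 1L
      t <- (seq_len(n_total) - 1L) / rate
      clean <- rep(baseline_p[p], n_total)
      if (cfg$drift_amp > 0) {
        ph <- stats::runif(2, 0, 2 * pi)
        clean <- clean + cfg$drift_amp * (
          sin(2 * pi * t / cfg$drift_periods[1] + ph[1]) +
            0.6 * sin(2 * pi * t / cfg$drift_periods[2] + ph[2])) / 1.6
      }
      for (k in seq_len(ns)) {
        i0 <- as.integer(round(onsets[k] * rate)) + 1L
        i1 <- min(i0 + as.integer(cfg$kernel_taper[2] * rate), n_total)
        idx <- i0:i1
        clean[idx] <- clean[idx] + a[k] * pupil_kernel(
          t[idx] - onsets[k],
          peak_s = cfg$kernel_peak_s, shape = cfg$kernel_shape,
          taper = cfg$kernel_taper
        )
      }
      s_i <- s_i + 1L
      sample_rows[[s_i]] <- tibble::tibble(
        participant_id = parts$participant_id[p], list_id = lid,
        eye = "right", time_s = t,
        pupil = noisy_eye(clean, t, n_total, cfg$blink_rate)
      )
      if (cfg$both_eyes) {
        s_i <- s_i + 1L
        sample_rows[[s_i]] <- tibble::tibble(
          participant_id = parts$participant_id[p], list_id = lid,
          eye = "left", time_s = t,
          pupil = noisy_eye(
            clean, t, n_total,
            cfg$blink_rate * cfg$left_eye_blink_mult
          )
        )
      }
    }
  }

  samples <- dplyr::bind_rows(sample_rows[seq_len(s_i)])
  list(
    samples = samples,
    events = dplyr::bind_rows(event_rows),
    participants = parts,
    truth = list(
      trials = dplyr::bind_rows(truth_rows),
      u_participant = stats::setNames(u_p, parts$participant_id),
      position_effects = pos_eff,
      config = cfg
    )
  )
}

#' Simulate trial features directly (no traces)
#'
#' Fast path that draws the latent amplitudes and recall outcomes of
#' [simulate_study()] but emits the trial-feature table directly, with
#' `ppd = amplitude + N(0, ppd_noise_sd)`. Used for calibration studies of
#' the inference machinery (for example null simulations at scale), where
#' generating and cleaning raw traces adds nothing.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param ppd_noise_sd Measurement noise added to the latent amplitude.
#' @param beta_ppd_sq Optional quadratic coefficient on the centered latent
#'   amplitude (an inverted-U recall link when negative); 0 keeps the link
#'   linear.
#' @return A trial-feature tibble ready for [fit_recall_glmm()], with the
#'   latent `amplitude` column retained.
#' @export
simulate_features <- function(config = sim_config(), seed = NULL,
                              ppd_noise_sd = 0, beta_ppd_sq = 0) {
  cfg <- config
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(seed)) set.seed(seed)
  np <- cfg$n_participants
  nl <- cfg$n_lists
  ns <- cfg$list_length
  parts <- sim_participants(cfg)
  age_c <- parts$age - mean(parts$age)
  pta <- (parts$pta_left + parts$pta_right) / 2
  pta_c <- pta - mean(pta)
  rs_c <- parts$rs_score - mean(parts$rs_score)
  u_p <- stats::rnorm(np, 0, cfg$sigma_participant)
  u_pos <- stats::rnorm(ns, 0, cfg$sigma_trial)
  pos_eff <- cfg$position_profile + u_pos

  n <- np * nl * ns
  p_idx <- rep(seq_len(np), each = nl * ns)
  l_idx <- rep(rep(seq_len(nl), each = ns), times = np)
  pos <- rep(seq_len(ns), times = np * nl)
  conds <- character(np * nl)
  for (p in seq_len(np)) {
    conds[(p - 1L) * nl + seq_len(nl)] <-
      sample(rep(c("on", "off"), each = nl / 2L))
  }
  nr <- conds[(p_idx - 1L) * nl + l_idx]
  a <- rnorm_trunc(n, cfg$amp_mean, cfg$amp_sd, cfg$amp_min)
  b <- cfg$beta
  eta <- b[["intercept"]] + b[["ppd"]] * (a - cfg$amp_mean) +
    beta_ppd_sq * (a - cfg$amp_mean)^2 +
    b[["rs_score"]] * rs_c[p_idx] + b[["noise_reduction"]] * (nr == "on") +
    b[["age"]] * age_c[p_idx] + b[["pta"]] * pta_c[p_idx] +
    u_p[p_idx] + pos_eff[pos]
  recalled <- stats::rbinom(n, 1, stats::plogis(eta)) == 1
  ppd <- a + if (ppd_noise_sd > 0) stats::rnorm(n, 0, ppd_noise_sd) else 0
  tibble::tibble(
    participant_id = parts$participant_id[p_idx],
    list_id = sprintf("L%02d", l_idx),
    position = pos,
    noise_reduction = nr,
    baseline = cfg$baseline_mean,
    ppd = ppd,
    amplitude = a,
    fraction_valid = 1,
    repeated_correct = stats::rbinom(n, 1, cfg$repeat_prob) == 1,
    recalled = recalled,
    age = parts$age[p_idx],
    pta = pta[p_idx],
    rs_score = parts$rs_score[p_idx]
  )
}

#' End-to-end parameter recovery study
#'
#' Repeatedly simulates a study, runs the full pipeline (eye selection, blink
#' cleaning, validity filtering, feature extraction, repeated-word filtering,
#' model fit) and summarises how well each generative parameter is recovered:
#' bias, RMSE and Wald-CI coverage per fixed effect, plus an attenuation
#' oracle for the PPD slope obtained by refitting each replicate with the
#' true latent amplitudes in place of extracted PPD (measurement noise in the
#' extracted PPD attenuates the fitted slope; the oracle shows the ceiling).
#'
#' @param config A [sim_config()] with nonzero effects (typically the
#'   `"small"` preset).
#' @param n_replicates Number of replicate studies.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param progress Print a dot per replicate.
#' @return A list with `estimates` (one row per replicate x parameter) and
#'   `summary` (per parameter: true value, mean estimate, bias, RMSE,
#'   coverage, and for `ppd` the mean oracle estimate).
#' @export
end_to_end_recovery <- function(config = sim_config("small"),
                                n_replicates = 100, seed = 1,
                                progress = FALSE) {
  rows <- vector("list", n_replicates)
  truth_beta <- c(
    "(Intercept)" = unname(config$beta[["intercept"]]),
    ppd = unname(config$beta[["ppd"]]),
    rs_score = unname(config$beta[["rs_score"]]),
    noise_reduction = unname(config$beta[["noise_reduction"]]),
    age = unname(config$beta[["age"]]),
    pta = unname(config$beta[["pta"]])
  )
  for (r in seq_len(n_replicates)) {
    sim <- simulate_study(config, seed = seed + r)
    cleaned <- clean_study(sim$samples, sim$events,
      rate = config$sample_rate, validate = FALSE
    )
    feats <- extract_features(cleaned, sim$events, sim$participants,
      rate = config$sample_rate
    )
    feats <- filter_repeated(feats)
    fit <- fit_recall_glmm(feats)
    tkey <- paste(
      sim$truth$trials$participant_id, sim$truth$trials$list_id,
      sim$truth$trials$position
    )
    oracle_feats <- feats
    oracle_feats$ppd <- sim$truth$trials$amplitude[
      match(
        paste(feats$participant_id, feats$list_id, feats$position),
        tkey
      )
    ]
    oracle_fit <- fit_recall_glmm(oracle_feats)
    co <- fit$coefficients
    rows[[r]] <- tibble::tibble(
      replicate = r,
      term = co$term,
      true = unname(truth_beta[co$term]),
      estimate = co$estimate,
      se = co$se,
      ci_lo = co$ci_lo,
      ci_hi = co$ci_hi,
      covered = co$ci_lo <= unname(truth_beta[co$term]) &
        unname(truth_beta[co$term]) <= co$ci_hi,
      oracle_estimate = oracle_fit$coefficients$estimate[
        match(co$term, oracle_fit$coefficients$term)
      ],
      sigma_participant = fit$sigma[["participant"]],
      sigma_trial = fit$sigma[["trial"]],
      converged = fit$converged
    )
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  estimates <- dplyr::bind_rows(rows)
  summary <- estimates |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      true = .data$true[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$true),
      rmse = sqrt(mean((.data$estimate - .data$true)^2)),
      coverage = mean(.data$covered),
      mean_oracle = mean(.data$oracle_estimate),
      .groups = "drop"
    )
  list(estimates = estimates, summary = summary)
}

#' HINT adaptive SNR staircase
#'
#' Sequential update of the signal-to-noise ratio during the hearing-in-noise
#' test: starting from 0 dB (speech and babble both at 70 dB SPL), the SNR
#' decreases by 0.8 dB after a correctly repeated sentence and increases by
#' 3.2 dB otherwise; for the first five sentences the step sizes are doubled
#' (-1.6 / +6.4 dB).
#'
#' @param responses Logical vector of per-sentence correctness, in order.
#' @param start_snr Starting SNR in dB.
#' @return Final SNR in dB, with the full trajectory (SNR after each
#'   sentence) as attribute `"trajectory"`.
#' @export
hint_staircase <- function(responses, start_snr = 0) {
  if (length(responses) == 0L) stop("empty response sequence")
  snr <- start_snr
  traj <- numeric(length(responses))
  for (i in seq_along(responses)) {
    mult <- if (i <= 5L) 2 else 1
    snr <- snr + mult * (if (responses[i]) -0.8 else 3.2)
    traj[i] <- snr
  }
  attr(snr, "trajectory") <- traj
  snr
}

#' SWIR training SNR adjustment
#'
#' Adjustment of the HINT-derived SNR after a SWIR training list, based on
#' how many of the seven last words were repeated correctly: 6-7 correct
#' (86-100%) leaves the SNR unchanged, 4-5 correct adds 1 dB, 0-3 correct
#' adds 2 dB.
#'
#' @param n_correct_of_7 Integer count of correctly repeated last words, 0-7.
#' @return SNR increment in dB (0, 1 or 2).
#' @export
swir_snr_adjust <- function(n_correct_of_7) {
  if (any(n_correct_of_7 < 0 | n_correct_of_7 > 7 |
    n_correct_of_7 != round(n_correct_of_7))) {
    stop("n_correct_of_7 must be an integer in 0..7")
  }
  ifelse(n_correct_of_7 >= 6, 0, ifelse(n_correct_of_7 >= 4, 1, 2))
}

#' Reading Span score
#'
#' Percentage of the 24 target words correctly recalled, irrespective of
#' order. The test presents two lists each of three, four and five
#' three-word sentences (24 target words in total).
#'
#' @param recalled_flags Logical vector of length 24, one per target word.
#' @return Score in percent.
#' @export
rs_score <- function(recalled_flags) {
  if (length(recalled_flags) != 24L) {
    stop("the RS test has 24 target words (two lists each of 3/4/5 sentences)")
  }
  100 * mean(as.logical(recalled_flags))
}
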