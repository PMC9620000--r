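small2 <- function(...) {
  sim_config("small", n_participants = 2L, n_lists = 2L, ...)
}

test_that("the same seed reproduces a study bit-identically", {
  a <- simulate_study(small2(), seed = 7)
  b <- simulate_study(small2(), seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
  expect_identical(a$participants, b$participants)
  expect_identical(a$truth$trials, b$truth$trials)
})

test_that("generated events satisfy the design invariants", {
  sim <- simulate_study(sim_config("small"), seed = 23)
  ev <- sim$events
  expect_silent(validate_event_table(ev))
  per_list <- ev |>
    dplyr::group_by(participant_id, list_id) |>
    dplyr::summarise(
      n = dplyr::n(), nr = noise_reduction[1],
      .groups = "drop"
    )
  expect_true(all(per_list$n == 7))
  # half the lists per participant in each noise-reduction condition
  split <- per_list |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(on = sum(nr == "on"), off = sum(nr == "off"))
  expect_true(all(split$on == split$off))
  # babble timing: first onset 3 s into the list, later onsets spaced enough
  # for a 1 s baseline plus 4 s response window
  first <- ev[ev$position == 1, ]
  expect_true(all(first$sentence_onset_s == 3))
  gaps <- ev |>
    dplyr::group_by(participant_id, list_id) |>
    dplyr::summarise(min_gap = min(diff(sentence_onset_s)), .groups = "drop")
  expect_true(all(gaps$min_gap >= 5))
})

test_that("an intercept-only generator hits the expected recall rate", {
  cfg <- sim_config(
    beta = c(
      intercept = 0.61, ppd = 0, rs_score = 0,
      noise_reduction = 0, age = 0, pta = 0
    ),
    sigma_participant = 0, sigma_trial = 0,
    position_profile = rep(0, 7)
  )
  f <- simulate_features(cfg, seed = 30)
  p0 <- plogis(0.61)
  se <- sqrt(p0 * (1 - p0) / nrow(f))
  expect_lt(abs(mean(f$recalled) - p0), 3 * se)
})

test_that("recall increases with the latent amplitude when the slope is positive", {
  cfg <- sim_config(
    sigma_participant = 0, sigma_trial = 0,
    position_profile = rep(0, 7),
    beta = c(
      intercept = 0.61, ppd = 0.60, rs_score = 0,
      noise_reduction = 0, age = 0, pta = 0
    )
  )
  f <- simulate_features(cfg, seed = 31)
  qs <- quantile(f$ppd, c(0.25, 0.75))
  top <- mean(f$recalled[f$ppd >= qs[2]])
  bottom <- mean(f$recalled[f$ppd <= qs[1]])
  expect_gt(top, bottom)
})

test_that("with the primacy/recency profile on, the last position is recalled best", {
  f <- simulate_features(sim_config(n_participants = 40L), seed = 32)
  by_pos <- tapply(f$recalled, f$position, mean)
  expect_identical(unname(which.max(by_pos)), 7L)
})

test_that("a noiseless, blink-free study returns the latent amplitude as PPD", {
  cfg <- small2(
    noise_sd = 0, drift_amp = 0, blink_rate = 0, dip_rate = 0
  )
  sim <- simulate_study(cfg, seed = 5)
  cl <- clean_study(sim$samples, sim$events)
  fe <- extract_features(cl, sim$events, sim$participants)
  key <- paste(
    sim$truth$trials$participant_id, sim$truth$trials$list_id,
    sim$truth$trials$position
  )
  a <- sim$truth$trials$amplitude[
    match(paste(fe$participant_id, fe$list_id, fe$position), key)
  ]
  expect_lt(max(abs(fe$ppd - a)), 1e-6)
  expect_true(all(cl$trials$fraction_valid == 1))
})

test_that("the truth record reproduces every latent recall probability", {
  sim <- simulate_study(small2(), seed = 41)
  tr <- sim$truth$trials
  parts <- sim$participants
  age_c <- parts$age - mean(parts$age)
  pta_c <- (parts$pta_left + parts$pta_right) / 2 -
    mean((parts$pta_left + parts$pta_right) / 2)
  rs_c <- parts$rs_score - mean(parts$rs_score)
  cfg <- sim$truth$config
  i <- match(tr$participant_id, parts$participant_id)
  ev <- sim$events
  nr <- ev$noise_reduction[match(
    paste(tr$participant_id, tr$list_id, tr$position),
    paste(ev$participant_id, ev$list_id, ev$position)
  )]
  eta <- cfg$beta[["intercept"]] +
    cfg$beta[["ppd"]] * (tr$amplitude - cfg$amp_mean) +
    cfg$beta[["rs_score"]] * rs_c[i] +
    cfg$beta[["noise_reduction"]] * (nr == "on") +
    cfg$beta[["age"]] * age_c[i] + cfg$beta[["pta"]] * pta_c[i] +
    sim$truth$u_participant[tr$participant_id] +
    sim$truth$position_effects[tr$position]
  expect_equal(unname(eta), tr$eta, tolerance = 1e-12)
  expect_equal(plogis(tr$eta), tr$p_recall)
})

test_that("the HINT staircase applies doubled steps for the first five sentences", {
  expect_equal(as.numeric(hint_staircase(TRUE)), -1.6)
  expect_equal(as.numeric(hint_staircase(FALSE)), 6.4)

  # sixth sentence: normal step sizes resume
  resp <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  s5 <- as.numeric(hint_staircase(resp[1:5]))
  expect_equal(as.numeric(hint_staircase(resp)), s5 + 3.2)
  resp[6] <- TRUE
  expect_equal(as.numeric(hint_staircase(resp)), s5 - 0.8)

  # trajectories are ordered: all-correct below all-incorrect
  n <- 12
  expect_lt(
    as.numeric(hint_staircase(rep(TRUE, n))),
    as.numeric(hint_staircase(rep(FALSE, n)))
  )
  expect_error(hint_staircase(logical(0)), "empty")
})

test_that("the SWIR training SNR adjustment follows the banded rule", {
  expect_equal(swir_snr_adjust(7), 0)
  expect_equal(swir_snr_adjust(6), 0)
  expect_equal(swir_snr_adjust(5), 1)
  expect_equal(swir_snr_adjust(4), 1)
  expect_equal(swir_snr_adjust(3), 2)
  expect_equal(swir_snr_adjust(0), 2)
  expect_error(swir_snr_adjust(8), "0..7")
  expect_error(swir_snr_adjust(-1), "0..7")
})

test_that("the Reading Span score is the percentage of 24 target words", {
  expect_equal(rs_score(rep(TRUE, 24)), 100)
  expect_equal(rs_score(c(rep(TRUE, 10), rep(FALSE, 14))), 100 * 10 / 24)
  expect_equal(round(rs_score(c(rep(TRUE, 10), rep(FALSE, 14))), 2), 41.67)
  expect_equal(rs_score(rep(FALSE, 24)), 0)
  expect_error(rs_score(rep(TRUE, 20)), "24 target words")
})
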