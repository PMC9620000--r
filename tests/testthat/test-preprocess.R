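test_that("a constant trace produces no blink flags", {
  expect_length(detect_blinks(rep(4, 3000)), 0)
})

test_that("blink detection matches a brute-force windowed oracle", {
  # deep rectangular dip, far below the local mean
  x <- rep(4, 2400) + rnorm(2400, 0, 0.02)
  x[1000:1049] <- x[1000:1049] - 3
  expect_identical(detect_blinks(x), brute_detect_blinks(x))

  # random traces with dips and dropouts, various lengths
  for (seed in 1:5) {
    n <- c(500, 1500, 2400, 3600, 5000)[seed]
    x <- random_trace(n, seed)
    expect_identical(
      detect_blinks(x, rate = 1200),
      brute_detect_blinks(x, rate = 1200)
    )
  }

  # shrunk edge windows, short trace
  x <- random_trace(800, 99)
  expect_identical(detect_blinks(x), brute_detect_blinks(x))
})

test_that("already-missing samples are flagged like blinks", {
  x <- rep(4, 3000)
  x[100:120] <- NA
  expect_identical(detect_blinks(x), 100:120)
  expect_error(detect_blinks(rep(NA_real_, 100)), "all samples")
})

test_that("padded removal covers exactly the union of padded runs", {
  expect_identical(nrow(pad_and_remove(integer(0), 1000)), 0L)

  # single flagged sample: 77 before, 181 after, inclusive
  seg <- pad_and_remove(1001, 5000)
  expect_identical(seg$start, 924L)
  expect_identical(seg$end, 1182L)
  expect_identical(sum(seg$end - seg$start + 1L), 259L)

  # clipping at the edges
  seg <- pad_and_remove(c(10, 4995), 5000)
  expect_identical(seg$start, c(1L, 4918L))
  expect_identical(seg$end, c(191L, 5000L))

  # overlapping padded runs merge; index set equals brute-force union
  for (seed in 1:5) {
    set.seed(seed)
    n <- 5000
    flags <- sort(sample(n, 40))
    seg <- pad_and_remove(flags, n)
    got <- which(segments_to_mask(seg, n))
    expect_identical(got, brute_pad_union(flags, n))
    expect_true(all(seg$start[-1] > seg$end[-nrow(seg)] + 1))
  }
})

test_that("linear interpolation is exact on a ramp and matches the closed form", {
  # gap punched into an exact line
  x <- seq(3, 5, length.out = 1000)
  seg <- tibble::tibble(start = 400L, end = 500L)
  out <- interpolate_gaps(replace(x, 400:500, NA), seg)
  expect_equal(out$pupil, x, tolerance = 1e-12)
  expect_equal(out$fraction, 101 / 1000)

  # i-th filled value between anchors a and b is a + (b - a) i / (n + 1)
  a <- 4
  b <- 6
  x <- c(rep(a, 5), rep(NA, 3), rep(b, 5))
  out <- interpolate_gaps(x, tibble::tibble(start = 6L, end = 8L))
  expect_equal(out$pupil[6:8], a + (b - a) * (1:3) / 4)

  # no gaps: unchanged, fraction 0
  x <- 4 + rnorm(100, 0, 0.01)
  out <- interpolate_gaps(x, tibble::tibble(start = integer(0), end = integer(0)))
  expect_identical(out$pupil, x)
  expect_identical(out$fraction, 0)
})

test_that("interpolation never alters survivors and is bounded by its anchors", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- 4 + rnorm(2000, 0, 0.2)
    flags <- sort(sample(2000, 8))
    seg <- pad_and_remove(flags, 2000, pre_samples = 10, post_samples = 20)
    out <- interpolate_gaps(x, seg)
    keep <- !out$interpolated
    expect_identical(out$pupil[keep], x[keep])
    expect_true(all(out$pupil >= min(x, na.rm = TRUE) &
      out$pupil <= max(x, na.rm = TRUE)))
  }
})

test_that("leading and trailing gaps are held at the nearest value", {
  x <- c(NA, NA, 4, 5, NA)
  out <- interpolate_gaps(x, pad_and_remove(detect_blinks(x, rate = 2, window_s = 1), 5,
    pre_samples = 0, post_samples = 0
  ))
  expect_equal(out$pupil, c(4, 4, 4, 5, 5))
  expect_equal(out$fraction, 3 / 5)
})

test_that("trial validity keeps exactly-60% trials and discards below", {
  removed <- rep(FALSE, 1000)
  expect_true(trial_validity(removed, 1:1000)$kept)
  expect_equal(trial_validity(removed, 1:1000)$fraction_valid, 1)

  removed <- c(rep(TRUE, 400), rep(FALSE, 600)) # exactly 60% valid
  tv <- trial_validity(removed, 1:1000)
  expect_equal(tv$fraction_valid, 0.6)
  expect_true(tv$kept)

  removed <- c(rep(TRUE, 401), rep(FALSE, 599)) # 59.9% valid
  expect_false(trial_validity(removed, 1:1000)$kept)

  expect_error(trial_validity(removed, integer(0)), "empty")
})

test_that("participant exclusion uses the strict more-than-15% rule", {
  expect_true(participant_validity(rep(TRUE, 196)))
  expect_false(participant_validity(c(rep(FALSE, 30), rep(TRUE, 166)))) # 15.3%
  expect_true(participant_validity(c(rep(FALSE, 29), rep(TRUE, 167)))) # 14.8%
  expect_error(participant_validity(logical(0)), "zero trials")
})

test_that("re-running the cleaning stage on its own output is near-idempotent", {
  # after interpolation nothing is missing, so a second pass can only act
  # through the threshold rule; the interpolated spans carry no noise, which
  # tightens the local SD slightly, so a handful of marginal samples may be
  # re-flagged -- but the re-flag rate must be negligible next to the first
  # pass, and surviving values must be untouched
  cfg <- sim_config("small", n_participants = 2L, n_lists = 2L)
  sim <- simulate_study(cfg, seed = 31)
  s <- sim$samples
  tr <- s[s$participant_id == "P001" & s$list_id == "L01" & s$eye == "right", ]
  pass1 <- preprocess_trace(tr$pupil)
  expect_false(anyNA(pass1$pupil))
  flags1 <- detect_blinks(tr$pupil)
  flags2 <- detect_blinks(pass1$pupil)
  expect_lt(length(flags2) / nrow(tr), 0.001)
  expect_lt(length(flags2), 0.05 * length(flags1))
  pass2 <- preprocess_trace(pass1$pupil)
  keep2 <- !pass2$removed
  expect_identical(pass2$pupil[keep2], pass1$pupil[keep2])
})
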