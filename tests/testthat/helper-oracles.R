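# Independent brute-force oracles used to validate the vectorized
# preprocessing primitives. Deliberately written as per-sample loops so that
# they share no code with the implementation under test.

brute_detect_blinks <- function(pupil, rate = 1200, window_s = 1, k = 3) {
  n <- length(pupil)
  w <- as.integer(round(window_s * rate))
  before <- w %/% 2L
  after <- w - before - 1L
  out <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(pupil[i])) {
      out <- c(out, i)
      next
    }
    win <- pupil[max(1L, i - before):min(n, i + after)]
    win <- win[!is.na(win)]
    if (length(win) >= 2L) {
      if (pupil[i] < mean(win) - k * stats::sd(win)) out <- c(out, i)
    }
  }
  out
}

brute_pad_union <- function(flags, n, pre = 77, post = 181) {
  removed <- logical(n)
  for (f in flags) {
    removed[max(1L, f - pre):min(n, f + post)] <- TRUE
  }
  which(removed)
}

# random test traces: smooth base + noise, with optional dips and dropouts
random_trace <- function(n, seed, dip = TRUE, dropout = TRUE) {
  set.seed(seed)
  x <- 4 + 0.2 * sin(2 * pi * seq_len(n) / (n / 3)) + rnorm(n, 0, 0.05)
  if (dip) {
    at <- sample(seq_len(n - 60), 2)
    for (a in at) x[a:(a + 40)] <- x[a:(a + 40)] - runif(1, 1, 3)
  }
  if (dropout) {
    at <- sample(seq_len(n - 120), 2)
    for (a in at) x[a:(a + sample(30:100, 1))] <- NA
  }
  x
}

# minimal well-formed sample table
make_sample_table <- function(pupil, pid = "P1", lid = "L1", eye = "right",
                              rate = 1200) {
  tibble::tibble(
    participant_id = pid, list_id = lid, eye = eye,
    time_s = (seq_along(pupil) - 1) / rate, pupil = pupil
  )
}
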