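test_that("HRF kernel has the canonical shape", {
  h <- hrf_kernel(FS)
  expect_equal(max(h), 1)
  peak_s <- (which.max(h) - 1) / FS
  expect_gte(peak_s, 4); expect_lte(peak_s, 8)
  expect_gt(sum(h) / FS, 0)
  expect_lte(length(h) / FS, 30 + 1 / FS)
  # doubling the sampling rate keeps the peak location within one sample
  h2 <- hrf_kernel(2 * FS)
  expect_lte(abs((which.max(h2) - 1) / (2 * FS) - peak_s), 1 / FS)
  expect_error(hrf_kernel(FS, peak_delay = -1), "positive")
})

test_that("delayed kernel rises ~onset_delay later without long tails", {
  h <- hrf_kernel(FS, onset_delay = 10)
  peak_s <- (which.max(h) - 1) / FS
  expect_gte(peak_s, 13); expect_lte(peak_s, 17)
  # recovered (except undershoot) by 30 s: positive lobe below 5% of peak
  late <- h[seq(floor(30 * FS), length(h))]
  expect_lt(max(late), 0.05)
})

test_that("noise-free sessions are lateralized by construction", {
  p <- quiet_params(trials_per_condition = 3, seed = 7)
  for (cond in c("execution", "imagery")) {
    rec <- generate_session(p, cond)
    trials <- slice_trials(rec)
    for (tr in trials) {
      pd <- pair_differences(baseline_correct(tr), DEFAULT_PAIRS)
      sgn <- if (tr$hand == "right") 1 else -1
      expect_true(all(sgn * pd$d_hbo > 0))
      expect_true(all(sgn * pd$d_hbr < 0))
    }
  }
})

test_that("same seed gives bit-identical recordings", {
  p <- synth_params(trials_per_condition = 2, seed = 12)
  r1 <- generate_session(p, "imagery")
  r2 <- generate_session(p, "imagery")
  expect_identical(r1$hbo, r2$hbo)
  expect_identical(r1$events, r2$events)
  p2 <- synth_params(trials_per_condition = 2, seed = 13)
  expect_false(identical(generate_session(p2, "imagery")$hbo, r1$hbo))
})

test_that("injected physiological noise peaks at 0.1, 0.25 and 1 Hz", {
  # oscillations only: no response, no white noise, no drift
  p <- synth_params(trials_per_condition = 6, exec_amplitude = 0,
                    white_sd = 0, drift = 0, seed = 3)
  rec <- generate_session(p, "execution")
  x <- rec$hbo[, 1] - mean(rec$hbo[, 1])
  n <- length(x)
  spec <- Mod(stats::fft(x))[1:(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) * FS / n
  for (f0 in c(0.1, 0.25, 1.0)) {
    band <- which(abs(freq - f0) < 0.05)
    peak_f <- freq[band[which.max(spec[band])]]
    expect_lte(abs(peak_f - f0), FS / n + 1e-9)   # within one FFT bin
  }
})

test_that("HbO/HbR are anti-correlated in active channels at zero noise", {
  rec <- generate_session(quiet_params(trials_per_condition = 3, seed = 5),
                          "execution")
  for (ch in c("2", "7", "8", "12", "17", "18")) {
    expect_lt(stats::cor(rec$hbo[, ch], rec$hbr[, ch]), -0.9)
  }
  # laterality of task-window means, trial by trial
  for (tr in slice_trials(rec)) {
    wa <- window_average(baseline_correct(tr))
    if (tr$hand == "right") {
      expect_true(all(wa$hbo[c("2", "7", "8")] >
                        wa$hbo[c("12", "17", "18")]))
    } else {
      expect_true(all(wa$hbo[c("12", "17", "18")] >
                        wa$hbo[c("2", "7", "8")]))
    }
  }
})

test_that("band-pass removes >= 90% of the 0.25 and 1 Hz injected power", {
  p <- synth_params(trials_per_condition = 6, exec_amplitude = 0,
                    white_sd = 0, drift = 0, mayer_amp = 0, seed = 9)
  rec <- generate_session(p, "execution")
  raw <- rec$hbo[, 1]
  filt <- bandpass(raw, FS)
  trim <- round(100 * FS)
  mid <- (trim + 1):(length(raw) - trim)
  expect_lt(mean(filt[mid]^2) / mean(raw[mid]^2), 0.1)
})

test_that("benchmark grids enumerate sessions with a faithful manifest", {
  p <- synth_params(trials_per_condition = 2)
  bench <- generate_benchmark(p, snr = c(1, 2, 3),
                              conditions = c("execution", "imagery"),
                              seed = 100)
  expect_length(bench$sessions, 6)
  expect_equal(nrow(bench$manifest), 6)
  expect_equal(bench$manifest$n_trials, rep(4, 6))
  # manifest round-trips through the text writer
  path <- tempfile(fileext = ".tsv")
  utils::write.table(bench$manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- utils::read.delim(path)
  expect_equal(back, bench$manifest)
})

test_that("classification accuracy degrades monotonically with noise", {
  acc_at <- function(snr) {
    accs <- vapply(1:3, function(s) {
      trials <- make_trials(10, "execution", snr = snr, seed = 50 + s)
      dec <- classify_session(trials, DEFAULT_PAIRS)
      mean(dec$label == dec$true_hand)
    }, numeric(1))
    mean(accs)
  }
  a <- vapply(c(3, 0.75, 0.2), acc_at, numeric(1))
  expect_true(all(diff(a) <= 0.05))   # non-increasing up to seed jitter
  expect_gt(a[1], a[3])
})
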