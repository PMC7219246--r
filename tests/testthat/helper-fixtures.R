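# Shared fixtures: everything is generated in code at test time.

FS <- 7.8125
DEFAULT_PAIRS <- cbind(left = c(2, 7, 8), right = c(12, 17, 18))

# filtered, sliced trials of one synthetic session
make_trials <- function(n_per_hand = 10, condition = "execution", snr = 3,
                        seed = 1, filter = TRUE, ...) {
  p <- synth_params(trials_per_condition = n_per_hand, snr = snr,
                    seed = seed, ...)
  rec <- generate_session(p, condition)
  if (filter) rec <- bandpass(rec)
  slice_trials(rec)
}

# a flat trial with constant per-channel values (20 channels)
constant_trial <- function(values, fs = FS, hand = "right",
                           condition = "execution", hbr = -values / 3) {
  n <- trial_length(fs)
  fnirs_trial(matrix(values, n, 20, byrow = TRUE),
              matrix(hbr, n, 20, byrow = TRUE),
              fs, hand, condition)
}

# noise-free recording with a single constant lateralized offset, used where
# deterministic window averages are needed
quiet_params <- function(...) {
  synth_params(white_sd = 0, mayer_amp = 0, resp_amp = 0, cardiac_amp = 0,
               drift = 0, ...)
}

# brute-force oracle for the sign + empirical-CDF quartile filter
brute_quartile <- function(d, chromophore, q) {
  keep <- if (chromophore == "HbO") d > 0 else d < 0
  vals <- abs(d)[keep]
  out <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (i in seq_len(nrow(d))) for (j in seq_len(ncol(d))) {
    if (!keep[i, j]) next
    v <- abs(d[i, j])
    if (sum(vals <= v) / length(vals) >= q) out[i, j] <- v
  }
  out
}

# amplitude of a (filtered) sinusoid estimated away from the edges
sine_amplitude <- function(x, fs, trim_s = 100) {
  k <- round(trim_s * fs)
  mid <- x[(k + 1):(length(x) - k)]
  sqrt(2) * stats::sd(mid)
}
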