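test_that("window averages: constants, ramp oracle, index arithmetic", {
  tr <- constant_trial(seq(-1, 1, length.out = 20))
  wa <- window_average(tr)
  expect_equal(unname(wa$hbo), seq(-1, 1, length.out = 20))
  expect_equal(unname(wa$hbr), -seq(-1, 1, length.out = 20) / 3)
  # [5,20) at fs = 7.8125 covers 117 samples
  idx <- window_indices(c(5, 20), FS)
  expect_length(idx, 117)
  # linear ramp 0 -> 1 across exactly the window: discrete mean 0.5 +/- 1/(2n)
  n <- trial_length(FS)
  x <- matrix(0, n, 20)
  x[idx, ] <- seq(0, 1, length.out = length(idx))
  tr2 <- fnirs_trial(x, x, FS, "left", "execution")
  expect_equal(unname(window_average(tr2)$hbo[1]), 0.5,
               tolerance = 1 / (2 * length(idx)))
  expect_error(window_average(tr2, c(10, 10)), "empty window")
  expect_error(window_average(tr2, c(5, 36)), "within")
})

test_that("difference matrices are antisymmetric pairwise differences", {
  dm <- difference_matrix(c(a = 1, b = 2, c = 3), "HbO")
  expect_equal(dm$d["a", "c"], -2)
  expect_equal(dm$d["c", "a"], 2)
  expect_true(all(difference_matrix(rep(1, 5), "HbR")$d == 0))
  set.seed(2)
  d <- difference_matrix(rnorm(8), "HbO")$d
  expect_equal(unname(d + t(d)), matrix(0, 8, 8))
  expect_true(all(diag(d) == 0))
})

test_that("quartile filter matches the brute-force empirical CDF oracle", {
  # 3-channel worked case: averages (0, 0.1, 0.5); kept positive values
  # {0.1, 0.4, 0.5} have F = 1/3, 2/3, 1 -> only 0.5 survives, at (3,1)
  dm <- difference_matrix(c(0, 0.1, 0.5), "HbO")
  cm <- quartile_filter(dm, 0.75)
  expect_equal(sum(cm$delta != 0), 1)
  expect_equal(cm$delta[3, 1], 0.5)
  # ties at the threshold all survive (degenerate CDF)
  dm2 <- difference_matrix(c(0, 1, 2), "HbO")
  dm2$d[dm2$d > 0] <- 1            # all kept values equal -> F = 1 each
  expect_equal(sum(quartile_filter(dm2)$delta != 0), 3)
  # HbR with all-positive differences: zero matrix with warning
  dm3 <- difference_matrix(c(1, 2, 3), "HbR")
  dm3$d[dm3$d < 0] <- 0
  expect_warning(cm3 <- quartile_filter(dm3), "sign filter")
  expect_true(all(cm3$delta == 0))
  # randomized equivalence, both chromophores
  set.seed(5)
  for (chrom in c("HbO", "HbR")) {
    for (rep in 1:25) {
      dm <- difference_matrix(stats::setNames(rnorm(5), 1:5), chrom)
      cm <- quartile_filter(dm, 0.75)
      expect_equal(cm$delta, brute_quartile(dm$d, chrom, 0.75))
    }
  }
})

test_that("surviving entries are a subset of |dH| and respect the quota", {
  set.seed(6)
  for (rep in 1:20) {
    dm <- difference_matrix(stats::setNames(rnorm(6), 1:6), "HbO")
    cm <- quartile_filter(dm, 0.75)
    nz <- which(cm$delta != 0)
    expect_true(all(abs(cm$delta[nz] - abs(dm$d[nz])) < 1e-15))
    kept <- sum(dm$d > 0)
    expect_lte(length(nz), ceiling((1 - 0.75) * kept) + 1)
  }
})

test_that("rank_channels finds the injected informative pairs", {
  # activation only in channels 2 <-> 12
  trials <- slice_trials(generate_session(
    quiet_params(trials_per_condition = 3, informative_left = 2, seed = 3),
    "execution"))
  rk <- rank_channels(build_connectivity(trials), default_montage(), top = 1)
  expect_equal(rk$left[1], 2)
  expect_equal(rk$right[1], 12)
  # all-zero connectivity: zero scores, ties broken by ascending channel id
  cm0 <- quartile_filter(difference_matrix(
    stats::setNames(c(1:10, 1:10 - 10), 1:20), "HbO"))
  cm0$delta[] <- 0
  cm0$hand <- "right"
  rk0 <- rank_channels(list(cm0), default_montage(), top = 3)
  expect_true(all(rk0$score == 0))
  expect_equal(rk0$left, 1:10)
})

test_that("rank_channels recovers {2,7,8}<->{12,17,18} on a high-SNR session", {
  trials <- make_trials(10, "execution", snr = 3, seed = 21)
  sel <- selected_pairs(rank_channels(build_connectivity(trials),
                                      default_montage(), top = 3))
  expect_setequal(sel[, "left"], c(2, 7, 8))
  expect_setequal(sel[, "right"], c(12, 17, 18))
})

test_that("rank_channels is permutation-equivariant", {
  trials <- make_trials(3, "execution", snr = 3, seed = 13)
  mont <- default_montage()
  rk <- rank_channels(build_connectivity(trials), mont, top = 3)
  # relabel: swap channels (2,12) with (5,15) everywhere
  perm <- 1:20
  perm[c(2, 12, 5, 15)] <- c(5, 15, 2, 12)
  trials_p <- lapply(trials, function(tr) {
    tr$hbo <- tr$hbo[, perm]; tr$hbr <- tr$hbr[, perm]
    colnames(tr$hbo) <- colnames(tr$hbr) <- as.character(1:20)
    tr
  })
  rk_p <- rank_channels(build_connectivity(trials_p), mont, top = 3)
  remap <- function(x) ifelse(x == 2, 5, ifelse(x == 5, 2, x))
  expect_equal(stats::setNames(rk_p$score[match(remap(rk$left), rk_p$left)],
                               NULL),
               rk$score, tolerance = 1e-12)
})
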