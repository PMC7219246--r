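fake_decisions <- function(truth, label) {
  structure(data.frame(trial = seq_along(truth), true_hand = truth,
                       condition = "execution", CR = 0L, CL = 0L,
                       label = label, stringsAsFactors = FALSE),
            class = c("fnirs_decisions", "data.frame"))
}

test_that("confusion counts by definition and applies the uncertain policy", {
  d <- fake_decisions(rep(c("right", "left"), each = 10),
                      rep(c("right", "left"), each = 10))
  ct <- confusion(d)
  expect_equal(unlist(ct[c("TP", "FP", "TN", "FN")]),
               c(TP = 10L, FP = 0L, TN = 10L, FN = 0L))
  # uncertain under policy = error charges the true class
  d2 <- fake_decisions(c("right", "left"), c("uncertain", "uncertain"))
  ct2 <- confusion(d2, "error")
  expect_equal(ct2$FN, 1L)
  expect_equal(ct2$FP, 1L)
  ct3 <- confusion(d2, "drop")
  expect_equal(ct3$TP + ct3$TN + ct3$FP + ct3$FN, 0L)
  expect_equal(ct3$uncertain, 2L)
  expect_error(confusion(fake_decisions("both", "left")), "hand")
})

test_that("confusion equals a brute-force recount on fuzzed decisions", {
  set.seed(31)
  for (rep in 1:10) {
    truth <- sample(c("left", "right"), 50, replace = TRUE)
    label <- sample(c("left", "right", "uncertain"), 50, replace = TRUE)
    ct <- confusion(fake_decisions(truth, label), "error")
    # independent recount
    tp <- tn <- fp <- fn <- 0
    for (i in 1:50) {
      if (truth[i] == "right") {
        if (label[i] == "right") tp <- tp + 1 else fn <- fn + 1
      } else {
        if (label[i] == "left") tn <- tn + 1 else fp <- fp + 1
      }
    }
    expect_equal(unlist(ct[c("TP", "FP", "TN", "FN")]),
                 c(TP = tp, FP = fp, TN = tn, FN = fn),
                 ignore_attr = TRUE)
  }
})

test_that("rates implement the percent formulas with FPF = 100 - TNF", {
  ct <- confusion(fake_decisions(rep("right", 100), rep("left", 100)))
  expect_error(rates(ct), "left-hand")      # no negatives at all
  mk_ct <- function(tp, fp, tn, fn)
    structure(list(TP = tp, FP = fp, TN = tn, FN = fn, uncertain = 0L,
                   policy = "error"), class = "fnirs_confusion")
  expect_equal(rates(mk_ct(86, 10, 90, 14))$TPF, 86.0)
  # the published specificity/false-positive pair: TNF 76.2 -> FPF 23.8
  r <- rates(mk_ct(861, 238, 762, 139))
  expect_equal(r$TNF, 76.2)
  expect_equal(r$FPF, 23.8)
  # TNF 98.0 -> FPF 2.0
  expect_equal(rates(mk_ct(982, 20, 980, 18))$FPF, 2.0)
  # TP == FN -> 50%
  expect_equal(rates(mk_ct(7, 1, 1, 7))$TPF, 50)
})

test_that("rates . confusion is consistent on fuzzed sets (property)", {
  set.seed(37)
  for (rep in 1:20) {
    truth <- sample(c("left", "right"), 40, replace = TRUE)
    truth[1:2] <- c("left", "right")          # both classes present
    label <- sample(c("left", "right", "uncertain"), 40, replace = TRUE)
    r <- rates(confusion(fake_decisions(truth, label), "error"))
    expect_equal(r$FPF, 100 - r$TNF)
    expect_true(all(unlist(r[c("TPF", "TNF", "FPF")]) >= 0))
    expect_true(all(unlist(r[c("TPF", "TNF", "FPF")]) <= 100))
  }
})

test_that("two-segment ROC vertices and AUC", {
  mk_rates <- function(tpf, fpf)
    structure(list(TPF = tpf, TNF = 100 - fpf, FPF = fpf, accuracy = NA),
              class = "fnirs_rates")
  expect_equal(roc_curve(mk_rates(100, 0))$auc, 1.0)
  expect_equal(roc_curve(mk_rates(100, 100))$auc, 0.5)
  # worked pair (FPF 23.8, TPF 86.1): trapezoid oracle ~ 0.812
  roc <- roc_curve(mk_rates(86.1, 23.8))
  expect_equal(roc$auc, 0.8115, tolerance = 1e-3)
  expect_equal(roc$vertices[2, ], c(FPF = 23.8, TPF = 86.1))
  # closed form equals independent trapezoid integration (property)
  set.seed(41)
  for (rep in 1:20) {
    tpf <- runif(1, 0, 100); fpf <- runif(1, 0, 100)
    r <- roc_curve(mk_rates(tpf, fpf))
    x <- c(0, fpf, 100) / 100; y <- c(0, tpf, 100) / 100
    trapz <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
    expect_equal(r$auc, trapz, tolerance = 1e-12)
    expect_true(all(diff(r$vertices[, 1]) >= 0) &&
                  all(diff(r$vertices[, 2]) >= 0))
  }
})

test_that("k-fold evaluation partitions trials and is seed-reproducible", {
  trials <- make_trials(100, "execution", snr = 3, seed = 43)
  cv <- kfold_evaluate(trials, k = 10, subsample = 20, seed = 1)
  expect_equal(nrow(cv$folds), 10)
  expect_true(all(grepl("^2:12|^7:17|^8:18", cv$folds$pairs)))
  expect_gte(cv$mean["TPF"], 98)
  # reproducibility and input-order invariance
  cv2 <- kfold_evaluate(trials, k = 10, subsample = 20, seed = 1)
  expect_identical(cv$folds, cv2$folds)
  cv3 <- kfold_evaluate(trials[sample(seq_along(trials))], k = 10,
                        subsample = 20, seed = 1)
  expect_identical(cv$folds, cv3$folds)
  expect_error(kfold_evaluate(trials[1:30], k = 10, subsample = 20),
               "at least")
})

test_that("identical trials in every fold give zero spread", {
  base <- make_trials(2, "execution", snr = 3, seed = 47)
  trials <- rep(base, 50)[1:200]
  cv <- kfold_evaluate(trials, k = 10, subsample = 20, seed = 2)
  expect_equal(unname(cv$sd["TPF"]), 0)
  expect_equal(unname(cv$sd["accuracy"]), 0)
})
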